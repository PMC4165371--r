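---
title: "Methods: inferring lung-to-muscle cytokine crosstalk networks"
author: "MuscleCrosstalk package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring lung-to-muscle cytokine crosstalk networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MuscleCrosstalk)
```

## The scientific question

Chronic obstructive pulmonary disease (COPD) is a lung disease, but one of
its most debilitating co-morbidities is skeletal-muscle wasting. A standing
hypothesis is that inflammatory mediators secreted by the diseased lung act
as systemic signals that reprogram energy metabolism in distant muscle.
MuscleCrosstalk implements a complete analysis chain for testing this kind
of cross-tissue hypothesis with expression data: it links the expression of
soluble-factor (cytokine-superfamily) genes in one tissue to the
pathway-level transcriptional state of other tissues, scores the resulting
signatures against a reference disease signature across species, and
validates candidate mediators in a serum-protein arm.

The chain has six analysis stages, each exposed as ordinary functions and
orchestrated by `runPipeline()`:

1. **Detection filtering** (`filterByDetection`): probes flagged absent in
   at least 80% of samples are discarded, i.e. a gene must be called present
   in at least 20% of chips (the `min_present_fraction = 0.2` default).
2. **Differential expression** (`samTwoClass`, `selectDe`): a SAM-style
   moderated statistic with permutation-based FDR, thresholded at q <= 0.01.
3. **Pathway over-representation** (`easeScore`, `enrichLists`): the
   conservative EASE variant of the one-tailed Fisher test, applied to the
   up-, down- and combined gene lists of each contrast, threshold p < 0.2.
4. **Pathway activity indices** (`pathwayPcIndex`): the first three
   principal components of each enriched pathway's gene-centred member
   submatrix summarise its activity per sample.
5. **Crosstalk network inference** (`spearmanPerm`, `inferNetwork`):
   Spearman correlation between each soluble factor's profile and each
   pathway component, with permutation p-values (10,000 permutations by
   convention) thresholded at p < 0.01.
6. **Cross-species overlap and serum validation** (`sensitivitySpecificity`,
   `jaccardMatrix`, `knnImpute`, `mackSkillings`, `prerankedGsea`): the
   animal signatures are scored against a human reference signature, and
   serum analytes are tested for disease effects and correlated with muscle
   expression, with pre-ranked GSEA on the correlation ranking.

## The statistical machinery, in detail

### SAM differential expression

For a two-class unpaired contrast the statistic per gene is

\[ d_i = \frac{\bar x_{i1} - \bar x_{i2}}{s_i + s_0}, \qquad
   s_i = \sqrt{\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)
   \frac{\sum_1 (x - \bar x_{i1})^2 + \sum_2 (x - \bar x_{i2})^2}{n_1 + n_2 - 2}} \]

where the fudge factor $s_0$ is chosen by Tusher's procedure: among the
percentiles of the $s_i$ distribution, pick the one minimising the
coefficient of variation of window-wise median absolute deviations of $d$
across the range of $s$ (a fixed-percentile fallback is selectable via
`s0_method = "percentile"`). The false discovery rate at each observed
$|d_i|$ is the median, over class-label permutations, of the number of
permuted $|d^*|$ values reaching $|d_i|$, divided by the number of observed
values reaching it, capped at one and monotonized along the $|d|$ ranking.
No $\pi_0$ shrinkage is applied, which makes the q-values deliberately
conservative (the null-calibration test shows the realised call fraction is
far below nominal). When the number of distinct label arrangements is at
most `n_perm` the arrangements are enumerated exhaustively, which makes
small-cohort results (e.g. 4 vs 4 animals: 70 arrangements) fully
deterministic. Fold change is the difference of class means, because the
inputs are log-scale ratios.

### EASE over-representation

The EASE score penalises the classical one-tailed hypergeometric p-value by
removing one gene from the observed overlap: with overlap $k$, list size
$n$, set size $K$ and universe $N$ it reports $P(X \ge k - 1)$, and returns
1 whenever $k \le 1$. The universe is the set of genes that survive
detection filtering on the platform, a configurable choice. Each pathway is
tested against the up list, the down list and their union; the reported
direction is `up`/`down` when only that directional test passes, and `both`
when both pass or only the combined list does. Category filtering (e.g.
restricting to the four canonical KEGG top-level groups) happens before
testing but never alters the universe, so it cannot change p-values of
retained pathways. Eligibility of pathways for activity indexing uses a
separate, stricter threshold (default: Benjamini-Hochberg adjusted
combined-list EASE p < 0.10; the adjustment can be switched off).

### Pathway activity indices

For each eligible pathway the member submatrix is gene-centred (not
variance-scaled: all values are log ratios on a common scale) and
decomposed with samples as observations. The first three components are
retained; the variance fractions reported are each eigenvalue over the
total member-gene variance. Principal components carry a sign
indeterminacy, so each component's sign is fixed to correlate non-negatively
with the mean member-gene profile; this makes reruns bit-identical. Samples
(not genes) carry the scores because the downstream correlation step pairs
them with per-animal cytokine profiles.

### Permutation-tested Spearman edges

Rank correlation captures monotone, not merely linear, coupling. For each
(factor, pathway, component) triple the p-value is two-sided: the fraction
of permutations of one margin whose $|\rho^*|$ reaches the observed
$|\rho|$, computed exhaustively when $n! \le$ `n_perm` and otherwise by
sampling with the $(1 + \text{exceedances})/(n_\text{perm} + 1)$ estimator.
Animals missing either tissue are dropped pairwise per test. Each test
derives its own sub-seed from the global seed and the triple's identity, so
the edge set is independent of iteration order and of which other factors
are present. No multiplicity correction is applied across the grid — raw
permutation p < 0.01 is the replicated convention — but a
Benjamini-Hochberg switch is available (`adjust = "BH"`). Pathway-level
network views collapse multiple per-component edges to the strongest
(`collapseNetwork`).

### Cross-species overlap scoring

A pathway signature is a set of pathway identifiers with enrichment
directions. Sensitivity is the fraction of reference ("true response")
pathways recovered; specificity is the fraction of non-reference pathways
in a declared universe correctly absent from the test signature. The
direction-aware variant additionally requires compatible directions, where
`both` acts as a wildcard on either side — the lenient rule is stated
explicitly so the directed-versus-undirected inequality is unambiguous.
Because the published specificity numbers depend on an unstated pathway
universe, the package treats the universe as an explicit argument (the
pipeline uses the pathways tested in both species' enrichment runs) and
reproduces only the sensitivity arithmetic exactly. Overlap significance is
an upper-tail hypergeometric test, the standard exact choice for an
unstated test; the sampling assumptions are the usual fixed-margin ones.

### Serum arm

Serum analyte panels are log2 values with missing cells. The pipeline order
is impute, then standardise, then test. Imputation replaces a missing cell
by the mean of the subject's values for the k analytes nearest in
root-mean-square distance over jointly observed subjects (k = 10 by
default, reduced for small panels). Standardisation is analyte-wise with
the sample-SD (n-1) convention. The Mack-Skillings statistic generalises
Friedman's test to replicated cells: observations are jointly ranked within
each block, treatment rank sums are standardised by block size
($W_i = \sum_j R_{ij}/(n_j + 1)$), and the quadratic form of $W - E[W]$ in
the generalized inverse of its null covariance is referred to
$\chi^2_{k-1}$. Ties get average ranks without a variance correction. With
one replicate per cell this reduces exactly to Friedman's statistic. Both
main effects (disease, training) are obtained by exchanging the treatment
and block roles; incomplete blocks are an error by default, with a
drop-block policy available (`incomplete = "drop"`) since the correct
handling of unbalanced layouts is a judgment call.

Analytes with a disease main effect are correlated (Pearson) against every
muscle gene, and the resulting ranking is tested with pre-ranked GSEA:
member genes advance a running sum by $|r|^p$ normalised over the set,
non-members retreat it by $1/(N - m)$, and the enrichment score is the
maximal deviation. Because the ranking is a correlation vector rather than
per-sample data, the null is gene-set permutation (random sets of the same
size drawn from the ranking); the normalised score divides by the mean
|null ES| of matching sign and the p-value is the same-sign exceedance
fraction. Defaults are weighted scoring ($p = 1$) and 1,000 draws; the
classic unweighted statistic ($p = 0$) is invariant to monotone rescaling
of the scores, which the tests verify.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream property is demonstrated.

The animal cohort emulates a smoke-exposure design: 16 animals in four
groups of four (sham, smoke, hypoxia, combined), three tissues per animal
(lung plus an oxidative and a glycolytic hindlimb muscle), and three
samples lost during processing, one per tissue, chosen uniformly under the
seed. Baseline expression is gene-wise Gaussian on the log scale with a
gene-specific mean drawn from U(4, 12) and a common residual SD
(`noise_sd`, default 0.25 log units — a free parameter, since within-group
variance of real cohorts is not part of the design being emulated).
Pathways (default 15, sizes 10-50 over the non-cytokine genes, 10% member
overlap between sets) receive a shared per-animal co-expression factor at
half the residual SD, so member genes have within-group SD
$\sigma\sqrt{1.25}$.

Differential expression is planted pathway-wise: whole pathways are shifted
with a common sign in a contrast group, and the remaining DE budget
(`de_fraction`, default 5% of genes at `de_effect_sd = 3` within-group SDs)
is filled with individually shifted genes. Planting at pathway granularity
is what makes enrichment recovery a testable property; uniformly scattered
DE genes would carry no pathway signal by construction.

Cytokine-to-pathway couplings are planted through a per-animal latent
factor added to the cytokine's lung profile and to the member genes of the
target pathway in both muscles. Two calibration details matter. First, the
muscle-side latent is mixed to an **exact sample** Pearson correlation with
the cytokine-side latent (residualising and standardising the second
factor), so couplings stay tight at n = 16. Second, the target of that
Pearson mixing is $2\sin(\pi\rho/6)$ rather than $\rho$ itself — the
Gaussian-copula inversion — so that the **Spearman** correlation of the
emitted data converges to the requested `planted_rho`. The latent is
planted only on genes exclusive to the target pathway; planting on shared
genes would leak the coupling into overlapping pathways' indices and
manufacture spurious edges. When DE planting is active, each planted
cytokine is also made differentially expressed by letting the group shift
ride on the latent factor itself: the muscle side then co-varies with the
shift, so the coupling survives — which is the intended biology, a
disease-modulated mediator tracking a muscle pathway.

The human cohort emulates a clinical validation arm: 23 controls and 26
patients split over normal- and low-FFMI groups, a small serum panel with
completely-at-random missing cells, a training-status factor, and a paired
muscle matrix in which selected analytes are coupled to pathway activity
(default: two analytes at Pearson r = -0.8, mirroring an inverse
inflammation-to-energy-metabolism coupling) and a disease signature of six
wholesale-shifted pathways distinguishes the low-FFMI group.

What the generator does **not** emulate: probe-level intensities, scanner
or batch artefacts, heavy-tailed or count-distributed noise, correlated
missingness, and ortholog mapping noise between species. Passing tests
therefore demonstrate correctness of the statistical machinery under a
clean Gaussian co-expression model, not robustness to real microarray
pathology.

## Numerical and design choices

- **Seed fan-out.** One global seed is hashed with a stage or test label
  (`deriveSeed`) to give every stage and every permutation test its own
  sub-seed below $2^{31}$; adding a stage never perturbs another stage's
  randomness, and two runs with the same configuration produce
  byte-identical manifests (checksums included).
- **Exhaustive enumeration.** Both `samTwoClass` and `spearmanPerm` switch
  to exhaustive enumeration whenever the arrangement count does not exceed
  `n_perm`, removing Monte-Carlo noise on small cohorts.
- **Degenerate inputs.** Constant genes get $d = 0$ (the fudge factor
  guards the denominator; a fully constant matrix yields all-null results);
  constant vectors make the rank correlation undefined and are flagged
  rather than scored; zero-variance analytes are an error naming the
  analyte; pathways with fewer members than components are an error naming
  the pathway.
- **Tie handling.** Average ranks throughout (Spearman, Mack-Skillings);
  GSEA ranking ties and correlation-rank ties break lexicographically by
  gene id for determinism.
- **Eligibility fallback.** If no pathway passes the indexing eligibility
  threshold in a pipeline run, the run indexes all pathways and says so,
  rather than failing or silently emitting nothing.
- **Problem sizes.** The shipped tests and the acceptance script
  demonstrate the pipeline at desk scale: 800-2,000 genes, 10-15 pathways,
  16 animals, 49 subjects, 200-2,000 permutations, and 20-seed averages for
  recovery rates. These sizes were chosen so the full property suite runs
  in minutes while keeping every test's expected behaviour comfortably
  inside its tolerance; the statistical machinery itself is size-agnostic.
- **Edge-recovery conditions.** The planted-edge recovery study uses
  `de_fraction = 0`: the quantity under test is the specificity and
  sensitivity of the correlation machinery, so the background must be free
  of group-shift confounding, which would otherwise induce genuine (but
  unplanted) cytokine-pathway correlations through shared group structure.

## Known limitations

- The EASE/enrichment stage tests each pathway independently; redundant
  (highly overlapping) pathways are reported individually, with the Jaccard
  map and clustering available for interpretation rather than correction.
- The chi-square reference for Mack-Skillings is asymptotic; on very small
  layouts its p-value is bracketed by, but not equal to, the exact
  permutation tail (the tests verify the bracketing on a 2x2x2 layout).
- Specificity values depend on the declared pathway universe and are not
  comparable across analyses that declare different universes.
- The pre-ranked GSEA null (gene-set permutation) ignores gene-gene
  correlation, as any pre-ranked variant must; p-values for strongly
  co-expressed sets are optimistic in the usual, well-documented way.

## A worked example

```{r example, eval = FALSE}
co <- generateAnimalCohort(animalCohortConfig(seed = 11, noise_sd = 0.05,
                                              de_fraction = 0))
idx <- pathwayIndices(co$expression$soleus, co$collection)
dsg <- co$design
pair_l <- setNames(dsg$animal_id[dsg$tissue == "lung"],
                   dsg$sample_id[dsg$tissue == "lung"])
pair_s <- setNames(dsg$animal_id[dsg$tissue == "soleus"],
                   dsg$sample_id[dsg$tissue == "soleus"])
lung <- exprValues(co$expression$lung)
factors <- lapply(setNames(co$catalog, co$catalog), function(g)
  list(gene_id = g, values = setNames(lung[g, ], unname(pair_l[colnames(lung)])),
       de_status = c(CS = "null", CH = "null", CSCH = "null")))
net <- inferNetwork(factors, idx, pairing = pair_s,
                    n_perm = 2000, alpha = 0.01, seed = 5)
net
collapseNetwork(net)[, c("factor_id", "pathway_id", "rho", "p_perm")]
co$truth$planted_edges
```

All five planted couplings appear among the collapsed edges with rank
correlations near the planted 0.9; the handful of additional component
edges reflect the 1% per-test false-positive budget over the
factor-by-pathway-by-component grid.
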