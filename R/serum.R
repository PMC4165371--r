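#' K-nearest-neighbour imputation of a serum panel
#'
#' A missing cell (analyte a, subject s) is replaced by the mean of subject
#' s's values for the k analytes nearest to a, where nearness is Euclidean
#' distance over jointly observed subjects (root mean squared difference, so
#' pairs with different overlap are comparable). Only analytes observed at
#' subject s qualify as neighbours; when fewer than k of them are observed
#' there, the available ones are used. Complete cells are never changed.
#'
#' @param panel a \linkS4class{SerumPanel}.
#' @param k number of neighbours (default 10, capped per cell by availability).
#' @return The imputed \linkS4class{SerumPanel} (no missing cells).
#' @export
knnImpute <- function(panel, k = 10L) {
  V <- panelValues(panel)
  .stopIfNot(k >= 1L, "k must be at least 1")
  all_missing <- rownames(V)[rowSums(!is.na(V)) == 0L]
  if (length(all_missing))
    stop(sprintf("analyte '%s' has no observed values", all_missing[1]), call. = FALSE)
  out <- V
  na_cells <- which(is.na(V), arr.ind = TRUE)
  for (i in seq_len(nrow(na_cells))) {
    a <- na_cells[i, 1]; s <- na_cells[i, 2]
    cand <- which(!is.na(V[, s]))
    cand <- setdiff(cand, a)
    d <- vapply(cand, function(b) {
      joint <- !is.na(V[a, ]) & !is.na(V[b, ])
      if (!any(joint)) return(Inf)
      sqrt(mean((V[a, joint] - V[b, joint])^2))
    }, numeric(1))
    cand <- cand[is.finite(d)]; d <- d[is.finite(d)]
    if (!length(cand))
      stop(sprintf("analyte '%s' has no usable neighbour at subject '%s'",
                   rownames(V)[a], colnames(V)[s]), call. = FALSE)
    # fewer neighbours than requested: use what is observed for this subject
    nn <- cand[order(d, rownames(V)[cand])][seq_len(min(k, length(cand)))]
    out[a, s] <- mean(V[nn, s])
  }
  SerumPanel(out, panelDesign(panel))
}

#' Z-score a complete serum panel analyte-wise
#'
#' Centres every analyte and scales it to unit sample SD (n - 1 convention).
#'
#' @param panel a complete \linkS4class{SerumPanel}.
#' @return The standardised \linkS4class{SerumPanel}.
#' @export
zscorePanel <- function(panel) {
  V <- panelValues(panel)
  .stopIfNot(!anyNA(V), "panel has missing cells; impute first")
  sds <- apply(V, 1, sd)
  if (any(sds == 0))
    stop(sprintf("analyte '%s' has zero variance", rownames(V)[sds == 0][1]),
         call. = FALSE)
  SerumPanel((V - rowMeans(V)) / sds, panelDesign(panel))
}

#' Mack-Skillings rank test for a treatment effect in a replicated two-way layout
#'
#' Generalises the Friedman test to cells with replication: observations are
#' jointly ranked within each block (average ranks for ties), treatment rank
#' sums are standardised by block size, and a quadratic form in the
#' standardised sums is referred to a chi-square distribution on
#' (treatments - 1) degrees of freedom. With one replicate per cell the
#' statistic reduces to Friedman's. Unbalanced (but complete) layouts are
#' supported; a treatment absent from a block is an error unless
#' \code{incomplete = "drop"} removes such blocks.
#'
#' @param values numeric response vector.
#' @param treatment factor of treatment levels (the effect under test).
#' @param block factor of blocking levels (the nuisance factor).
#' @param incomplete \code{"error"} or \code{"drop"}.
#' @return list(statistic, df, p).
#' @examples
#' set.seed(1)
#' mackSkillings(rnorm(24), gl(2, 12), rep(gl(2, 6), 2))$p
#' @export
mackSkillings <- function(values, treatment, block, incomplete = c("error", "drop")) {
  incomplete <- match.arg(incomplete)
  treatment <- factor(treatment); block <- factor(block)
  .stopIfNot(length(values) == length(treatment) && length(values) == length(block),
             "values, treatment and block must have equal length")
  .stopIfNot(nlevels(treatment) >= 2L, "need at least two treatment levels")
  counts <- table(treatment, block)
  if (any(counts == 0)) {
    if (incomplete == "error")
      stop("a treatment is absent from a block (set incomplete = \"drop\" to drop such blocks)",
           call. = FALSE)
    keep_blocks <- colnames(counts)[colSums(counts == 0) == 0]
    keep <- block %in% keep_blocks
    values <- values[keep]; treatment <- droplevels(treatment[keep])
    block <- droplevels(block[keep])
    counts <- table(treatment, block)
    .stopIfNot(ncol(counts) > 0, "no complete blocks remain")
  }
  k <- nlevels(treatment)
  blocks <- levels(block)
  W <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  for (j in blocks) {
    in_b <- block == j
    r <- rank(values[in_b], ties.method = "average")
    nj <- sum(in_b)
    tb <- treatment[in_b]
    cj <- as.numeric(table(tb)[levels(treatment)])
    Rj <- vapply(levels(treatment), function(tl) sum(r[tb == tl]), numeric(1))
    W <- W + Rj / (nj + 1)
    E <- E + cj / 2
    V <- V - outer(cj, cj) / (12 * (nj + 1))
    diag(V) <- diag(V) + (cj * nj) / (12 * (nj + 1))  # restores c(n - c) on the diagonal
  }
  d <- W - E
  stat <- drop(t(d) %*% MASS::ginv(V) %*% d)
  stat <- max(0, stat)
  list(statistic = stat, df = k - 1L, p = pchisq(stat, df = k - 1L, lower.tail = FALSE))
}

#' Both main effects of a two-factor design via Mack-Skillings
#'
#' Tests each factor as the treatment with the other as block.
#'
#' @param values numeric response vector.
#' @param disease,training the two factors.
#' @param incomplete passed to \code{\link{mackSkillings}}.
#' @return data.frame with one row per effect: effect, statistic, df, p.
#' @export
mackSkillingsTwoFactor <- function(values, disease, training, incomplete = "error") {
  a <- mackSkillings(values, disease, training, incomplete = incomplete)
  b <- mackSkillings(values, training, disease, incomplete = incomplete)
  data.frame(effect = c("disease", "training"),
             statistic = c(a$statistic, b$statistic),
             df = c(a$df, b$df), p = c(a$p, b$p), stringsAsFactors = FALSE)
}

#' Rank all muscle genes by Pearson correlation with a serum analyte
#'
#' @param analyte named numeric vector of analyte levels by subject id.
#' @param muscle \linkS4class{ExpressionMatrix} (columns = subjects).
#' @return data.frame(gene_id, r) sorted by r descending, ties broken by
#'   gene id for determinism.
#' @export
correlateSerumMuscle <- function(analyte, muscle) {
  X <- exprValues(muscle)
  .stopIfNot(ncol(X) >= 5L, "need at least 5 subjects")
  .stopIfNot(!is.null(names(analyte)) && all(colnames(X) %in% names(analyte)),
             "subjects misaligned between analyte vector and muscle matrix")
  a <- analyte[colnames(X)]
  r <- suppressWarnings(as.vector(cor(t(X), a)))
  out <- data.frame(gene_id = rownames(X), r = r, stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Enrichment-score walk from hit positions within a ranking of length N.
# Candidate extrema occur at, and just before, each hit.
.gseaEs <- function(positions, weights, N) {
  m <- length(positions)
  o <- order(positions)
  positions <- positions[o]; weights <- weights[o]
  wsum <- sum(weights)
  cum_hit <- if (wsum > 0) cumsum(weights) / wsum else seq_len(m) / m
  j <- seq_len(m)
  miss_rate <- 1 / (N - m)
  at_hit <- cum_hit - (positions - j) * miss_rate
  before_hit <- c(0, cum_hit[-m]) - (positions - j) * miss_rate
  cand <- c(at_hit, before_hit)
  es <- cand[which.max(abs(cand))]
  list(es = es, at_hit = at_hit, before_hit = before_hit, order = o)
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov-like running sum over a score-ranked gene
#' list: member genes increment the walk proportionally to
#' |score|^\code{weight_exponent} (normalised over the set), non-members
#' decrement it by 1/(N - set size); the enrichment score (ES) is the
#' maximal deviation from zero. The null is gene-set permutation (random
#' sets of equal size drawn from the ranking), the normalised score (NES)
#' divides ES by the mean |null ES| of matching sign, and p is the fraction
#' of same-sign null scores at least as extreme.
#'
#' @param ranking data.frame(gene_id, score), or a named score vector; it is
#'   ordered by score descending (ties by gene id) internally.
#' @param geneset character vector of member gene ids (>= 3 in the ranking).
#' @param n_perm number of null gene-set draws.
#' @param weight_exponent 0 for the classic unweighted statistic, 1
#'   (default) for score weighting.
#' @param seed integer RNG seed.
#' @param set_id label stored in the result.
#' @return list(set_id, es, nes, p, leading_edge).
#' @export
prerankedGsea <- function(ranking, geneset, n_perm = 1000L, weight_exponent = 1,
                          seed = 1L, set_id = "geneset") {
  if (!is.data.frame(ranking))
    ranking <- data.frame(gene_id = names(ranking), score = as.numeric(ranking),
                          stringsAsFactors = FALSE)
  .stopIfNot(n_perm >= 100L, "n_perm too small")
  ranking <- ranking[order(-ranking$score, ranking$gene_id), , drop = FALSE]
  N <- nrow(ranking)
  positions <- which(ranking$gene_id %in% geneset)
  m <- length(positions)
  .stopIfNot(m >= 3L, "fewer than 3 gene-set members found in the ranking")
  .stopIfNot(m < N, "gene set must not cover the whole ranking")
  w_all <- abs(ranking$score)^weight_exponent
  obs <- .gseaEs(positions, w_all[positions], N)
  es <- obs$es

  set.seed(as.integer(seed))
  null_es <- vapply(seq_len(n_perm), function(b) {
    pos <- sample.int(N, m)
    .gseaEs(pos, w_all[pos], N)$es
  }, numeric(1))
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same) && mean(abs(same)) > 0) es / mean(abs(same)) else NA_real_
  p <- if (length(same)) sum(abs(same) >= abs(es) - 1e-12) / length(same)
       else 1 / (n_perm + 1)

  sorted_pos <- sort(positions)
  genes_sorted <- ranking$gene_id[sorted_pos]
  if (es >= 0) {
    peak <- which.max(obs$at_hit)
    leading <- genes_sorted[seq_len(peak)]
  } else {
    trough <- which.min(obs$before_hit)
    leading <- genes_sorted[seq(trough, m)]
  }
  list(set_id = set_id, es = es, nes = nes, p = p, leading_edge = leading)
}

#' Relative quantification by the comparative cycle-threshold method
#'
#' Computes 2^-((Ct_target - Ct_reference) - (Ct_target,cal - Ct_reference,cal)).
#'
#' @param ct_target,ct_reference sample Ct values for target and reference gene.
#' @param calibrator_target,calibrator_reference calibrator-sample Ct values.
#' @return Fold change relative to the calibrator.
#' @examples
#' deltaDeltaCt(22, 15, 24, 15)  # 4
#' @export
deltaDeltaCt <- function(ct_target, ct_reference, calibrator_target,
                         calibrator_reference) {
  .stopIfNot(all(is.finite(c(ct_target, ct_reference, calibrator_target,
                             calibrator_reference))), "Ct values must be finite")
  2^-((ct_target - ct_reference) - (calibrator_target - calibrator_reference))
}
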