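#' Configuration for a synthetic animal (smoke-exposure) cohort
#'
#' Defaults emulate the study design the downstream analysis assumes: 16
#' animals in four exposure groups of four (sham, cigarette smoke, chronic
#' hypoxia, and the combination), three tissues per animal (whole lung plus an
#' oxidative and a glycolytic hindlimb muscle), and three samples lost during
#' processing, one per tissue.
#'
#' @param n_per_group animals per exposure group.
#' @param groups ordered group labels; the first is the control/sham group.
#' @param tissues tissue labels; the first is the lung (cytokine) tissue and
#'   the remainder are muscles.
#' @param n_genes genes per tissue matrix (cytokines included).
#' @param n_pathways number of pathways in the synthetic collection.
#' @param pathway_size_range integer pair, inclusive pathway size bounds.
#' @param de_fraction fraction of genes planted as differentially expressed
#'   per tissue and contrast.
#' @param de_effect_sd planted group-mean shift in units of \code{noise_sd}.
#' @param n_cytokines number of soluble-factor genes (reserved "CYT" prefix).
#' @param n_planted_edges number of planted cytokine-to-pathway couplings.
#' @param planted_rho target Spearman correlation of planted couplings.
#' @param noise_sd within-group residual SD on the log scale.
#' @param dropout number of samples removed (at most one per tissue).
#' @param undetected_fraction fraction of genes emitted as absent-flagged
#'   noise rows, exercising the present-call filter.
#' @param seed integer RNG seed.
#' @return A validated list of class \code{"AnimalCohortConfig"}.
#' @export
animalCohortConfig <- function(n_per_group = 4L,
                               groups = c("SHAM", "CS", "CH", "CSCH"),
                               tissues = c("lung", "soleus", "gastrocnemius"),
                               n_genes = 2000L,
                               n_pathways = 15L,
                               pathway_size_range = c(10L, 50L),
                               de_fraction = 0.05,
                               de_effect_sd = 3,
                               n_cytokines = 20L,
                               n_planted_edges = 5L,
                               planted_rho = 0.9,
                               noise_sd = 0.25,
                               dropout = 3L,
                               undetected_fraction = 0.05,
                               seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group), groups = groups,
              tissues = tissues, n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              de_fraction = de_fraction, de_effect_sd = de_effect_sd,
              n_cytokines = as.integer(n_cytokines),
              n_planted_edges = as.integer(n_planted_edges),
              planted_rho = planted_rho, noise_sd = noise_sd,
              dropout = as.integer(dropout),
              undetected_fraction = undetected_fraction,
              seed = as.integer(seed))
  class(cfg) <- "AnimalCohortConfig"
  .validateAnimalConfig(cfg)
  cfg
}

.cfgErr <- function(field, why) stop(sprintf("invalid config field '%s': %s", field, why),
                                     call. = FALSE)

.validateAnimalConfig <- function(cfg) {
  if (cfg$n_per_group < 1L) .cfgErr("n_per_group", "must be positive")
  if (length(cfg$groups) < 2L) .cfgErr("groups", "need at least a control and one exposure group")
  if (length(cfg$tissues) < 2L) .cfgErr("tissues", "need lung plus at least one muscle")
  if (cfg$n_genes < 1L) .cfgErr("n_genes", "must be positive")
  if (cfg$n_pathways < 1L) .cfgErr("n_pathways", "must be positive")
  r <- cfg$pathway_size_range
  if (length(r) != 2L || r[1] < 1L || r[2] < r[1]) .cfgErr("pathway_size_range", "must be an increasing positive pair")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) .cfgErr("de_fraction", "must lie in [0,1]")
  if (cfg$de_effect_sd < 0) .cfgErr("de_effect_sd", "must be non-negative")
  if (cfg$n_cytokines < 1L) .cfgErr("n_cytokines", "must be positive")
  if (cfg$n_planted_edges < 0L) .cfgErr("n_planted_edges", "must be non-negative")
  if (abs(cfg$planted_rho) > 1) .cfgErr("planted_rho", "must lie in [-1,1]")
  if (cfg$noise_sd <= 0) .cfgErr("noise_sd", "must be positive")
  if (cfg$dropout < 0L || cfg$dropout > length(cfg$tissues))
    .cfgErr("dropout", "at most one sample may be removed per tissue")
  n_samples <- cfg$n_per_group * length(cfg$groups) * length(cfg$tissues)
  if (n_samples < cfg$dropout) .cfgErr("dropout", "exceeds total sample count")
  if (cfg$n_planted_edges > min(cfg$n_cytokines, cfg$n_pathways))
    .cfgErr("n_planted_edges", "needs distinct cytokines and pathways per edge")
  if (cfg$undetected_fraction < 0 || cfg$undetected_fraction >= 1)
    .cfgErr("undetected_fraction", "must lie in [0,1)")
  if (cfg$n_cytokines >= cfg$n_genes) .cfgErr("n_cytokines", "must be smaller than n_genes")
  invisible(cfg)
}

# Gaussian-copula inversion: the latent Pearson correlation that yields an
# asymptotic Spearman correlation equal to rho for bivariate normal latents.
.pearsonForSpearman <- function(rho) 2 * sin(pi * rho / 6)

# Build a latent with EXACT sample Pearson correlation r to f1: residualize
# f2 against f1, standardise both, and mix. Scaling to the target (rather
# than relying on the population correlation) keeps planted couplings tight
# at small cohort sizes.
.coupleLatent <- function(f1, f2, r) {
  z1 <- (f1 - mean(f1)) / sd(f1)
  e <- f2 - mean(f2) - sum((f2 - mean(f2)) * z1) / sum(z1^2) * z1
  z2 <- e / sd(e)
  r * z1 + sqrt(max(0, 1 - r^2)) * z2
}

#' Generate a synthetic pathway collection over a gene universe
#'
#' Pathway sizes are drawn uniformly from \code{size_range}. The first
#' pathway is sampled uniformly from the universe; each later pathway draws
#' \code{round(overlap_fraction * size)} members from genes already used by
#' earlier pathways (capped by availability) and the remainder from unused
#' genes, so \code{overlap_fraction = 0} yields pairwise-disjoint sets.
#'
#' @param n_pathways number of pathways.
#' @param size_range integer pair of inclusive size bounds.
#' @param universe character vector of candidate gene ids.
#' @param overlap_fraction fraction of each pathway drawn from
#'   previously-used genes.
#' @param seed integer RNG seed.
#' @return A \linkS4class{PathwayCollection}.
#' @examples
#' gp <- generatePathwayCollection(5, c(10, 20), paste0("g", 1:500), 0, seed = 1)
#' lengths(geneSets(gp))
#' @export
generatePathwayCollection <- function(n_pathways, size_range, universe,
                                      overlap_fraction = 0, seed = 1L) {
  size_range <- as.integer(size_range)
  if (max(size_range) > length(universe))
    .cfgErr("size_range", "maximum pathway size exceeds the gene universe")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    .cfgErr("overlap_fraction", "must lie in [0,1]")
  set.seed(as.integer(seed))
  sets <- vector("list", n_pathways)
  names(sets) <- sprintf("P%02d", seq_len(n_pathways))
  used <- character()
  for (i in seq_len(n_pathways)) {
    size <- if (size_range[1] == size_range[2]) size_range[1] else
      sample(seq(size_range[1], size_range[2]), 1L)
    n_shared <- if (i == 1L) 0L else min(round(overlap_fraction * size), length(used), size)
    shared <- if (n_shared > 0L) sample(used, n_shared) else character()
    unused <- setdiff(universe, used)
    n_rest <- size - n_shared
    if (length(unused) < n_rest) {
      if (length(setdiff(universe, shared)) < n_rest)
        .cfgErr("size_range", "gene universe exhausted while sampling pathways")
      rest <- sample(setdiff(universe, shared), n_rest)
    } else {
      rest <- if (n_rest > 0L) sample(unused, n_rest) else character()
    }
    sets[[i]] <- c(shared, rest)
    used <- union(used, sets[[i]])
  }
  PathwayCollection(sets,
                    descriptions = setNames(sprintf("synthetic pathway %d", seq_len(n_pathways)),
                                            names(sets)),
                    category = setNames(rep(sprintf("group%d", 1:4), length.out = n_pathways),
                                        names(sets)))
}

#' Generate a synthetic animal cohort with planted effects and ground truth
#'
#' Baseline expression is gene-wise Gaussian on the log scale (gene-specific
#' mean, common residual SD). Differential expression is planted pathway-wise:
#' whole pathways are shifted by \code{de_effect_sd * noise_sd} in a contrast
#' group (common sign per pathway), and the remaining DE budget is filled with
#' individually shifted genes. Cytokine-to-pathway couplings are planted via a
#' per-animal latent factor added both to the cytokine's lung profile and to
#' every member gene of the target pathway in the muscles, with the latent
#' Pearson correlation calibrated so the planted \emph{Spearman} correlation
#' converges to \code{planted_rho} as \code{noise_sd} shrinks.
#'
#' @param cfg an \code{\link{animalCohortConfig}}.
#' @return A list with elements \code{expression} (named list of
#'   \linkS4class{ExpressionMatrix}, one per tissue), \code{flags} (matching
#'   present-call logical matrices), \code{design} (sample design sheet),
#'   \code{collection} (a \linkS4class{PathwayCollection}), \code{catalog}
#'   (the soluble-factor gene list) and \code{truth} (ground-truth record).
#' @examples
#' cohort <- generateAnimalCohort(animalCohortConfig(n_genes = 300, seed = 7))
#' cohort$expression$lung
#' @export
generateAnimalCohort <- function(cfg) {
  stopifnot(inherits(cfg, "AnimalCohortConfig"))
  .validateAnimalConfig(cfg)
  set.seed(deriveSeed(cfg$seed, "animal_cohort"))

  n_animals <- cfg$n_per_group * length(cfg$groups)
  animals <- sprintf("A%02d", seq_len(n_animals))
  animal_group <- rep(cfg$groups, each = cfg$n_per_group)
  contrasts <- cfg$groups[-1]

  cyt_ids <- sprintf("CYT%02d", seq_len(cfg$n_cytokines))
  reg_ids <- sprintf("g%04d", seq_len(cfg$n_genes - cfg$n_cytokines))
  gene_ids <- c(cyt_ids, reg_ids)

  collection <- generatePathwayCollection(cfg$n_pathways, cfg$pathway_size_range,
                                          universe = reg_ids, overlap_fraction = 0.1,
                                          seed = deriveSeed(cfg$seed, "pathways"))
  sets <- geneSets(collection)
  pathway_ids <- names(sets)
  # restore cohort-level RNG stream after the nested, separately-seeded call
  set.seed(deriveSeed(cfg$seed, "animal_cohort_body"))

  # planted couplings: distinct cytokines and pathways
  planted <- data.frame(factor_id = character(), pathway_id = character(),
                        sign = character(), stringsAsFactors = FALSE)
  if (cfg$n_planted_edges > 0L) {
    planted <- data.frame(
      factor_id = sample(cyt_ids, cfg$n_planted_edges),
      pathway_id = sample(pathway_ids, cfg$n_planted_edges),
      sign = if (cfg$planted_rho >= 0) "+" else "-",
      stringsAsFactors = FALSE)
  }
  r_lat <- .pearsonForSpearman(cfg$planted_rho)
  latent_f <- matrix(rnorm(n_animals * max(1L, cfg$n_planted_edges)), n_animals,
                     dimnames = list(animals, NULL))
  latent_aux <- matrix(rnorm(length(latent_f)), n_animals)
  # with DE planting active, each planted cytokine is also differentially
  # expressed: the group shift rides on the latent factor itself so the
  # muscle-side coupling (and the cross-tissue correlation) survives it
  planted_de <- data.frame(contrast = character(), side = character())
  if (nrow(planted) && cfg$de_fraction > 0) {
    planted_de <- data.frame(contrast = sample(contrasts, nrow(planted), replace = TRUE),
                             side = sample(c("up", "down"), nrow(planted), replace = TRUE),
                             stringsAsFactors = FALSE)
    shift_cyt <- cfg$de_effect_sd * sqrt(1 + cfg$noise_sd^2)
    for (i in seq_len(nrow(planted))) {
      dir <- if (planted_de$side[i] == "up") 1 else -1
      latent_f[, i] <- latent_f[, i] +
        dir * shift_cyt * (animal_group == planted_de$contrast[i])
    }
  }
  latent_m <- apply(rbind(latent_f, latent_aux), 2,
                    function(z) .coupleLatent(z[seq_len(n_animals)],
                                              z[-seq_len(n_animals)], r_lat))
  rownames(latent_m) <- animals

  # undetected (dead) genes live outside pathways and cytokines
  in_pathway <- unique(unlist(sets, use.names = FALSE))
  dead_pool <- setdiff(reg_ids, in_pathway)
  n_dead <- min(round(cfg$undetected_fraction * cfg$n_genes), length(dead_pool))
  dead <- if (n_dead > 0L) sample(dead_pool, n_dead) else character()

  # DE planting per tissue x contrast, pathway-wise with a uniform remainder
  budget <- round(cfg$de_fraction * cfg$n_genes)
  de_genes <- de_pathways <- list()
  for (tis in cfg$tissues) {
    de_genes[[tis]] <- de_pathways[[tis]] <- list()
    for (ctr in contrasts) {
      up <- down <- character(); pw <- character()
      if (budget > 0L) {
        left <- budget
        for (p in sample(pathway_ids)) {
          if (length(sets[[p]]) > left) next
          pw <- c(pw, p)
          s <- sample(c("+", "-"), 1L)
          if (s == "+") up <- union(up, sets[[p]]) else down <- union(down, sets[[p]])
          left <- left - length(sets[[p]])
          if (left < min(lengths(sets))) break
        }
        pool <- setdiff(gene_ids, c(up, down, dead))
        extra <- sample(pool, min(left, length(pool)))
        sgn <- sample(c(TRUE, FALSE), length(extra), replace = TRUE)
        up <- c(up, extra[sgn]); down <- c(down, extra[!sgn])
      }
      de_genes[[tis]][[ctr]] <- list(up = sort(up), down = sort(down))
      de_pathways[[tis]][[ctr]] <- sort(pw)
    }
  }
  # record the planted cytokines' differential expression in the truth table
  # (their shift is carried by the latent factor, not the shift loop below)
  if (nrow(planted_de)) {
    for (i in seq_len(nrow(planted_de))) {
      ctr <- planted_de$contrast[i]; side <- planted_de$side[i]
      de_genes[[cfg$tissues[1]]][[ctr]][[side]] <-
        sort(union(de_genes[[cfg$tissues[1]]][[ctr]][[side]], planted$factor_id[i]))
    }
  }

  # dropout: pick tissues, then one random animal sample in each
  dropped <- character()
  if (cfg$dropout > 0L) {
    for (tis in sample(cfg$tissues, cfg$dropout))
      dropped <- c(dropped, paste(tis, sample(animals, 1L), sep = "_"))
  }

  # planted shifts are expressed in within-group SD units: pathway members
  # carry a shared co-expression factor at half the residual SD, so their
  # within-group SD is noise_sd * sqrt(1.25); cytokines coupled to a latent
  # factor have SD sqrt(noise_sd^2 + 1)
  sd_gene <- setNames(rep(cfg$noise_sd, cfg$n_genes), gene_ids)
  sd_gene[unique(unlist(sets, use.names = FALSE))] <- cfg$noise_sd * sqrt(1.25)
  shift_gene <- cfg$de_effect_sd * sd_gene
  shift_gene[planted$factor_id] <- 0   # their shift rides on the latent factor
  expression <- list(); flags <- list(); design <- NULL
  for (tis in cfg$tissues) {
    mu <- runif(cfg$n_genes, 4, 12)
    vals <- mu + matrix(rnorm(cfg$n_genes * n_animals, sd = cfg$noise_sd),
                        cfg$n_genes, n_animals)
    dimnames(vals) <- list(gene_ids, animals)
    # pathway co-expression (skip planted pathways: their coupling IS the factor)
    for (p in setdiff(pathway_ids, planted$pathway_id)) {
      u <- rnorm(n_animals)
      vals[sets[[p]], ] <- vals[sets[[p]], ] +
        rep(0.5 * cfg$noise_sd * u, each = length(sets[[p]]))
    }
    # planted couplings
    if (nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        if (tis == cfg$tissues[1]) {
          vals[planted$factor_id[i], ] <- vals[planted$factor_id[i], ] + latent_f[, i]
        } else {
          # plant only on genes exclusive to the target pathway so the
          # coupling cannot leak into overlapping pathways' indices
          pid <- planted$pathway_id[i]
          others <- unique(unlist(sets[names(sets) != pid], use.names = FALSE))
          mem <- setdiff(sets[[pid]], others)
          if (!length(mem)) mem <- sets[[pid]]
          vals[mem, ] <- vals[mem, ] + rep(latent_m[, i], each = length(mem))
        }
      }
    }
    # group-mean DE shifts (per-gene magnitude in within-group SD units)
    for (ctr in contrasts) {
      cols <- animal_group == ctr
      dg <- de_genes[[tis]][[ctr]]
      vals[dg$up, cols] <- vals[dg$up, cols] + shift_gene[dg$up]
      vals[dg$down, cols] <- vals[dg$down, cols] - shift_gene[dg$down]
    }
    # dead genes: noise floor, flagged absent almost everywhere
    flag <- matrix(runif(cfg$n_genes * n_animals) > 0.05, cfg$n_genes, n_animals,
                   dimnames = list(gene_ids, animals))
    if (length(dead)) {
      vals[dead, ] <- 2 + matrix(rnorm(length(dead) * n_animals, sd = cfg$noise_sd),
                                 length(dead), n_animals)
      flag[dead, ] <- matrix(runif(length(dead) * n_animals) < 0.05,
                             length(dead), n_animals)
    }
    sample_ids <- paste(tis, animals, sep = "_")
    colnames(vals) <- colnames(flag) <- sample_ids
    keep <- !(sample_ids %in% dropped)
    expression[[tis]] <- ExpressionMatrix(vals[, keep, drop = FALSE], tissue = tis)
    flags[[tis]] <- flag[, keep, drop = FALSE]
    design <- rbind(design, data.frame(sample_id = sample_ids[keep],
                                       animal_id = animals[keep],
                                       tissue = tis,
                                       group = animal_group[keep],
                                       stringsAsFactors = FALSE))
  }

  ncol_pl <- nrow(planted)
  truth <- list(de_genes = de_genes, de_pathways = de_pathways,
                planted_edges = planted,
                pathway_membership = sets,
                undetected_genes = sort(dead),
                # cytokine-side latent (per factor) and muscle-side latent
                # (per pathway); their sample Pearson correlation is the
                # copula-calibrated target
                latent_factors = `colnames<-`(latent_f[, seq_len(ncol_pl), drop = FALSE],
                                              planted$factor_id),
                pathway_latents = `colnames<-`(latent_m[, seq_len(ncol_pl), drop = FALSE],
                                               planted$pathway_id))
  list(expression = expression, flags = flags, design = design,
       collection = collection, catalog = cyt_ids, truth = truth)
}

#' Configuration for a synthetic human serum + muscle cohort
#'
#' Defaults emulate a clinical validation arm: 23 healthy controls and 26
#' patients split over a normal and a low fat-free-mass-index group, a small
#' multiplexed serum analyte panel with missing values, and a paired muscle
#' expression matrix whose pathway activity is coupled to selected analytes.
#'
#' @param n_controls,n_copd_normal,n_copd_low subjects per clinical group.
#' @param n_analytes serum analytes on the panel.
#' @param n_modulated_analytes analytes shifted between disease groups.
#' @param analyte_shift_sd disease shift in units of the serum residual SD.
#' @param missing_fraction completely-at-random missing-cell rate in [0,1).
#' @param coupling data.frame (analyte_id, pathway_id, r) of planted
#'   analyte-to-pathway Pearson couplings; NULL for the default two
#'   negative couplings.
#' @param training_factor_levels number of training-status levels.
#' @param n_genes,n_pathways,pathway_size_range muscle matrix dimensions.
#' @param noise_sd serum residual SD (log2 units).
#' @param muscle_de_pathways number of pathways shifted wholesale in the
#'   low-FFMI muscle (the cohort's disease signature).
#' @param muscle_de_effect_sd that shift in within-group SD units.
#' @param seed integer RNG seed.
#' @return A validated list of class \code{"HumanCohortConfig"}.
#' @export
humanCohortConfig <- function(n_controls = 23L, n_copd_normal = 13L, n_copd_low = 13L,
                              n_analytes = 7L, n_modulated_analytes = 2L,
                              analyte_shift_sd = 3, missing_fraction = 0.05,
                              coupling = NULL, training_factor_levels = 2L,
                              n_genes = 2000L, n_pathways = 15L,
                              pathway_size_range = c(10L, 50L),
                              noise_sd = 0.3, muscle_de_pathways = 6L,
                              muscle_de_effect_sd = 3, seed = 1L) {
  if (is.null(coupling))
    coupling <- data.frame(analyte_id = c("ANL01", "ANL02"),
                           pathway_id = c("P01", "P02"),
                           r = c(-0.8, -0.8), stringsAsFactors = FALSE)
  cfg <- list(n_controls = as.integer(n_controls),
              n_copd_normal = as.integer(n_copd_normal),
              n_copd_low = as.integer(n_copd_low),
              n_analytes = as.integer(n_analytes),
              n_modulated_analytes = as.integer(n_modulated_analytes),
              analyte_shift_sd = analyte_shift_sd,
              missing_fraction = missing_fraction, coupling = coupling,
              training_factor_levels = as.integer(training_factor_levels),
              n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              noise_sd = noise_sd,
              muscle_de_pathways = as.integer(muscle_de_pathways),
              muscle_de_effect_sd = muscle_de_effect_sd, seed = as.integer(seed))
  class(cfg) <- "HumanCohortConfig"
  .validateHumanConfig(cfg)
  cfg
}

.validateHumanConfig <- function(cfg) {
  for (f in c("n_controls", "n_copd_normal", "n_copd_low", "n_analytes",
              "training_factor_levels"))
    if (cfg[[f]] < 1L) .cfgErr(f, "must be positive")
  if (cfg$n_modulated_analytes < 0L || cfg$n_modulated_analytes > cfg$n_analytes)
    .cfgErr("n_modulated_analytes", "must lie in [0, n_analytes]")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1)
    .cfgErr("missing_fraction", "must lie in [0,1)")
  if (any(abs(cfg$coupling$r) > 1)) .cfgErr("coupling", "target Pearson r must lie in [-1,1]")
  if (cfg$noise_sd <= 0) .cfgErr("noise_sd", "must be positive")
  if (cfg$muscle_de_pathways < 0L || cfg$muscle_de_pathways > cfg$n_pathways)
    .cfgErr("muscle_de_pathways", "must lie in [0, n_pathways]")
  if (cfg$muscle_de_effect_sd < 0) .cfgErr("muscle_de_effect_sd", "must be non-negative")
  invisible(cfg)
}

#' Generate a synthetic human serum + muscle cohort
#'
#' @param cfg a \code{\link{humanCohortConfig}}.
#' @return A list with elements \code{serum} (a \linkS4class{SerumPanel} with
#'   missing cells), \code{muscle} (an \linkS4class{ExpressionMatrix}),
#'   \code{design} (subject design sheet), \code{collection} and \code{truth}.
#' @examples
#' hc <- generateHumanCohort(humanCohortConfig(n_genes = 300, seed = 3))
#' hc$serum
#' @export
generateHumanCohort <- function(cfg) {
  stopifnot(inherits(cfg, "HumanCohortConfig"))
  .validateHumanConfig(cfg)
  set.seed(deriveSeed(cfg$seed, "human_cohort"))

  subjects <- c(sprintf("CTL%02d", seq_len(cfg$n_controls)),
                sprintf("CPN%02d", seq_len(cfg$n_copd_normal)),
                sprintf("CPL%02d", seq_len(cfg$n_copd_low)))
  group <- rep(c("control", "copd_normal_ffmi", "copd_low_ffmi"),
               c(cfg$n_controls, cfg$n_copd_normal, cfg$n_copd_low))
  n_sub <- length(subjects)
  training <- sprintf("T%d", sample(seq_len(cfg$training_factor_levels),
                                    n_sub, replace = TRUE))
  design <- data.frame(subject_id = subjects, group = group, training = training,
                       stringsAsFactors = FALSE)

  analyte_ids <- sprintf("ANL%02d", seq_len(cfg$n_analytes))
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  collection <- generatePathwayCollection(cfg$n_pathways, cfg$pathway_size_range,
                                          universe = gene_ids, overlap_fraction = 0.1,
                                          seed = deriveSeed(cfg$seed, "human_pathways"))
  sets <- geneSets(collection)
  set.seed(deriveSeed(cfg$seed, "human_cohort_body"))

  bad <- setdiff(cfg$coupling$pathway_id, names(sets))
  if (length(bad)) .cfgErr("coupling", paste("unknown pathway id:", bad[1]))
  bad <- setdiff(cfg$coupling$analyte_id, analyte_ids)
  if (length(bad)) .cfgErr("coupling", paste("unknown analyte id:", bad[1]))

  serum <- matrix(runif(cfg$n_analytes, 4, 10) +
                    rnorm(cfg$n_analytes * n_sub, sd = cfg$noise_sd),
                  cfg$n_analytes, n_sub, dimnames = list(analyte_ids, subjects))
  muscle <- matrix(runif(cfg$n_genes, 4, 12) +
                     rnorm(cfg$n_genes * n_sub, sd = 0.25),
                   cfg$n_genes, n_sub, dimnames = list(gene_ids, subjects))

  # disease-modulated analytes: common shift for all COPD subjects
  modulated <- head(analyte_ids, cfg$n_modulated_analytes)
  mod_sign <- if (length(modulated))
    sample(c(1, -1), length(modulated), replace = TRUE) else numeric()
  is_copd <- group != "control"
  for (i in seq_along(modulated))
    serum[modulated[i], is_copd] <- serum[modulated[i], is_copd] +
      mod_sign[i] * cfg$analyte_shift_sd * cfg$noise_sd

  # planted analyte-pathway couplings via a per-subject latent factor
  for (p in setdiff(names(sets), cfg$coupling$pathway_id)) {
    u <- rnorm(n_sub)
    muscle[sets[[p]], ] <- muscle[sets[[p]], ] + rep(0.125 * u, each = length(sets[[p]]))
  }
  for (i in seq_len(nrow(cfg$coupling))) {
    r <- cfg$coupling$r[i]
    f1 <- rnorm(n_sub); f2 <- rnorm(n_sub)
    m <- .coupleLatent(f1, f2, r)
    serum[cfg$coupling$analyte_id[i], ] <- serum[cfg$coupling$analyte_id[i], ] + f1
    mem <- sets[[cfg$coupling$pathway_id[i]]]
    muscle[mem, ] <- muscle[mem, ] + rep(m, each = length(mem))
  }

  # disease signature in muscle: whole pathways shifted in the low-FFMI group
  de_pw <- character(); de_sign <- character()
  if (cfg$muscle_de_pathways > 0L) {
    candidates <- setdiff(names(sets), cfg$coupling$pathway_id)
    de_pw <- sample(candidates, min(cfg$muscle_de_pathways, length(candidates)))
    de_sign <- sample(c("+", "-"), length(de_pw), replace = TRUE)
    is_low <- group == "copd_low_ffmi"
    shift <- cfg$muscle_de_effect_sd * 0.25 * sqrt(1 + 0.25^2)
    for (i in seq_along(de_pw)) {
      mem <- sets[[de_pw[i]]]
      muscle[mem, is_low] <- muscle[mem, is_low] +
        if (de_sign[i] == "+") shift else -shift
    }
  }

  # completely-at-random missingness on the serum panel
  if (cfg$missing_fraction > 0) {
    miss <- runif(length(serum)) < cfg$missing_fraction
    serum[miss] <- NA_real_
  }

  truth <- list(modulated_analytes = data.frame(analyte_id = modulated,
                                                sign = ifelse(mod_sign > 0, "+", "-"),
                                                stringsAsFactors = FALSE),
                coupling = cfg$coupling,
                de_pathways = data.frame(pathway_id = de_pw, sign = de_sign,
                                         stringsAsFactors = FALSE),
                pathway_membership = sets)
  list(serum = SerumPanel(serum, design),
       muscle = ExpressionMatrix(muscle, tissue = "vastus_lateralis"),
       design = design, collection = collection, truth = truth)
}
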