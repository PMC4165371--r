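#' Default pipeline configuration
#'
#' Thresholds default to the replicated study conventions: DE FDR 1\%,
#' enrichment EASE p < 0.2, pathway-index eligibility FDR < 10\%, network
#' edge alpha 0.01 with 10,000 permutations.
#'
#' @return Nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    thresholds = list(de_fdr = 0.01, enrich_p = 0.2, index_eligibility = 0.10,
                      edge_alpha = 0.01, serum_p = 0.05),
    n_perm = list(de = 1000L, network = 10000L, gsea = 1000L),
    serum_k = 5L,
    categories = NULL,
    paths = NULL,
    animal = list(),
    human = list()
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML string, a YAML file path, or a nested list. Omitted keys
#' are filled with the defaults of \code{\link{defaultPipelineConfig}}.
#' Violations are collected and returned, not raised, each naming the
#' offending field path.
#'
#' @param raw YAML text, YAML file path, or list.
#' @return list(config, errors); the configuration is usable iff
#'   \code{length(errors) == 0}.
#' @examples
#' v <- validatePipelineConfig("thresholds:\n  edge_alpha: 1.5\n")
#' v$errors
#' @export
validatePipelineConfig <- function(raw = NULL) {
  if (is.null(raw)) raw <- list()
  if (is.character(raw) && length(raw) == 1L) {
    raw <- if (file.exists(raw)) yaml::read_yaml(raw) else yaml::yaml.load(raw)
    if (is.null(raw)) raw <- list()
  }
  def <- defaultPipelineConfig()
  cfg <- utils::modifyList(def, raw)
  # modifyList drops NULL-valued keys; restore them so validated configs
  # round-trip through YAML unchanged
  for (k in names(def)) if (!k %in% names(cfg)) cfg[k] <- list(def[[k]])
  cfg <- cfg[c(names(def), setdiff(names(cfg), names(def)))]
  errors <- character()
  flag <- function(cond, field, why) {
    if (!isTRUE(cond)) errors <<- c(errors, sprintf("%s: %s", field, why))
  }
  for (f in names(cfg$thresholds))
    flag(is.numeric(cfg$thresholds[[f]]) && cfg$thresholds[[f]] > 0 &&
           cfg$thresholds[[f]] <= 1,
         paste0("thresholds.", f), "must lie in (0, 1]")
  for (f in names(cfg$n_perm))
    flag(is.numeric(cfg$n_perm[[f]]) && cfg$n_perm[[f]] >= 100,
         paste0("n_perm.", f), "must be at least 100")
  flag(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed", "must be an integer")
  flag(is.numeric(cfg$serum_k) && cfg$serum_k >= 1, "serum_k", "must be at least 1")
  flag(!is.null(cfg$outdir), "outdir", "output directory is required")
  if (!is.null(cfg$paths))
    for (f in names(cfg$paths))
      flag(file.exists(cfg$paths[[f]]), paste0("paths.", f), "file does not exist")
  list(config = cfg, errors = errors)
}

.needStage <- function(state, what, stage, from) {
  if (is.null(state[[what]]))
    stop(sprintf("stage '%s' requires the output of stage '%s'; include it in `stages`",
                 stage, from), call. = FALSE)
}

#' Run the cross-tissue crosstalk pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate, filter, de, enrich, index, network, overlap, serum) on a
#' synthetic cohort, writing all intermediate tables and a JSON run manifest
#' recording every parameter and an MD5 checksum per output file.
#' Re-running with an identical configuration and seed reproduces identical
#' checksums. Stage randomness is isolated by deriving one sub-seed per
#' stage from the global seed, so adding or removing a stage never perturbs
#' another stage's results.
#'
#' @param config raw or validated configuration
#'   (see \code{\link{validatePipelineConfig}}).
#' @param stages character subset of stages to run.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "filter", "de", "enrich",
                                   "index", "network", "overlap", "serum")) {
  all_stages <- c("simulate", "filter", "de", "enrich", "index", "network",
                  "overlap", "serum")
  .stopIfNot(all(stages %in% all_stages),
             sprintf("unknown stage: %s", paste(setdiff(stages, all_stages), collapse = ", ")))
  stages <- all_stages[all_stages %in% stages]
  if (!is.list(config) || is.null(config$config)) config <- validatePipelineConfig(config)
  if (length(config$errors))
    stop(paste(c("invalid pipeline configuration:", config$errors), collapse = "\n  "),
         call. = FALSE)
  cfg <- config$config
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  state <- new.env(parent = emptyenv())
  files <- character()
  emit <- function(path) files <<- c(files, path)
  rel <- function(p) file.path(outdir, p)

  if ("simulate" %in% stages) {
    acfg <- do.call(animalCohortConfig,
                    utils::modifyList(list(seed = deriveSeed(cfg$seed, "simulate_animal")),
                                      cfg$animal))
    state$animal <- generateAnimalCohort(acfg)
    hcfg <- do.call(humanCohortConfig,
                    utils::modifyList(list(seed = deriveSeed(cfg$seed, "simulate_human")),
                                      cfg$human))
    state$human <- generateHumanCohort(hcfg)
    dir.create(rel("synth"), showWarnings = FALSE)
    for (tis in names(state$animal$expression)) {
      emit(writeExpressionTsv(state$animal$expression[[tis]],
                              rel(file.path("synth", paste0("expr_", tis, ".tsv")))))
      fl <- state$animal$flags[[tis]]
      utils::write.table(data.frame(gene_id = rownames(fl), fl * 1L, check.names = FALSE),
                         rel(file.path("synth", paste0("flags_", tis, ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(rel(file.path("synth", paste0("flags_", tis, ".tsv"))))
    }
    utils::write.table(state$animal$design, rel("synth/design_animal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(rel("synth/design_animal.tsv"))
    emit(writeGmt(state$animal$collection, rel("synth/pathways.gmt")))
    writeLines(state$animal$catalog, rel("synth/cytokine_catalog.txt"))
    emit(rel("synth/cytokine_catalog.txt"))
    emit(writeTruthJson(state$animal$truth, rel("synth/truth_animal.json")))
    emit(writeSerumTsv(state$human$serum, rel("synth/serum.tsv")))
    emit(writeExpressionTsv(state$human$muscle, rel("synth/expr_human_muscle.tsv")))
    utils::write.table(state$human$design, rel("synth/design_human.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(rel("synth/design_human.tsv"))
  }

  if ("filter" %in% stages) {
    .needStage(state, "animal", "filter", "simulate")
    state$filtered <- lapply(names(state$animal$expression), function(tis) {
      keep <- filterByDetection(state$animal$flags[[tis]], 0.2)
      em <- state$animal$expression[[tis]]
      ExpressionMatrix(exprValues(em)[keep, , drop = FALSE], tissue = tissueOf(em))
    })
    names(state$filtered) <- names(state$animal$expression)
    tab <- data.frame(tissue = names(state$filtered),
                      retained = vapply(state$filtered, nrow, integer(1)))
    utils::write.table(tab, rel("filter_summary.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(rel("filter_summary.tsv"))
  }

  if ("de" %in% stages) {
    .needStage(state, "filtered", "de", "filter")
    design <- state$animal$design
    groups <- unique(design$group)
    sham <- groups[1]
    state$de <- list()
    dir.create(rel("de"), showWarnings = FALSE)
    for (tis in names(state$filtered)) {
      em <- state$filtered[[tis]]
      d_t <- design[design$tissue == tis, ]
      state$de[[tis]] <- list()
      for (ctr in setdiff(groups, sham)) {
        ids <- d_t$sample_id[d_t$group %in% c(ctr, sham)]
        labs <- factor(d_t$group[match(ids, d_t$sample_id)], levels = c(ctr, sham))
        res <- samTwoClass(exprValues(em)[, ids, drop = FALSE], labs,
                           n_perm = cfg$n_perm$de,
                           seed = deriveSeed(cfg$seed, paste("de", tis, ctr)))
        state$de[[tis]][[ctr]] <- res
        f <- rel(file.path("de", sprintf("de_%s_%s.tsv", tis, ctr)))
        utils::write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
        emit(f)
      }
    }
  }

  if ("enrich" %in% stages) {
    .needStage(state, "de", "enrich", "de")
    state$enrich <- list()
    dir.create(rel("enrich"), showWarnings = FALSE)
    muscles <- setdiff(names(state$filtered), names(state$filtered)[1])
    for (tis in muscles) {
      state$enrich[[tis]] <- list()
      universe <- rownames(exprValues(state$filtered[[tis]]))
      for (ctr in names(state$de[[tis]])) {
        calls <- selectDe(state$de[[tis]][[ctr]], th$de_fdr)
        tab <- enrichLists(calls$up, calls$down, state$animal$collection,
                           universe, p_cutoff = th$enrich_p,
                           categories = cfg$categories, keep_all = TRUE)
        state$enrich[[tis]][[ctr]] <- tab
        f <- rel(file.path("enrich", sprintf("enrich_%s_%s.tsv", tis, ctr)))
        utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
        emit(f)
      }
    }
  }

  if ("index" %in% stages) {
    .needStage(state, "enrich", "index", "enrich")
    state$indices <- list()
    dir.create(rel("index"), showWarnings = FALSE)
    for (tis in names(state$enrich)) {
      eligible <- unique(unlist(lapply(state$enrich[[tis]], eligiblePathways,
                                       fdr = th$index_eligibility)))
      if (!length(eligible)) {
        message(sprintf("index: no pathway passes eligibility in %s; indexing all pathways", tis))
        eligible <- names(geneSets(state$animal$collection))
      }
      idx <- pathwayIndices(state$filtered[[tis]], state$animal$collection,
                            sort(eligible))
      state$indices[[tis]] <- idx
      sc <- do.call(cbind, lapply(names(idx), function(p) {
        s <- indexScores(idx[[p]]); colnames(s) <- paste0(p, "::", colnames(s)); s
      }))
      f <- rel(file.path("index", sprintf("indices_%s.tsv", tis)))
      utils::write.table(data.frame(sample_id = rownames(sc), sc, check.names = FALSE),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f)
    }
  }

  if ("network" %in% stages) {
    .needStage(state, "indices", "network", "index")
    design <- state$animal$design
    lung <- names(state$filtered)[1]
    pair_lung <- setNames(design$animal_id[design$tissue == lung],
                          design$sample_id[design$tissue == lung])
    factors <- selectDeFactors(state$animal$catalog, state$de[[lung]],
                               q_cutoff = th$de_fdr, expr = state$filtered[[lung]],
                               pairing = pair_lung)
    state$network <- list()
    dir.create(rel("network"), showWarnings = FALSE)
    for (tis in names(state$indices)) {
      pair_mus <- setNames(design$animal_id[design$tissue == tis],
                           design$sample_id[design$tissue == tis])
      if (length(factors)) {
        net <- inferNetwork(factors, state$indices[[tis]], pairing = pair_mus,
                            n_perm = cfg$n_perm$network, alpha = th$edge_alpha,
                            seed = deriveSeed(cfg$seed, paste("network", tis)))
      } else {
        message(sprintf("network: no differentially expressed factors for %s; emitting empty network", tis))
        net <- new("CrosstalkNetwork",
                   edges = data.frame(factor_id = character(), pathway_id = character(),
                                      component = integer(), rho = numeric(),
                                      p_perm = numeric(), n_pairs = integer(),
                                      sign = character(), stringsAsFactors = FALSE),
                   factor_nodes = data.frame(factor_id = character()),
                   pathway_nodes = data.frame(pathway_id = character()),
                   alpha = th$edge_alpha)
      }
      state$network[[tis]] <- net
      emit(exportNetwork(net, rel(file.path("network", paste0("network_", tis)))))
    }
  }

  if ("overlap" %in% stages) {
    .needStage(state, "enrich", "overlap", "enrich")
    .needStage(state, "human", "overlap", "simulate")
    hm <- state$human
    hdesign <- hm$design
    ids <- hdesign$subject_id[hdesign$group %in% c("copd_low_ffmi", "control")]
    labs <- factor(hdesign$group[match(ids, hdesign$subject_id)],
                   levels = c("copd_low_ffmi", "control"))
    hres <- samTwoClass(exprValues(hm$muscle)[, ids, drop = FALSE], labs,
                        n_perm = cfg$n_perm$de,
                        seed = deriveSeed(cfg$seed, "de_human_muscle"))
    calls <- selectDe(hres, th$de_fdr)
    htab <- enrichLists(calls$up, calls$down, hm$collection,
                        rownames(exprValues(hm$muscle)), p_cutoff = th$enrich_p,
                        categories = cfg$categories, keep_all = TRUE)
    ref <- htab[htab$direction != "none", , drop = FALSE]
    dir.create(rel("overlap"), showWarnings = FALSE)
    reports <- NULL
    universe <- sort(intersect(htab$pathway_id,
                               unique(unlist(lapply(state$enrich,
                                                    function(e) e[[1]]$pathway_id)))))
    if (nrow(ref)) {
      truth_sig <- pathwaySignature(ref, condition = "human_reference")
      for (tis in names(state$enrich)) for (ctr in names(state$enrich[[tis]])) {
        tab <- state$enrich[[tis]][[ctr]]
        test_sig <- pathwaySignature(tab[tab$direction != "none", , drop = FALSE],
                                     condition = paste(tis, ctr))
        for (dir_flag in c(FALSE, TRUE)) {
          rep1 <- sensitivitySpecificity(test_sig, truth_sig, universe, directed = dir_flag)
          rep1$condition <- paste(tis, ctr, sep = "_")
          reports <- rbind(reports, rep1)
        }
      }
    }
    if (is.null(reports))
      reports <- data.frame(n_truth = integer(), n_test = integer(),
                            n_overlap = integer(), sensitivity = numeric(),
                            specificity = numeric(), p_overlap = numeric(),
                            directed = logical(), condition = character())
    utils::write.table(reports, rel("overlap/overlap_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(rel("overlap/overlap_report.tsv"))
    if (nrow(ref) >= 2) {
      jm <- jaccardMatrix(hm$collection, ref$pathway_id)
      hc <- averageLinkageCluster(jm)
      emit(writeDendrogramNewick(hc, rel("overlap/reference_pathways.nwk")))
    }
    state$overlap <- reports
  }

  if ("serum" %in% stages) {
    .needStage(state, "human", "serum", "simulate")
    hm <- state$human
    panel <- zscorePanel(knnImpute(hm$serum, k = min(cfg$serum_k,
                                                     nrow(panelValues(hm$serum)) - 1L)))
    dir.create(rel("serum"), showWarnings = FALSE)
    V <- panelValues(panel); des <- panelDesign(panel)
    ms <- do.call(rbind, lapply(rownames(V), function(a) {
      r <- mackSkillingsTwoFactor(V[a, ], des$group, des$training)
      r$analyte_id <- a
      r
    }))
    utils::write.table(ms, rel("serum/mack_skillings.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(rel("serum/mack_skillings.tsv"))
    sig_analytes <- unique(ms$analyte_id[ms$effect == "disease" & ms$p < th$serum_p])
    gsea_rows <- NULL
    for (a in sig_analytes) {
      ranking <- correlateSerumMuscle(setNames(V[a, ], colnames(V)), hm$muscle)
      f <- rel(file.path("serum", sprintf("ranking_%s.tsv", a)))
      utils::write.table(ranking, f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f)
      for (p in names(geneSets(hm$collection))) {
        g <- prerankedGsea(ranking$r |> setNames(ranking$gene_id),
                           geneSets(hm$collection)[[p]],
                           n_perm = cfg$n_perm$gsea,
                           seed = deriveSeed(cfg$seed, paste("gsea", a, p)),
                           set_id = p)
        gsea_rows <- rbind(gsea_rows,
                           data.frame(analyte_id = a, set_id = p, es = g$es,
                                      nes = g$nes, p = g$p,
                                      leading_edge = paste(g$leading_edge, collapse = ";"),
                                      stringsAsFactors = FALSE))
      }
    }
    if (is.null(gsea_rows))
      gsea_rows <- data.frame(analyte_id = character(), set_id = character(),
                              es = numeric(), nes = numeric(), p = numeric(),
                              leading_edge = character(), stringsAsFactors = FALSE)
    utils::write.table(gsea_rows, rel("serum/gsea.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(rel("serum/gsea.tsv"))
    state$serum <- list(tests = ms, gsea = gsea_rows)
  }

  manifest <- list(
    parameters = cfg[setdiff(names(cfg), "outdir")],
    stages = stages,
    files = {
      # all paths were built under outdir; strip that prefix for portability
      relfiles <- substring(files, nchar(outdir) + 2L)
      sums <- unname(tools::md5sum(files))
      setNames(as.list(sums), relfiles)
    }
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(state = state)))
}
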