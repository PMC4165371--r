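test_that("animal cohort reproduces the study layout: 45 samples after losing one per tissue", {
  co <- generateAnimalCohort(quick_animal_cfg(seed = 4))
  expect_equal(sum(vapply(co$expression, ncol, integer(1))), 45L)
  # at most one sample dropped per tissue
  expect_true(all(vapply(co$expression, ncol, integer(1)) >= 15L))
  expect_setequal(unique(co$design$group), c("SHAM", "CS", "CH", "CSCH"))
  expect_equal(nrow(co$design), 45L)
  # every animal present in every tissue except the dropouts
  tab <- table(co$design$animal_id)
  expect_true(all(tab >= 2) && sum(3 - tab) == 3)
})

test_that("null configuration yields empty ground truth", {
  co <- generateAnimalCohort(quick_animal_cfg(seed = 2, de_fraction = 0,
                                              n_planted_edges = 0L))
  expect_equal(nrow(co$truth$planted_edges), 0L)
  for (tis in names(co$truth$de_genes)) for (ctr in names(co$truth$de_genes[[tis]])) {
    expect_length(co$truth$de_genes[[tis]][[ctr]]$up, 0)
    expect_length(co$truth$de_genes[[tis]][[ctr]]$down, 0)
  }
})

test_that("planted couplings reach the target Spearman correlation in the emitted data", {
  co <- generateAnimalCohort(animalCohortConfig(seed = 1, noise_sd = 0.05,
                                                de_fraction = 0))
  lung <- exprValues(co$expression$lung)
  la <- sub(".*_", "", colnames(lung))
  for (tis in c("soleus", "gastrocnemius")) {
    mus <- exprValues(co$expression[[tis]])
    ma <- sub(".*_", "", colnames(mus))
    common <- intersect(la, ma)
    for (i in seq_len(nrow(co$truth$planted_edges))) {
      f <- co$truth$planted_edges$factor_id[i]
      p <- co$truth$planted_edges$pathway_id[i]
      rho <- cor(lung[f, match(common, la)],
                 colMeans(mus[co$truth$pathway_membership[[p]], match(common, ma)]),
                 method = "spearman")
      expect_lt(abs(rho - 0.9), 0.15)
    }
  }
})

test_that("baseline genes are independent noise around a gene-specific mean", {
  co <- generateAnimalCohort(quick_animal_cfg(seed = 9, de_fraction = 0,
                                              n_planted_edges = 0L))
  X <- exprValues(co$expression$lung)
  outside <- setdiff(rownames(X),
                     c(unlist(co$truth$pathway_membership), co$catalog,
                       co$truth$undetected_genes))
  sub <- X[sample(outside, 50), ]
  # row SDs close to noise_sd, and cross-gene correlations centred on zero
  expect_lt(abs(mean(apply(sub, 1, sd)) - 0.25), 0.05)
  cors <- cor(t(sub))
  expect_lt(abs(mean(cors[upper.tri(cors)])), 0.05)
})

test_that("generation is deterministic: identical config and seed give identical output", {
  a <- generateAnimalCohort(quick_animal_cfg(seed = 5))
  b <- generateAnimalCohort(quick_animal_cfg(seed = 5))
  expect_identical(lapply(a$expression, exprValues), lapply(b$expression, exprValues))
  expect_identical(a$truth, b$truth)
  expect_identical(a$design, b$design)
  h1 <- generateHumanCohort(humanCohortConfig(seed = 5, n_genes = 400))
  h2 <- generateHumanCohort(humanCohortConfig(seed = 5, n_genes = 400))
  expect_identical(panelValues(h1$serum), panelValues(h2$serum))
})

test_that("invalid configurations name the offending field", {
  expect_error(animalCohortConfig(de_fraction = 1.5), "de_fraction")
  expect_error(animalCohortConfig(planted_rho = 2), "planted_rho")
  expect_error(animalCohortConfig(dropout = 7), "dropout")
  expect_error(animalCohortConfig(noise_sd = 0), "noise_sd")
  expect_error(humanCohortConfig(missing_fraction = 1), "missing_fraction")
  expect_error(humanCohortConfig(n_modulated_analytes = 99), "n_modulated_analytes")
})

test_that("pathway collections respect size bounds, disjointness and the overlap rule", {
  universe <- sprintf("g%04d", 1:2000)
  pc <- generatePathwayCollection(19, c(10, 50), universe, 0, seed = 3)
  expect_length(geneSets(pc), 19)
  expect_true(all(lengths(geneSets(pc)) >= 10 & lengths(geneSets(pc)) <= 50))
  # overlap_fraction = 0: pairwise disjoint
  sets <- geneSets(pc)
  for (i in 1:5) for (j in seq_len(i - 1))
    expect_length(intersect(sets[[i]], sets[[j]]), 0)
  expect_error(generatePathwayCollection(3, c(10, 50), universe[1:20], 0, seed = 1),
               "size_range")

  # overlap rule oracle: two size-20 pathways at overlap 0.5 share exactly
  # round(0.5 * 20) = 10 genes, so Jaccard = 10 / 30 under the sampling rule
  expected_j <- 10 / 30
  jacc <- vapply(1:100, function(s) {
    p2 <- geneSets(generatePathwayCollection(2, c(20, 20), universe, 0.5, seed = s))
    length(intersect(p2[[1]], p2[[2]])) / length(union(p2[[1]], p2[[2]]))
  }, numeric(1))
  expect_lt(abs(mean(jacc) - expected_j), 0.1)
})

test_that("human cohort matches the clinical arm: 49 subjects, MCAR missingness, couplings", {
  hc <- generateHumanCohort(humanCohortConfig(seed = 2, n_genes = 800,
                                              missing_fraction = 0))
  expect_equal(ncol(panelValues(hc$serum)), 49L)
  expect_false(anyNA(panelValues(hc$serum)))
  hc2 <- generateHumanCohort(humanCohortConfig(seed = 2, n_genes = 800,
                                               missing_fraction = 0.1))
  expect_lt(abs(mean(is.na(panelValues(hc2$serum))) - 0.1), 0.06)

  # coupled analyte/pathway pairs reach the target Pearson r
  V <- panelValues(hc$serum); M <- exprValues(hc$muscle)
  for (i in seq_len(nrow(hc$truth$coupling))) {
    a <- hc$truth$coupling$analyte_id[i]
    p <- hc$truth$coupling$pathway_id[i]
    r <- cor(V[a, ], colMeans(M[hc$truth$pathway_membership[[p]], ]))
    expect_lt(abs(r - hc$truth$coupling$r[i]), 0.15)
  }
})

test_that("cohort TSV/GMT/JSON exports round-trip", {
  co <- generateAnimalCohort(quick_animal_cfg(seed = 6))
  tmp <- withr::local_tempdir()
  f <- writeExpressionTsv(co$expression$soleus, file.path(tmp, "sol.tsv"))
  back <- readExpressionTsv(f, tissue = "soleus")
  expect_equal(exprValues(back), exprValues(co$expression$soleus))
  g <- writeGmt(co$collection, file.path(tmp, "sets.gmt"))
  cc <- readGmt(g)
  expect_identical(geneSets(cc), geneSets(co$collection))
  expect_identical(setCategories(cc), setCategories(co$collection))
  writeTruthJson(co$truth, file.path(tmp, "truth.json"))
  tj <- jsonlite::read_json(file.path(tmp, "truth.json"))
  expect_setequal(unlist(tj$pathway_membership$P01),
                  co$truth$pathway_membership$P01)
})
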