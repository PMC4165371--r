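test_that("sensitivity arithmetic matches the reference worked examples", {
  universe <- sprintf("P%03d", 1:100)
  truth <- pathwaySignature(universe[1:19])
  # perfect agreement
  perfect <- sensitivitySpecificity(truth, truth, universe)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  # 13 of 19 recovered -> 68% rounded; 10 of 19 -> 53%
  t13 <- pathwaySignature(c(universe[1:13], universe[30:35]))
  r13 <- sensitivitySpecificity(t13, truth, universe)
  expect_equal(r13$n_overlap, 13L)
  expect_equal(round(100 * r13$sensitivity), 68)
  t10 <- pathwaySignature(c(universe[1:10], universe[30:35]))
  r10 <- sensitivitySpecificity(t10, truth, universe)
  expect_equal(round(100 * r10$sensitivity), 53)
  expect_error(sensitivitySpecificity(t13, pathwaySignature(character()), universe),
               "non-empty")
})

test_that("directed overlap requires compatible directions with 'both' as wildcard", {
  universe <- sprintf("P%02d", 1:30)
  truth <- pathwaySignature(universe[1:4], c("up", "down", "both", "up"))
  test <- pathwaySignature(universe[1:4], c("up", "up", "down", "both"))
  und <- sensitivitySpecificity(test, truth, universe, directed = FALSE)
  dir <- sensitivitySpecificity(test, truth, universe, directed = TRUE)
  expect_equal(und$n_overlap, 4L)
  # P01 equal, P02 incompatible, P03 truth-both wildcard, P04 test-both wildcard
  expect_equal(dir$n_overlap, 3L)
  expect_lte(dir$sensitivity, und$sensitivity)
})

test_that("overlap significance equals direct hypergeometric summation", {
  expect_equal(overlapSignificance(13, 13, 19, 150),
               oracle_hyper_upper(13, 13, 19, 150), tolerance = 1e-12)
  expect_equal(overlapSignificance(0, 5, 10, 50), 1)
  expect_equal(overlapSignificance(10, 10, 10, 10), 1)
  # non-increasing in n_overlap at fixed margins
  ps <- vapply(0:10, overlapSignificance, numeric(1), n_test = 10, n_truth = 19,
               n_universe = 150)
  expect_true(all(diff(ps) <= 1e-15))
  expect_error(overlapSignificance(10, 5, 19, 150), "inconsistent")
})

test_that("Jaccard matrix follows set arithmetic and ignores gene labels", {
  pc <- PathwayCollection(list(A = c("a", "b", "c", "d"), B = c("c", "d", "e"),
                               C = c("x", "y")))
  jm <- jaccardMatrix(pc)
  expect_equal(jm["A", "B"], 2 / 5)
  expect_equal(jm["A", "C"], 0)
  expect_equal(diag(jm), c(A = 1, B = 1, C = 1))
  expect_equal(jm, t(jm))
  # relabeling genes consistently leaves the matrix unchanged
  relab <- setNames(sprintf("z%02d", 1:5), c("a", "b", "c", "d", "e"))
  pc2 <- PathwayCollection(list(A = relab[c("a", "b", "c", "d")],
                                B = relab[c("c", "d", "e")], C = c("x", "y")))
  expect_equal(unname(jaccardMatrix(pc2)), unname(jm))
})

test_that("average-linkage clustering matches hand calculations and a naive oracle", {
  # two identical items merge at height 0
  s2 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- averageLinkageCluster(s2)
  expect_equal(hc2$height, 0)
  # three items, distances 0.1, 0.9, 0.9: first merge the 0.1 pair, then 0.9
  s3 <- 1 - rbind(c(0, 0.1, 0.9), c(0.1, 0, 0.9), c(0.9, 0.9, 0))
  dimnames(s3) <- list(c("x", "y", "z"), c("x", "y", "z"))
  hc3 <- averageLinkageCluster(s3)
  expect_equal(hc3$height, c(0.1, 0.9))
  expect_setequal(hc3$merge[1, ], c(-1, -2))

  # random 8x8 similarity vs naive O(n^3) agglomeration (cophenetic equality)
  set.seed(12)
  m <- matrix(runif(64, 0, 0.95), 8); m <- (m + t(m)) / 2; diag(m) <- 1
  dimnames(m) <- list(letters[1:8], letters[1:8])
  hc <- averageLinkageCluster(m)
  expect_true(all(diff(hc$height) >= -1e-12))
  coph <- as.matrix(cophenetic(hc))[letters[1:8], letters[1:8]]
  oracle <- oracle_upgma_cophenetic(1 - m)
  dimnames(oracle) <- dimnames(coph)
  expect_equal(coph, oracle, tolerance = 1e-10)

  expect_error(averageLinkageCluster(matrix(runif(12), 3, 4)), "square")
  bad <- m; bad[1, 2] <- bad[1, 2] + 0.5
  expect_error(averageLinkageCluster(bad), "symmetric")
})

test_that("dendrograms and signatures survive a text round-trip", {
  tmp <- withr::local_tempdir()
  set.seed(2)
  m <- matrix(runif(25, 0, 0.9), 5); m <- (m + t(m)) / 2; diag(m) <- 1
  dimnames(m) <- list(paste0("P", 1:5), paste0("P", 1:5))
  hc <- averageLinkageCluster(m)
  writeDendrogramNewick(hc, file.path(tmp, "dend.nwk"))
  tree <- ape::read.tree(file.path(tmp, "dend.nwk"))
  expect_setequal(tree$tip.label, paste0("P", 1:5))

  sig <- pathwaySignature(paste0("P", 1:4), c("up", "down", "both", "up"))
  writeSignatureTsv(sig, file.path(tmp, "sig.tsv"))
  back <- readSignatureTsv(file.path(tmp, "sig.tsv"))
  expect_equal(unclass(back)[names(sig)], unclass(sig)[names(sig)],
               ignore_attr = TRUE)
})
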