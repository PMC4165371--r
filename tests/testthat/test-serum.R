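mk_panel <- function(values, groups = NULL, training = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%02d", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- sprintf("ANL%02d", seq_len(nrow(values)))
  SerumPanel(values, data.frame(
    subject_id = colnames(values),
    group = if (is.null(groups)) rep(c("control", "copd"), length.out = n) else groups,
    training = if (is.null(training)) rep(c("T1", "T2"), length.out = n) else training,
    stringsAsFactors = FALSE))
}

test_that("KNN imputation is exact for duplicates, inert for complete data, and matches a naive oracle", {
  set.seed(61)
  V <- matrix(rnorm(12 * 20), 12, 20,
              dimnames = list(sprintf("ANL%02d", 1:12), sprintf("S%02d", 1:20)))
  p0 <- mk_panel(V)
  expect_identical(panelValues(knnImpute(p0, k = 3)), panelValues(p0))

  # one missing cell, k = 1, exact duplicate analyte present
  V1 <- V; V1[2, ] <- V1[1, ]; V1[1, 5] <- NA
  imp <- knnImpute(mk_panel(V1), k = 1)
  expect_equal(panelValues(imp)[1, 5], V1[2, 5])

  # random 10% missingness vs per-cell brute-force recomputation
  V2 <- V; V2[runif(length(V2)) < 0.1] <- NA
  panel <- mk_panel(V2)
  got <- panelValues(knnImpute(panel, k = 3))
  for (cell in which(is.na(V2))) {
    a <- (cell - 1) %% nrow(V2) + 1; s <- (cell - 1) %/% nrow(V2) + 1
    cand <- setdiff(which(!is.na(V2[, s])), a)
    d <- sapply(cand, function(b) {
      joint <- !is.na(V2[a, ]) & !is.na(V2[b, ])
      sqrt(mean((V2[a, joint] - V2[b, joint])^2))
    })
    nn <- cand[order(d, rownames(V2)[cand])][1:3]
    expect_equal(got[a, s], mean(V2[nn, s]), tolerance = 1e-12)
  }
  # untouched cells unchanged
  expect_identical(got[!is.na(V2)], V2[!is.na(V2)])

  V3 <- V; V3[4, ] <- NA
  expect_error(knnImpute(mk_panel(V3), k = 2), "ANL04")
})

test_that("Z-scoring uses the sample-SD convention and is shift-invariant", {
  V <- rbind(a = c(2, 4, 6), b = c(10, 20, 15))
  z <- panelValues(zscorePanel(mk_panel(V, groups = rep("g", 3))))
  expect_equal(unname(z["a", ]), c(-1, 0, 1))   # SD of (2,4,6) is exactly 2
  shifted <- V; shifted["b", ] <- shifted["b", ] + 100
  z2 <- panelValues(zscorePanel(mk_panel(shifted, groups = rep("g", 3))))
  expect_equal(z2["b", ], z["b", ])
  set.seed(3)
  big <- matrix(rnorm(8 * 30), 8, 30)
  zb <- panelValues(zscorePanel(mk_panel(big)))
  expect_true(all(abs(rowMeans(zb)) < 1e-12))
  expect_true(all(abs(apply(zb, 1, sd) - 1) < 1e-12))
  const <- rbind(a = rep(5, 6), b = rnorm(6))
  expect_error(zscorePanel(mk_panel(const)), "'a'")
})

test_that("Mack-Skillings is null for constant data and reduces to Friedman with one replicate", {
  r0 <- mackSkillings(rep(3.3, 12), gl(2, 6), rep(gl(3, 2), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  set.seed(5)
  for (i in 1:5) {
    v <- rnorm(15); tr <- gl(3, 1, 15); bl <- gl(5, 3)
    ms <- mackSkillings(v, tr, bl)
    fr <- friedman.test(v, tr, bl)
    expect_equal(ms$statistic, unname(fr$statistic), tolerance = 1e-10)
    expect_equal(ms$df, unname(fr$parameter))
    expect_equal(ms$p, unname(fr$p.value), tolerance = 1e-10)
  }

  expect_error(mackSkillings(rnorm(6), factor(c(1, 1, 1, 2, 2, 2)),
                             factor(c(1, 1, 2, 2, 2, 2))), "absent")
  # drop-block policy removes the incomplete block instead
  r <- mackSkillings(rnorm(10), factor(c(1, 1, 1, 2, 2, 1, 1, 2, 2, 2)),
                     factor(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)),
                     incomplete = "drop")
  expect_true(is.finite(r$p))
})

test_that("chi-square p is bracketed by the exact within-block permutation tail", {
  stat_fun <- function(v, tr, bl) mackSkillings(v, tr, bl)$statistic
  set.seed(2)
  for (i in 1:8) {
    vals <- rnorm(8); tr <- gl(2, 1, 8); bl <- gl(2, 4)
    p <- mackSkillings(vals, tr, bl)$p
    e <- oracle_ms_exact(vals, tr, bl, stat_fun)
    expect_gte(p, e["gt"] - 1e-9)
    expect_lte(p, e["ge"] + 1e-9)
  }
})

test_that("two-factor wrapper reports both main effects and subject order is irrelevant", {
  set.seed(33)
  n <- 40
  g <- sample(rep(c("control", "copd"), each = n / 2))
  tr <- sample(rep(c("T1", "T2"), n / 2))
  v <- rnorm(n) + 2 * (g == "copd")
  both <- mackSkillingsTwoFactor(v, g, tr)
  expect_setequal(both$effect, c("disease", "training"))
  expect_lt(both$p[both$effect == "disease"], 0.01)
  perm <- sample(n)
  both2 <- mackSkillingsTwoFactor(v[perm], g[perm], tr[perm])
  expect_equal(both2$statistic, both$statistic, tolerance = 1e-10)
})

test_that("serum-muscle correlation ranking is exact and deterministic", {
  set.seed(9)
  M <- matrix(rnorm(500 * 12), 500, 12,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("S%02d", 1:12)))
  a <- setNames(M["g100", ], colnames(M))
  M["g200", ] <- -M["g100", ]
  rk <- correlateSerumMuscle(a, ExpressionMatrix(M, tissue = "muscle"))
  expect_equal(rk$gene_id[1], "g100"); expect_equal(rk$r[1], 1)
  expect_equal(rk$gene_id[nrow(rk)], "g200"); expect_equal(rk$r[nrow(rk)], -1)
  # naive covariance-formula oracle
  r_oracle <- apply(M, 1, function(g)
    sum((g - mean(g)) * (a - mean(a))) /
      sqrt(sum((g - mean(g))^2) * sum((a - mean(a))^2)))
  expect_equal(rk$r, unname(r_oracle[rk$gene_id]), tolerance = 1e-10)
  expect_error(correlateSerumMuscle(a[1:3], ExpressionMatrix(M)), "misaligned")
})

test_that("GSEA enrichment score equals a position-by-position hand-computed walk", {
  set.seed(41)
  scores <- sort(rnorm(10), decreasing = TRUE)
  rk <- data.frame(gene_id = sprintf("g%02d", 1:10), score = scores)
  for (members in list(c(1, 2, 3), c(1, 5, 9), c(7, 8, 10), c(2, 4, 6, 8))) {
    for (w in c(0, 1)) {
      g <- prerankedGsea(rk, rk$gene_id[members], n_perm = 100,
                         weight_exponent = w, seed = 1)
      es_oracle <- oracle_gsea_walk(scores, seq_len(10) %in% members, w)
      expect_equal(g$es, es_oracle, tolerance = 1e-12)
      expect_lte(abs(g$es), 1)
      expect_true(all(g$leading_edge %in% rk$gene_id[members]))
    }
  }
})

test_that("GSEA is antisymmetric under ranking reversal and rescale-invariant at weight 0", {
  set.seed(15)
  rk <- data.frame(gene_id = sprintf("g%03d", 1:200), score = rnorm(200))
  gs <- sample(rk$gene_id, 15)
  g1 <- prerankedGsea(rk, gs, n_perm = 200, weight_exponent = 0, seed = 3)
  rev_rk <- rk; rev_rk$score <- -rev_rk$score
  g2 <- prerankedGsea(rev_rk, gs, n_perm = 200, weight_exponent = 0, seed = 3)
  expect_equal(g2$es, -g1$es, tolerance = 1e-10)
  # strictly increasing transform of scores leaves the unweighted ES unchanged
  mono <- rk; mono$score <- rk$score^3 + 5 * rk$score
  g3 <- prerankedGsea(mono, gs, n_perm = 200, weight_exponent = 0, seed = 3)
  expect_equal(g3$es, g1$es, tolerance = 1e-12)
})

test_that("weighted ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(27)
  stats <- sort(setNames(rnorm(80), sprintf("g%02d", 1:80)), decreasing = TRUE)
  gs <- sample(names(stats), 12)
  ours <- prerankedGsea(stats, gs, n_perm = 200, weight_exponent = 1, seed = 1)
  theirs <- suppressWarnings(
    fgsea::calcGseaStat(stats, selectedStats = match(gs, names(stats)),
                        gseaParam = 1))
  expect_equal(ours$es, theirs, tolerance = 1e-6)
})

test_that("comparative Ct quantification follows the 2^-ddCt rule", {
  expect_equal(deltaDeltaCt(20, 20, 20, 20), 1)
  expect_equal(deltaDeltaCt(19, 15, 20, 15), 2)   # ddCt = -1 doubles
  expect_equal(deltaDeltaCt(22, 15, 24, 15), 4)
  expect_error(deltaDeltaCt(NA, 15, 24, 15), "finite")
})

test_that("pipeline order impute -> z-score -> test is invariant to subject order", {
  hc <- generateHumanCohort(humanCohortConfig(seed = 8, n_genes = 400,
                                              n_analytes = 10,
                                              missing_fraction = 0.08))
  p1 <- zscorePanel(knnImpute(hc$serum, k = 4))
  perm <- sample(ncol(panelValues(hc$serum)))
  shuffled <- SerumPanel(panelValues(hc$serum)[, perm],
                         panelDesign(hc$serum)[perm, ])
  p2 <- zscorePanel(knnImpute(shuffled, k = 4))
  expect_equal(panelValues(p2), panelValues(p1)[, perm], tolerance = 1e-12)
  a <- panelValues(p1)[1, ]; d <- panelDesign(p1)
  r1 <- mackSkillingsTwoFactor(a, d$group, d$training)
  r2 <- mackSkillingsTwoFactor(a[perm], d$group[perm], d$training[perm])
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
})
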