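# Independent brute-force oracles used across test files. These deliberately
# re-derive every quantity with naive loops / direct summation rather than
# calling package internals.

# all permutations of 1..n, one per row (naive recursion)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# upper-tail hypergeometric P(X >= k_min) by direct mass summation
# (log-scale binomial coefficients so large tables stay finite)
oracle_hyper_upper <- function(k_min, n_draw, K, N) {
  if (k_min <= 0) return(1)
  ks <- k_min:min(n_draw, K)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n_draw - ks) - lchoose(N, n_draw)))
}

# SAM d and s recomputed gene-by-gene with plain loops
oracle_sam_d <- function(X, cls1, s0) {
  n1 <- sum(cls1); n2 <- sum(!cls1)
  t(vapply(seq_len(nrow(X)), function(i) {
    a <- X[i, cls1]; b <- X[i, !cls1]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
    d <- (mean(a) - mean(b)) / (s + s0)
    if (!is.finite(d)) d <- 0
    c(d = d, s = s)
  }, c(d = 0, s = 0)))
}

# exhaustive-permutation SAM q-values (median exceedance ratio, monotonized)
oracle_sam_q <- function(X, labels, s0_quantile = 0.05) {
  labels <- factor(labels)
  cls1 <- labels == levels(labels)[1]
  n1 <- sum(cls1)
  base <- oracle_sam_d(X, cls1, s0 = 0)
  s0 <- unname(quantile(base[, "s"], s0_quantile))
  d_obs <- oracle_sam_d(X, cls1, s0)[, "d"]
  arrangements <- combn(length(labels), n1)
  d_perm <- sapply(seq_len(ncol(arrangements)), function(b) {
    w <- rep(FALSE, length(labels)); w[arrangements[, b]] <- TRUE
    oracle_sam_d(X, w, s0)[, "d"]
  })
  q <- vapply(seq_along(d_obs), function(i) {
    thr <- abs(d_obs[i])
    exceed_b <- vapply(seq_len(ncol(d_perm)),
                       function(b) sum(abs(d_perm[, b]) >= thr - 1e-12), numeric(1))
    min(1, median(exceed_b) / sum(abs(d_obs) >= thr - 1e-12))
  }, numeric(1))
  ord <- order(abs(d_obs), decreasing = TRUE)
  q_sorted <- rev(cummin(rev(q[ord])))
  out <- numeric(length(q)); out[ord] <- q_sorted
  out
}

# naive O(n^3) UPGMA returning the cophenetic distance matrix
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  dist_cl <- function(a, b) mean(D[clusters[[a]], clusters[[b]]])
  while (sum(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    ia <- which(active)
    for (x in seq_along(ia)) for (y in seq_len(x - 1)) {
      dd <- dist_cl(ia[x], ia[y])
      if (dd < bestd) { bestd <- dd; best <- c(ia[x], ia[y]) }
    }
    for (i in clusters[[best[1]]]) for (j in clusters[[best[2]]])
      coph[i, j] <- coph[j, i] <- bestd
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active[best[2]] <- FALSE
  }
  coph
}

# position-by-position GSEA running sum (hit += |s|^w / sum, miss -= 1/(N-m))
oracle_gsea_walk <- function(scores, is_member, weight) {
  N <- length(scores); m <- sum(is_member)
  w <- abs(scores)^weight
  denom <- sum(w[is_member])
  walk <- numeric(N); cur <- 0
  for (i in seq_len(N)) {
    cur <- if (is_member[i]) cur + (if (denom > 0) w[i] / denom else 1 / m)
           else cur - 1 / (N - m)
    walk[i] <- cur
  }
  walk[which.max(abs(walk))]
}

# exhaustive within-block permutation tail probabilities for the
# Mack-Skillings statistic in a 2-treatment x 2-block x 2-replicate layout
oracle_ms_exact <- function(vals, tr, bl, stat_fun) {
  obs <- stat_fun(vals, tr, bl)
  combs <- combn(4, 2)
  stats <- numeric(0)
  for (i in 1:6) for (j in 1:6) {
    t1 <- rep(levels(tr)[2], 4); t1[combs[, i]] <- levels(tr)[1]
    t2 <- rep(levels(tr)[2], 4); t2[combs[, j]] <- levels(tr)[1]
    newtr <- as.character(tr)
    newtr[bl == levels(bl)[1]] <- t1
    newtr[bl == levels(bl)[2]] <- t2
    stats <- c(stats, stat_fun(vals, factor(newtr, levels = levels(tr)), bl))
  }
  c(ge = mean(stats >= obs - 1e-9), gt = mean(stats > obs + 1e-9))
}

# shared small-cohort generator settings used by several test files
quick_animal_cfg <- function(seed, ...) {
  animalCohortConfig(n_genes = 800L, n_pathways = 10L,
                     pathway_size_range = c(10L, 30L), n_cytokines = 10L,
                     seed = seed, ...)
}

# animal-id pairing helpers for network tests
design_pairing <- function(design, tissue) {
  d <- design[design$tissue == tissue, ]
  setNames(d$animal_id, d$sample_id)
}

cytokine_factors <- function(cohort, conditions = c("CS", "CH", "CSCH")) {
  lung <- exprValues(cohort$expression[[1]])
  pairing <- design_pairing(cohort$design, cohort$design$tissue[1])
  lapply(setNames(cohort$catalog, cohort$catalog), function(g) {
    list(gene_id = g,
         values = setNames(lung[g, ], unname(pairing[colnames(lung)])),
         de_status = setNames(rep("null", length(conditions)), conditions))
  })
}
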