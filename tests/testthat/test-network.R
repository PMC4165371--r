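test_that("Spearman permutation test is monotone-invariant and flags constants", {
  set.seed(19)
  x <- rnorm(8)
  sp <- spearmanPerm(x, exp(x), n_perm = 2000, seed = 1)
  expect_equal(sp$rho, 1)
  sp2 <- spearmanPerm(x, -x^3, n_perm = 2000, seed = 1)
  expect_equal(sp2$rho, -1)
  const <- spearmanPerm(rep(1, 8), rnorm(8), n_perm = 2000, seed = 1)
  expect_false(const$ok)
  expect_true(is.na(const$rho))
})

test_that("n = 6 p-values match exhaustive enumeration over all 720 orderings", {
  set.seed(4)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    sp <- spearmanPerm(x, y, n_perm = 1000, seed = 1)
    expect_true(sp$exhaustive)
    # independent brute force: every ordering of y against fixed x
    P <- oracle_perms(6)
    rho_obs <- cor(x, y, method = "spearman")
    rho_all <- apply(P, 1, function(idx) cor(x, y[idx], method = "spearman"))
    expect_equal(sp$rho, rho_obs, tolerance = 1e-12)
    expect_equal(sp$p, mean(abs(rho_all) >= abs(rho_obs) - 1e-12), tolerance = 1e-12)
  }
})

test_that("network inference respects alpha, ordering and factor duplication", {
  co <- generateAnimalCohort(quick_animal_cfg(seed = 7, noise_sd = 0.05,
                                              de_fraction = 0, n_planted_edges = 3L))
  idx <- pathwayIndices(co$expression$soleus, co$collection)
  pairing <- design_pairing(co$design, "soleus")
  factors <- cytokine_factors(co)
  net <- inferNetwork(factors, idx, pairing = pairing, n_perm = 500,
                      alpha = 0.01, seed = 2)
  expect_true(all(networkEdges(net)$p_perm < 0.01))
  expect_true(all(networkEdges(net)$sign == ifelse(networkEdges(net)$rho >= 0, "+", "-")))

  # alpha = 0 is unsatisfiable -> empty edge list
  net0 <- inferNetwork(factors, idx, pairing = pairing, n_perm = 500,
                       alpha = 1e-12, seed = 2)
  expect_equal(nrow(networkEdges(net0)), 0L)

  # factor order never changes the edge set (per-test derived sub-seeds)
  net_rev <- inferNetwork(rev(factors), idx, pairing = pairing, n_perm = 500,
                          alpha = 0.01, seed = 2)
  e1 <- networkEdges(net); e2 <- networkEdges(net_rev)
  key <- function(e) sort(paste(e$factor_id, e$pathway_id, e$component, e$rho))
  expect_identical(key(e1), key(e2))

  # a duplicated factor inherits exactly the duplicate's edges
  f2 <- factors
  f2[["DUPL"]] <- f2[[1]]; f2[["DUPL"]]$gene_id <- "DUPL"
  net_d <- inferNetwork(f2, idx, pairing = pairing, n_perm = 500,
                        alpha = 0.01, seed = 2)
  ed <- networkEdges(net_d)
  orig <- ed[ed$factor_id == names(factors)[1], c("pathway_id", "component", "rho")]
  dup <- ed[ed$factor_id == "DUPL", c("pathway_id", "component", "rho")]
  rownames(orig) <- rownames(dup) <- NULL
  expect_equal(dup, orig)

  # a monotone transform of every profile changes no edge
  f3 <- lapply(factors, function(fp) { fp$values <- exp(fp$values / 2); fp })
  net_m <- inferNetwork(f3, idx, pairing = pairing, n_perm = 500,
                        alpha = 0.01, seed = 2)
  expect_identical(key(networkEdges(net_m)), key(e1))
})

test_that("factor selection equals a brute-force q-value scan and reproduces the 33-of-72 count", {
  conditions <- c("CS", "CH", "CSCH")
  catalog <- sprintf("CYT%02d", 1:72)
  set.seed(55)
  de_results <- lapply(setNames(conditions, conditions), function(cn) {
    data.frame(gene_id = catalog,
               d = rnorm(72),
               q_value = runif(72),
               stringsAsFactors = FALSE)
  })
  # force exactly 33 catalogue genes significant somewhere
  for (cn in conditions) de_results[[cn]]$q_value <- pmax(de_results[[cn]]$q_value, 0.02)
  sig <- sample(catalog, 33)
  slot_cond <- sample(conditions, 33, replace = TRUE)
  for (i in seq_along(sig))
    de_results[[slot_cond[i]]]$q_value[de_results[[slot_cond[i]]]$gene_id == sig[i]] <- 0.001
  profs <- selectDeFactors(catalog, de_results, q_cutoff = 0.01)
  expect_length(profs, 33)
  expect_setequal(names(profs), sig)
  # brute-force scan oracle
  brute <- catalog[vapply(catalog, function(g) {
    any(vapply(de_results, function(res)
      res$q_value[res$gene_id == g] <= 0.01 && res$d[res$gene_id == g] != 0,
      logical(1)))
  }, logical(1))]
  expect_setequal(names(profs), brute)
  # de_status matches the sign of d in the condition where the gene is called
  g1 <- sig[1]; cn <- slot_cond[1]
  expected <- if (de_results[[cn]]$d[de_results[[cn]]$gene_id == g1] > 0) "up" else "down"
  expect_equal(unname(profs[[g1]]$de_status[cn]), expected)

  # no gene significant anywhere -> empty list
  none <- lapply(de_results, function(res) { res$q_value[] <- 1; res })
  expect_length(selectDeFactors(catalog, none, q_cutoff = 0.01), 0)
})

test_that("network export round-trips through SIF and GraphML", {
  tmp <- withr::local_tempdir()
  mk_edges <- function(n, factors, pathways) {
    set.seed(101)
    e <- data.frame(factor_id = sample(factors, n, replace = TRUE),
                    pathway_id = sample(pathways, n, replace = TRUE),
                    component = sample(1:3, n, replace = TRUE),
                    stringsAsFactors = FALSE)
    e <- e[!duplicated(e), ]
    e$rho <- runif(nrow(e), -1, 1)
    e$p_perm <- runif(nrow(e), 0, 0.009)
    e$sign <- ifelse(e$rho >= 0, "+", "-")
    e
  }
  e <- mk_edges(50, sprintf("CYT%02d", 1:8), sprintf("P%02d", 1:6))
  net <- new("CrosstalkNetwork", edges = e,
             factor_nodes = data.frame(factor_id = sprintf("CYT%02d", 1:8)),
             pathway_nodes = data.frame(pathway_id = sprintf("P%02d", 1:6)),
             alpha = 0.01)
  files <- exportNetwork(net, file.path(tmp, "net"))
  sif <- readLines(file.path(tmp, "net.sif"))
  expect_length(sif, nrow(e))
  expect_true(all(grepl("\tcorr[+-]\t", sif)))

  back <- importNetworkGraphml(file.path(tmp, "net.graphml"))
  ord <- function(d) d[order(d$factor_id, d$pathway_id, d$component), ]
  a <- ord(e[, c("factor_id", "pathway_id", "component", "rho", "p_perm", "sign")])
  b <- ord(back)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b, a, tolerance = 1e-9)

  # empty network: a valid, empty SIF
  empty <- new("CrosstalkNetwork", edges = e[0, ],
               factor_nodes = data.frame(factor_id = character()),
               pathway_nodes = data.frame(pathway_id = character()),
               alpha = 0.01)
  exportNetwork(empty, file.path(tmp, "empty"), format = "sif")
  expect_length(readLines(file.path(tmp, "empty.sif")), 0)
  expect_error(exportNetwork(net, file.path(tmp, "x"), format = "dot"), "unknown")
})

test_that("collapsed view keeps the strongest component per factor-pathway pair", {
  e <- data.frame(factor_id = c("A", "A", "B"), pathway_id = c("P1", "P1", "P2"),
                  component = c(1L, 2L, 3L), rho = c(0.5, -0.9, 0.7),
                  p_perm = c(0.005, 0.001, 0.002),
                  sign = c("+", "-", "+"), stringsAsFactors = FALSE)
  net <- new("CrosstalkNetwork", edges = e,
             factor_nodes = data.frame(factor_id = c("A", "B")),
             pathway_nodes = data.frame(pathway_id = c("P1", "P2")),
             alpha = 0.01)
  ce <- collapseNetwork(net)
  expect_equal(nrow(ce), 2L)
  expect_equal(ce$rho[ce$factor_id == "A"], -0.9)
})
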