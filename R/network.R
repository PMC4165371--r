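#' Spearman correlation with permutation p-value
#'
#' Rank correlation (average ranks for ties) with a two-sided permutation
#' test: one vector's ranks are permuted and the p-value is the fraction of
#' permutations whose |rho*| reaches the observed |rho|. When the number of
#' distinct orderings n! does not exceed \code{n_perm} the test enumerates
#' all of them exactly; otherwise it samples, and reports
#' (1 + exceedances) / (n_perm + 1). A constant vector leaves rho undefined
#' and yields a flagged null result.
#'
#' @param x,y numeric vectors of equal length (>= 5).
#' @param n_perm number of permutations (study convention: 10,000).
#' @param seed integer RNG seed.
#' @return list(rho, p, exhaustive, ok); \code{ok = FALSE} flags an
#'   undefined correlation (constant input).
#' @examples
#' set.seed(1); x <- rnorm(8)
#' spearmanPerm(x, exp(x), n_perm = 2000, seed = 1)$rho  # monotone => 1
#' @export
spearmanPerm <- function(x, y, n_perm = 10000L, seed = 1L) {
  .stopIfNot(length(x) == length(y), "x and y must have equal length")
  .stopIfNot(length(x) >= 5L, "need at least 5 paired observations")
  .stopIfNot(n_perm >= 100L, "n_perm too small")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, exhaustive = FALSE, ok = FALSE))
  n <- length(x)
  rx <- .centeredRanks(x); ry <- .centeredRanks(y)
  denom <- sqrt(sum(rx^2) * sum(ry^2))
  rho <- sum(rx * ry) / denom
  tol <- 1e-12
  if (factorial(n) <= n_perm) {
    P <- .allPermutations(n)
    rho_star <- as.vector(matrix(rx[t(P)], nrow = n) |> crossprod(ry)) / denom
    p <- mean(abs(rho_star) >= abs(rho) - tol)
    exhaustive <- TRUE
  } else {
    set.seed(as.integer(seed))
    # one blocked order() call generates all n_perm random permutations
    o <- order(rep.int(seq_len(n_perm), rep.int(n, n_perm)), runif(n * n_perm))
    idx <- (o - 1L) %% n + 1L
    rho_star <- colSums(matrix(rx[idx], nrow = n) * ry) / denom
    p <- (1 + sum(abs(rho_star) >= abs(rho) - tol)) / (n_perm + 1)
    exhaustive <- FALSE
  }
  list(rho = rho, p = p, exhaustive = exhaustive, ok = TRUE)
}

#' Select soluble factors differentially expressed in at least one condition
#'
#' Scans per-condition DE tables for a catalogue of soluble-factor genes and
#' keeps those with q-value at or below \code{q_cutoff} in at least one
#' condition, recording the per-condition status (up/down/null) used for node
#' colouring.
#'
#' @param catalog character vector of candidate soluble-factor gene ids.
#' @param de_results named list (condition -> \code{\link{samTwoClass}}
#'   data.frame) for the factor tissue.
#' @param q_cutoff q-value threshold (study convention: 0.01).
#' @param expr optional \linkS4class{ExpressionMatrix} of the factor tissue;
#'   when given, each profile carries the factor's expression by animal.
#' @param pairing named character vector mapping the expression matrix's
#'   sample ids to animal ids (default: sample ids already are animal ids).
#' @return Named list of profiles, each
#'   \code{list(gene_id, values, de_status)}.
#' @export
selectDeFactors <- function(catalog, de_results, q_cutoff = 0.01,
                            expr = NULL, pairing = NULL) {
  .stopIfNot(length(catalog) > 0, "catalog must be non-empty")
  status <- sapply(de_results, function(res) {
    st <- setNames(rep("null", length(catalog)), catalog)
    hit <- res$gene_id %in% catalog & res$q_value <= q_cutoff & res$d != 0
    st[res$gene_id[hit]] <- ifelse(res$d[hit] > 0, "up", "down")
    st
  })
  status <- matrix(status, nrow = length(catalog),
                   dimnames = list(catalog, names(de_results)))
  keep <- rownames(status)[rowSums(status != "null") > 0]
  vals <- NULL
  if (!is.null(expr)) {
    X <- exprValues(expr)
    ids <- if (is.null(pairing)) colnames(X) else unname(pairing[colnames(X)])
    vals <- X[, !is.na(ids), drop = FALSE]
    colnames(vals) <- ids[!is.na(ids)]
  }
  out <- lapply(keep, function(g) {
    list(gene_id = g,
         values = if (!is.null(vals) && g %in% rownames(vals)) vals[g, ] else NULL,
         de_status = status[g, ])
  })
  names(out) <- keep
  out
}

#' Infer the bipartite soluble-factor / pathway crosstalk network
#'
#' Runs one \code{\link{spearmanPerm}} test per (factor, pathway, component)
#' triple between a factor's expression profile over animals and the pathway
#' activity component scores, keeping edges with permutation p below
#' \code{alpha}. Animals missing either tissue are dropped pairwise per test.
#' Per-test permutation seeds are derived deterministically from the triple
#' so the edge set does not depend on iteration order. No multiplicity
#' correction is applied across the grid (raw permutation p thresholding is
#' the replicated convention); set \code{adjust = "BH"} to switch it on.
#'
#' @param factors named list of factor profiles as returned by
#'   \code{\link{selectDeFactors}} (each with a \code{values} vector named by
#'   animal id).
#' @param indices named list of \linkS4class{PathwayIndexSet}.
#' @param pairing optional named character vector mapping index score row
#'   names (sample ids) to animal ids.
#' @param n_perm permutations per test (study convention: 10,000).
#' @param alpha edge significance threshold (study convention: 0.01).
#' @param seed global seed; per-test sub-seeds are derived from it.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return A \linkS4class{CrosstalkNetwork}.
#' @export
inferNetwork <- function(factors, indices, pairing = NULL, n_perm = 10000L,
                         alpha = 0.01, seed = 1L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  .stopIfNot(length(factors) > 0, "no factor profiles supplied")
  .stopIfNot(length(indices) > 0, "no pathway indices supplied")
  rows <- list(); ri <- 1L
  any_common <- FALSE
  for (f in names(factors)) {
    fv <- factors[[f]]$values
    .stopIfNot(!is.null(fv), sprintf("factor '%s' carries no expression profile", f))
    for (p in names(indices)) {
      sc <- indexScores(indices[[p]])
      animals <- if (is.null(pairing)) rownames(sc) else unname(pairing[rownames(sc)])
      common <- intersect(names(fv), animals)
      if (length(common) < 5L) next
      any_common <- TRUE
      y_rows <- match(common, animals)
      for (k in seq_len(ncol(sc))) {
        sp <- spearmanPerm(fv[common], sc[y_rows, k], n_perm = n_perm,
                           seed = deriveSeed(seed, paste(f, p, k, sep = "|")))
        if (!sp$ok) next
        rows[[ri]] <- data.frame(factor_id = f, pathway_id = p, component = k,
                                 rho = sp$rho, p_perm = sp$p,
                                 n_pairs = length(common), stringsAsFactors = FALSE)
        ri <- ri + 1L
      }
    }
  }
  .stopIfNot(any_common, "no animals shared between factor profiles and indices")
  all_tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(factor_id = character(), pathway_id = character(),
               component = integer(), rho = numeric(), p_perm = numeric(),
               n_pairs = integer(), stringsAsFactors = FALSE)
  p_eff <- if (adjust == "BH") stats::p.adjust(all_tests$p_perm, "BH") else all_tests$p_perm
  edges <- all_tests[p_eff < alpha, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, "+", "-")
  rownames(edges) <- NULL

  conds <- names(factors[[1]]$de_status)
  factor_nodes <- data.frame(factor_id = names(factors), stringsAsFactors = FALSE)
  for (cn in conds)
    factor_nodes[[paste0("de_", cn)]] <-
      vapply(factors, function(fp) unname(fp$de_status[cn]), character(1))
  factor_nodes$degree <- vapply(factor_nodes$factor_id,
                                function(f) sum(edges$factor_id == f), integer(1))
  pathway_nodes <- data.frame(pathway_id = names(indices), stringsAsFactors = FALSE)
  pathway_nodes$degree <- vapply(pathway_nodes$pathway_id,
                                 function(p) sum(edges$pathway_id == p), integer(1))
  new("CrosstalkNetwork", edges = edges, factor_nodes = factor_nodes,
      pathway_nodes = pathway_nodes, alpha = alpha)
}

#' Collapse a crosstalk network to pathway-level edges
#'
#' Keeps one edge per (factor, pathway) pair - the component with the
#' strongest |rho| - mirroring pathway-level network drawings.
#'
#' @param net a \linkS4class{CrosstalkNetwork}.
#' @return data.frame of collapsed edges.
#' @export
collapseNetwork <- function(net) {
  e <- networkEdges(net)
  if (!nrow(e)) return(e)
  key <- paste(e$factor_id, e$pathway_id)
  picked <- tapply(seq_len(nrow(e)), key, function(ii) ii[which.max(abs(e$rho[ii]))])
  out <- e[unlist(picked), , drop = FALSE]
  out <- out[order(out$factor_id, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a crosstalk network for Cytoscape
#'
#' Writes the network in one or more formats: \code{"sif"} (interaction type
#' \code{corr+} / \code{corr-}), \code{"graphml"} (via igraph; a round-trip
#' read reproduces the edge list), and \code{"tsv"} (edge and node attribute
#' tables).
#'
#' @param net a \linkS4class{CrosstalkNetwork}.
#' @param path_prefix output path prefix; suffixes are appended.
#' @param format subset of \code{c("sif", "graphml", "tsv")}.
#' @return Invisibly, the character vector of files written.
#' @export
exportNetwork <- function(net, path_prefix, format = c("sif", "graphml", "tsv")) {
  .stopIfNot(all(format %in% c("sif", "graphml", "tsv")),
             sprintf("unknown export format: %s",
                     paste(setdiff(format, c("sif", "graphml", "tsv")), collapse = ", ")))
  e <- networkEdges(net)
  files <- character()
  if ("sif" %in% format) {
    f <- paste0(path_prefix, ".sif")
    lines <- if (nrow(e))
      sprintf("%s\tcorr%s\t%s", e$factor_id, e$sign, e$pathway_id) else character()
    writeLines(lines, f)
    files <- c(files, f)
  }
  if ("graphml" %in% format) {
    f <- paste0(path_prefix, ".graphml")
    verts <- data.frame(name = c(net@factor_nodes$factor_id, net@pathway_nodes$pathway_id),
                        type = rep(c("factor", "pathway"),
                                   c(nrow(net@factor_nodes), nrow(net@pathway_nodes))),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = e$factor_id, to = e$pathway_id,
                     component = e$component, rho = e$rho, p_perm = e$p_perm,
                     sign = e$sign, stringsAsFactors = FALSE),
      directed = FALSE, vertices = verts)
    igraph::write_graph(g, f, format = "graphml")
    files <- c(files, f)
  }
  if ("tsv" %in% format) {
    fe <- paste0(path_prefix, "_edges.tsv")
    fn <- paste0(path_prefix, "_nodes.tsv")
    utils::write.table(e, fe, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net@factor_nodes, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net@pathway_nodes, paste0(path_prefix, "_pathway_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, fe, fn, paste0(path_prefix, "_pathway_nodes.tsv"))
  }
  invisible(files)
}

#' Read back a GraphML network export
#'
#' @param path a \code{.graphml} file written by \code{\link{exportNetwork}}.
#' @return data.frame of edges (factor_id, pathway_id, component, rho,
#'   p_perm, sign).
#' @export
importNetworkGraphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  e <- igraph::as_data_frame(g, what = "edges")
  if (!nrow(e))
    return(data.frame(factor_id = character(), pathway_id = character(),
                      component = integer(), rho = numeric(), p_perm = numeric(),
                      sign = character(), stringsAsFactors = FALSE))
  data.frame(factor_id = e$from, pathway_id = e$to,
             component = as.integer(e$component), rho = e$rho,
             p_perm = e$p_perm, sign = e$sign, stringsAsFactors = FALSE)
}
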