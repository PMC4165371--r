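#' Build a pathway signature
#'
#' A signature is a named character vector mapping pathway ids to their
#' enrichment direction (\code{"up"}, \code{"down"} or \code{"both"}), with
#' the condition label stored as an attribute. \code{\link{enrichLists}}
#' output converts directly.
#'
#' @param pathways character vector of pathway ids, or an
#'   \code{enrichLists} data.frame.
#' @param directions directions per pathway (recycled; default "both").
#' @param condition condition label.
#' @return Named character vector of class \code{"PathwaySignature"}.
#' @export
pathwaySignature <- function(pathways, directions = "both", condition = "") {
  if (is.data.frame(pathways)) {
    directions <- pathways$direction
    pathways <- pathways$pathway_id
  }
  .stopIfNot(all(directions %in% c("up", "down", "both")),
             "directions must be up/down/both")
  sig <- setNames(rep(directions, length.out = length(pathways)), pathways)
  .stopIfNot(!anyDuplicated(names(sig)), "duplicate pathway ids in signature")
  structure(sig, condition = condition, class = "PathwaySignature")
}

# direction compatibility: equal, or either side is the "both" wildcard
.dirCompatible <- function(a, b) a == b | a == "both" | b == "both"

#' Sensitivity and specificity of a pathway signature against a reference
#'
#' Undirected mode counts shared pathway ids; directed mode additionally
#' requires compatible enrichment directions (equal, or either signature
#' reporting \code{"both"}). Sensitivity is the fraction of reference
#' ("true response") pathways recovered; specificity is the fraction of
#' non-reference pathways in the declared universe correctly absent from the
#' test signature. An overlap p-value from
#' \code{\link{overlapSignificance}} is attached.
#'
#' @param test,truth \code{\link{pathwaySignature}} objects (or named
#'   direction vectors / plain id vectors).
#' @param universe character vector: the declared pathway universe.
#' @param directed logical; require direction compatibility.
#' @return A one-row data.frame: n_truth, n_test, n_overlap, sensitivity,
#'   specificity, p_overlap, directed.
#' @examples
#' truth <- pathwaySignature(sprintf("P%02d", 1:19))
#' test <- pathwaySignature(sprintf("P%02d", c(1:13, 30:31)))
#' sensitivitySpecificity(test, truth, sprintf("P%02d", 1:100))$sensitivity
#' @export
sensitivitySpecificity <- function(test, truth, universe, directed = FALSE) {
  as_sig <- function(s) {
    if (is.null(names(s))) setNames(rep("both", length(s)), s) else s
  }
  test <- as_sig(test); truth <- as_sig(truth)
  .stopIfNot(length(truth) > 0, "truth signature must be non-empty")
  .stopIfNot(length(universe) > 0, "pathway universe must be non-empty")
  .stopIfNot(all(names(test) %in% universe) && all(names(truth) %in% universe),
             "signatures must be drawn from the universe")
  shared <- intersect(names(test), names(truth))
  if (directed)
    shared <- shared[.dirCompatible(test[shared], truth[shared])]
  n_overlap <- length(shared)
  sens <- n_overlap / length(truth)
  neg_universe <- setdiff(universe, names(truth))
  spec <- length(setdiff(neg_universe, names(test))) / length(neg_universe)
  p <- overlapSignificance(length(intersect(names(test), names(truth))),
                           length(test), length(truth), length(universe))
  data.frame(n_truth = length(truth), n_test = length(test),
             n_overlap = n_overlap, sensitivity = sens, specificity = spec,
             p_overlap = p, directed = directed)
}

#' Hypergeometric significance of a pathway overlap
#'
#' Probability of observing at least \code{n_overlap} shared pathways when
#' \code{n_test} pathways are drawn at random from a universe of
#' \code{n_universe} containing \code{n_truth} reference pathways.
#'
#' @param n_overlap,n_test,n_truth,n_universe overlap table counts.
#' @return Upper-tail hypergeometric p-value.
#' @export
overlapSignificance <- function(n_overlap, n_test, n_truth, n_universe) {
  .stopIfNot(n_overlap >= 0 && n_overlap <= min(n_test, n_truth) &&
               max(n_test, n_truth) <= n_universe &&
               n_overlap >= n_test + n_truth - n_universe,
             "inconsistent overlap counts")
  if (n_overlap == 0) return(1)
  phyper(n_overlap - 1, n_truth, n_universe - n_truth, n_test, lower.tail = FALSE)
}

#' Pairwise Jaccard similarity of pathways
#'
#' @param collection a \linkS4class{PathwayCollection}.
#' @param ids pathways to include (default: all).
#' @return Symmetric matrix of |intersection| / |union| with unit diagonal.
#' @examples
#' pc <- PathwayCollection(list(A = c("a", "b", "c", "d"), B = c("c", "d", "e")))
#' jaccardMatrix(pc)["A", "B"]  # 2/5
#' @export
jaccardMatrix <- function(collection, ids = names(geneSets(collection))) {
  sets <- geneSets(collection)
  .stopIfNot(all(ids %in% names(sets)), "unknown pathway id requested")
  sets <- sets[ids]
  n <- length(sets)
  out <- diag(1, n)
  dimnames(out) <- list(ids, ids)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- out[j, i] <-
      length(intersect(sets[[i]], sets[[j]])) / length(union(sets[[i]], sets[[j]]))
  }
  out
}

#' Average-linkage (UPGMA) clustering of a similarity matrix
#'
#' Agglomerates on distance = 1 - similarity with average linkage; merge
#' heights are non-decreasing.
#'
#' @param similarity square symmetric similarity matrix with maximal diagonal.
#' @return An \code{hclust} object (merge matrix plus heights).
#' @export
averageLinkageCluster <- function(similarity) {
  .stopIfNot(is.matrix(similarity) && nrow(similarity) == ncol(similarity),
             "similarity must be square")
  .stopIfNot(isTRUE(all.equal(similarity, t(similarity), tolerance = 1e-10)),
             "similarity must be symmetric")
  .stopIfNot(all(diag(similarity) >= apply(similarity, 1, max) - 1e-10),
             "diagonal must be maximal")
  hclust(as.dist(1 - similarity), method = "average")
}

#' Write a dendrogram in Newick format
#'
#' @param hc an \code{hclust} object.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeDendrogramNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
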