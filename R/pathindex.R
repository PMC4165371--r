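#' Principal-component pathway activity index
#'
#' Summarises the transcriptional activity of one pathway across samples by
#' the first \code{n_components} principal components of the gene-centred
#' member submatrix, with samples as observations and member genes as
#' variables (no variance scaling: inputs are log ratios on a common scale).
#' The sign of each component is fixed so that its correlation with the mean
#' member-gene profile is non-negative, resolving the eigenvector sign
#' indeterminacy deterministically.
#'
#' @param x \linkS4class{ExpressionMatrix} or genes x samples matrix.
#' @param members character vector of member gene ids.
#' @param n_components number of components to retain (default 3).
#' @param pathway_id identifier stored in the result.
#' @return A \linkS4class{PathwayIndexSet}: sample x component scores (zero
#'   mean per component) and the fraction of total member-gene variance each
#'   component retains.
#' @examples
#' m <- matrix(rnorm(30 * 13), 30, 13,
#'             dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:13)))
#' idx <- pathwayPcIndex(m, sprintf("g%02d", 1:10), pathway_id = "P01")
#' varianceFraction(idx)
#' @export
pathwayPcIndex <- function(x, members, n_components = 3L, pathway_id = "pathway") {
  X <- exprValues(x)
  present <- intersect(members, rownames(X))
  if (length(present) < n_components)
    stop(sprintf("pathway '%s': %d member genes present, need at least %d",
                 pathway_id, length(present), n_components), call. = FALSE)
  .stopIfNot(ncol(X) >= n_components + 1L,
             sprintf("pathway '%s': need more samples than components", pathway_id))
  sub <- t(X[present, , drop = FALSE])       # samples x genes
  pc <- prcomp(sub, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  vf <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  mean_profile <- rowMeans(scale(sub, center = TRUE, scale = FALSE))
  for (j in seq_len(k)) {
    cc <- sum(scores[, j] * mean_profile)
    if (cc < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(X)
  new("PathwayIndexSet", pathway_id = pathway_id, scores = scores,
      variance_fraction = vf, member_genes_used = present)
}

#' Compute activity indices for a list of pathways
#'
#' @param x \linkS4class{ExpressionMatrix} or matrix.
#' @param collection a \linkS4class{PathwayCollection}.
#' @param pathway_ids pathways to index (default: all in the collection).
#' @param n_components components per pathway.
#' @param min_members skip pathways with fewer members present than this
#'   (default: \code{n_components}, below which indexing is impossible).
#' @return Named list of \linkS4class{PathwayIndexSet}.
#' @export
pathwayIndices <- function(x, collection, pathway_ids = names(geneSets(collection)),
                           n_components = 3L, min_members = n_components) {
  sets <- geneSets(collection)
  .stopIfNot(all(pathway_ids %in% names(sets)), "unknown pathway id requested")
  out <- list()
  for (pid in pathway_ids) {
    present <- intersect(sets[[pid]], rownames(exprValues(x)))
    if (length(present) < max(min_members, n_components)) next
    out[[pid]] <- pathwayPcIndex(x, sets[[pid]], n_components, pathway_id = pid)
  }
  out
}

#' Summarise cumulative variance retained across pathway indices
#'
#' @param indices list of \linkS4class{PathwayIndexSet}.
#' @return Named numeric: \code{min}, \code{max} and \code{mean} of the
#'   cumulative variance fraction retained by the components of each pathway.
#' @examples
#' m <- matrix(rnorm(40 * 10), 40, 10,
#'             dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
#' idx <- list(pathwayPcIndex(m, sprintf("g%02d", 1:15), pathway_id = "A"),
#'             pathwayPcIndex(m, sprintf("g%02d", 16:40), pathway_id = "B"))
#' summariseVariance(idx)
#' @export
summariseVariance <- function(indices) {
  .stopIfNot(length(indices) > 0, "need at least one pathway index")
  cum <- vapply(indices, function(ix) sum(varianceFraction(ix)), numeric(1))
  c(min = min(cum), max = max(cum), mean = mean(cum))
}
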