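#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom stats cor sd prcomp var rnorm runif setNames phyper pchisq
#'   hclust as.dist quantile median mad complete.cases
#' @importFrom utils head combn
NULL

#' Log-scale expression matrix with a tissue tag
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a single
#' assay \code{"logexpr"} (genes x samples, log scale) plus the tissue the
#' samples were taken from. Gene and sample identifiers must be unique.
#'
#' @slot tissue single character, tissue label (e.g. \code{"soleus"}).
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(tissue = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@tissue) != 1L) msg <- c(msg, "tissue must be a single string")
  if (!"logexpr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'logexpr' is required")
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn)) msg <- c(msg, "gene ids must be unique and non-NULL")
  if (is.null(cn) || anyDuplicated(cn)) msg <- c(msg, "sample ids must be unique and non-NULL")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x samples, log scale.
#' @param gene_ids,sample_ids optional ids; default taken from dimnames.
#' @param tissue tissue label.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ExpressionMatrix(m, tissue = "lung")
#' @export
ExpressionMatrix <- function(values, gene_ids = rownames(values),
                             sample_ids = colnames(values), tissue = "unknown") {
  values <- as.matrix(values)
  dimnames(values) <- list(gene_ids, sample_ids)
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(logexpr = values))
  new("ExpressionMatrix", se, tissue = tissue)
}

#' @describeIn ExpressionMatrix-class tissue label accessor
#' @param x an ExpressionMatrix
#' @export
setGeneric("tissueOf", function(x) standardGeneric("tissueOf"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("tissueOf", "ExpressionMatrix", function(x) x@tissue)

#' Extract the log-expression values of an ExpressionMatrix (or pass a matrix through)
#'
#' @param x ExpressionMatrix or plain numeric matrix with dimnames.
#' @return numeric matrix, genes x samples.
#' @export
exprValues <- function(x) {
  if (is(x, "SummarizedExperiment")) return(SummarizedExperiment::assay(x, "logexpr"))
  as.matrix(x)
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples\n",
              object@tissue, nrow(object), ncol(object)))
})

#' Collection of gene sets (pathways)
#'
#' @slot sets named list of character vectors (pathway id -> member gene ids).
#' @slot descriptions named character, one free-text description per pathway.
#' @slot category named character, category tag per pathway (may be "").
#' @export
setClass("PathwayCollection",
  representation(sets = "list", descriptions = "character", category = "character")
)

setValidity("PathwayCollection", function(object) {
  msg <- character()
  ids <- names(object@sets)
  if (is.null(ids) || anyDuplicated(ids)) msg <- c(msg, "pathway ids must be unique")
  if (any(lengths(object@sets) == 0L)) msg <- c(msg, "empty gene sets are not allowed")
  if (!identical(names(object@descriptions), ids)) msg <- c(msg, "descriptions must be named by pathway id")
  if (!identical(names(object@category), ids)) msg <- c(msg, "category must be named by pathway id")
  if (length(msg)) msg else TRUE
})

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors.
#' @param descriptions optional named character (defaults to the ids).
#' @param category optional named character of category tags (defaults to "").
#' @return A \code{PathwayCollection} object.
#' @export
PathwayCollection <- function(sets, descriptions = NULL, category = NULL) {
  ids <- names(sets)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  names(sets) <- ids
  if (is.null(descriptions)) descriptions <- setNames(ids, ids)
  if (is.null(category)) category <- setNames(rep("", length(ids)), ids)
  new("PathwayCollection", sets = sets,
      descriptions = descriptions[ids], category = category[ids])
}

#' @rdname PathwayCollection-class
#' @param x a PathwayCollection
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname PathwayCollection-class
#' @export
setMethod("geneSets", "PathwayCollection", function(x) x@sets)

#' @rdname PathwayCollection-class
#' @export
setGeneric("setCategories", function(x) standardGeneric("setCategories"))

#' @rdname PathwayCollection-class
#' @export
setMethod("setCategories", "PathwayCollection", function(x) x@category)

#' @rdname PathwayCollection-class
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname PathwayCollection-class
#' @export
setMethod("setDescriptions", "PathwayCollection", function(x) x@descriptions)

setMethod("show", "PathwayCollection", function(object) {
  cat(sprintf("PathwayCollection: %d sets, sizes %d-%d\n",
              length(object@sets),
              if (length(object@sets)) min(lengths(object@sets)) else 0L,
              if (length(object@sets)) max(lengths(object@sets)) else 0L))
})

#' Per-pathway principal-component activity index
#'
#' Sample-level scores of the first components of the gene-centred member
#' submatrix, with the variance fraction each component retains.
#'
#' @slot pathway_id pathway identifier.
#' @slot scores samples x k numeric matrix of component scores (zero mean).
#' @slot variance_fraction numeric of length k, non-increasing, sums to <= 1.
#' @slot member_genes_used character, member genes present in the data.
#' @export
setClass("PathwayIndexSet",
  representation(pathway_id = "character", scores = "matrix",
                 variance_fraction = "numeric", member_genes_used = "character")
)

setValidity("PathwayIndexSet", function(object) {
  msg <- character()
  vf <- object@variance_fraction
  if (ncol(object@scores) != length(vf)) msg <- c(msg, "one variance fraction per component")
  if (any(diff(vf) > 1e-8)) msg <- c(msg, "variance fractions must be non-increasing")
  if (sum(vf) > 1 + 1e-8) msg <- c(msg, "variance fractions must sum to <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PathwayIndexSet", function(object) {
  cat(sprintf("PathwayIndexSet %s: %d samples x %d components (%.0f%% variance)\n",
              object@pathway_id, nrow(object@scores), ncol(object@scores),
              100 * sum(object@variance_fraction)))
})

#' @rdname PathwayIndexSet-class
#' @param x a PathwayIndexSet
#' @export
setGeneric("indexScores", function(x) standardGeneric("indexScores"))

#' @rdname PathwayIndexSet-class
#' @export
setMethod("indexScores", "PathwayIndexSet", function(x) x@scores)

#' @rdname PathwayIndexSet-class
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

#' @rdname PathwayIndexSet-class
#' @export
setMethod("varianceFraction", "PathwayIndexSet", function(x) x@variance_fraction)

#' Bipartite soluble-factor / pathway crosstalk network
#'
#' @slot edges data.frame with columns factor_id, pathway_id, component,
#'   rho, p_perm, sign.
#' @slot factor_nodes data.frame of per-condition differential-expression
#'   status for each soluble factor (for node colouring).
#' @slot pathway_nodes data.frame of pathway node annotations.
#' @slot alpha significance threshold the edges satisfy.
#' @export
setClass("CrosstalkNetwork",
  representation(edges = "data.frame", factor_nodes = "data.frame",
                 pathway_nodes = "data.frame", alpha = "numeric")
)

setValidity("CrosstalkNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("factor_id", "pathway_id", "component", "rho", "p_perm", "sign")
  if (!all(need %in% names(e))) msg <- c(msg, "edges must have the canonical columns")
  else if (nrow(e)) {
    if (any(e$p_perm > object@alpha + 1e-12)) msg <- c(msg, "all edges must satisfy p_perm <= alpha")
    if (any(e$sign != ifelse(e$rho >= 0, "+", "-"))) msg <- c(msg, "edge sign must match sign(rho)")
    if (anyDuplicated(e[, c("factor_id", "pathway_id", "component")]))
      msg <- c(msg, "duplicate (factor, pathway, component) edges")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CrosstalkNetwork", function(object) {
  cat(sprintf("CrosstalkNetwork: %d edges, %d factors, %d pathways (alpha = %g)\n",
              nrow(object@edges), nrow(object@factor_nodes),
              nrow(object@pathway_nodes), object@alpha))
})

#' @rdname CrosstalkNetwork-class
#' @param x a CrosstalkNetwork
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CrosstalkNetwork-class
#' @export
setMethod("networkEdges", "CrosstalkNetwork", function(x) x@edges)

#' Serum analyte panel (analytes x subjects, log2 scale)
#'
#' @slot values numeric matrix, analytes x subjects; NA marks missing cells.
#' @slot design data.frame with one row per subject: columns
#'   \code{subject_id}, \code{group} (disease), \code{training}.
#' @export
setClass("SerumPanel",
  representation(values = "matrix", design = "data.frame")
)

setValidity("SerumPanel", function(object) {
  msg <- character()
  if (is.null(rownames(object@values)) || anyDuplicated(rownames(object@values)))
    msg <- c(msg, "analyte ids must be unique")
  if (!identical(colnames(object@values), object@design$subject_id))
    msg <- c(msg, "design rows must align with panel columns")
  if (length(msg)) msg else TRUE
})

#' Construct a SerumPanel
#'
#' @param values analytes x subjects numeric matrix (log2 scale, NAs allowed).
#' @param design data.frame with subject_id, group, training columns.
#' @return A \code{SerumPanel}.
#' @export
SerumPanel <- function(values, design) {
  design$subject_id <- as.character(design$subject_id)
  new("SerumPanel", values = as.matrix(values), design = design)
}

setMethod("show", "SerumPanel", function(object) {
  cat(sprintf("SerumPanel: %d analytes x %d subjects (%.1f%% missing)\n",
              nrow(object@values), ncol(object@values),
              100 * mean(is.na(object@values))))
})

#' @rdname SerumPanel-class
#' @param x a SerumPanel
#' @export
setGeneric("panelValues", function(x) standardGeneric("panelValues"))

#' @rdname SerumPanel-class
#' @export
setMethod("panelValues", "SerumPanel", function(x) x@values)

#' @rdname SerumPanel-class
#' @export
setGeneric("panelDesign", function(x) standardGeneric("panelDesign"))

#' @rdname SerumPanel-class
#' @export
setMethod("panelDesign", "SerumPanel", function(x) x@design)
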