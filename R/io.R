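# Plain-text interchange: tab-delimited matrices and design sheets, GMT gene
# sets, pathway signatures, ground-truth JSON.

#' Write / read an expression matrix as TSV
#'
#' First column \code{gene_id}, remaining columns one per sample.
#'
#' @param x \linkS4class{ExpressionMatrix} or matrix.
#' @param path file path.
#' @param tissue tissue tag applied on read.
#' @return \code{writeExpressionTsv}: invisibly, \code{path};
#'   \code{readExpressionTsv}: an \linkS4class{ExpressionMatrix}.
#' @export
writeExpressionTsv <- function(x, path) {
  X <- exprValues(x)
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTsv
#' @export
readExpressionTsv <- function(path, tissue = "unknown") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ExpressionMatrix(m, tissue = tissue)
}

#' Write / read a gene-set collection in GMT format
#'
#' Standard 3+-column tab format: pathway id, description, member genes. A
#' category tag, when present, is carried in the description field as a
#' \code{"[category] description"} prefix and recovered on read.
#'
#' @param collection a \linkS4class{PathwayCollection}.
#' @param path file path.
#' @return \code{writeGmt}: invisibly, \code{path}; \code{readGmt}: a
#'   \linkS4class{PathwayCollection}.
#' @export
writeGmt <- function(collection, path) {
  ids <- names(geneSets(collection))
  desc <- setDescriptions(collection)
  cat <- setCategories(collection)
  lines <- vapply(ids, function(pid) {
    d <- if (nzchar(cat[pid])) sprintf("[%s] %s", cat[pid], desc[pid]) else desc[pid]
    paste(c(pid, d, geneSets(collection)[[pid]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  desc_raw <- vapply(parts, `[`, character(1), 2L)
  cat <- sub("^\\[([^]]*)\\].*$", "\\1", desc_raw)
  cat[!grepl("^\\[", desc_raw)] <- ""
  desc <- sub("^\\[[^]]*\\] ?", "", desc_raw)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  PathwayCollection(sets, descriptions = setNames(desc, ids),
                    category = setNames(cat, ids))
}

#' Write / read a pathway signature (pathway_id, direction) as TSV
#'
#' @param sig a \code{\link{pathwaySignature}}.
#' @param path file path.
#' @return \code{writeSignatureTsv}: invisibly, \code{path};
#'   \code{readSignatureTsv}: a \code{PathwaySignature}.
#' @export
writeSignatureTsv <- function(sig, path) {
  utils::write.table(data.frame(pathway_id = names(sig),
                                direction = unname(unclass(sig)),
                                stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignatureTsv
#' @export
readSignatureTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  pathwaySignature(df$pathway_id, df$direction)
}

#' Write a serum panel as TSV (empty cells mark missing values)
#'
#' @param panel a \linkS4class{SerumPanel}.
#' @param path file path.
#' @return Invisibly, \code{path}.
#' @export
writeSerumTsv <- function(panel, path) {
  V <- panelValues(panel)
  df <- data.frame(analyte_id = rownames(V), V, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write synthetic-cohort ground truth as JSON
#'
#' @param truth ground-truth list from a generator.
#' @param path file path.
#' @return Invisibly, \code{path}.
#' @export
writeTruthJson <- function(truth, path) {
  truth$latent_factors <- NULL   # matrices round-trip poorly; keep the record lean
  truth$pathway_latents <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
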