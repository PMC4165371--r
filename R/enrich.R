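#' EASE-penalized over-representation p-value
#'
#' One-tailed hypergeometric upper-tail probability with the observed overlap
#' decremented by one (the conservative "EASE score" variant of the Fisher
#' test used by DAVID-style enrichment tools). With k genes of an n-gene list
#' falling in a K-gene set over an N-gene universe, it returns
#' P(X >= k - 1); an overlap of one or zero genes carries no evidence and
#' returns 1.
#'
#' @param k overlap count.
#' @param n query list size.
#' @param K gene-set size.
#' @param N universe size.
#' @return EASE p-value in [0, 1].
#' @examples
#' easeScore(8, 50, 40, 2000)
#' @export
easeScore <- function(k, n, K, N) {
  .stopIfNot(k >= 0 && k <= min(n, K) && max(n, K) <= N,
             "inconsistent counts: need 0 <= k <= min(n, K) <= N")
  if (k <= 1) return(1)
  phyper(k - 2, K, N - K, n, lower.tail = FALSE)
}

# classical (non-penalized) one-tailed Fisher p for the same table
.fisherUpper <- function(k, n, K, N) phyper(k - 1, K, N - K, n, lower.tail = FALSE)

#' Directional pathway over-representation of up/down gene lists
#'
#' Each pathway is tested three times with the EASE score: against the
#' upregulated list, the downregulated list, and their union. The reported
#' direction is \code{"up"} or \code{"down"} when only that directional test
#' passes \code{p_cutoff}, and \code{"both"} when both directional tests pass
#' or when only the combined list does. The universe is the full (detected)
#' gene background: the category filter removes pathways before testing but
#' never changes the universe, so retained p-values are unaffected by it.
#'
#' @param up,down character vectors of gene ids (subsets of \code{universe}).
#' @param collection a \linkS4class{PathwayCollection}.
#' @param universe background gene ids (e.g. all genes passing detection).
#' @param p_cutoff EASE p threshold (study convention: 0.2).
#' @param categories optional character vector of category tags to keep.
#' @param keep_all if TRUE, return every tested pathway (direction
#'   \code{"none"} where no test passes) rather than only passing ones.
#' @return data.frame with columns pathway_id, overlap, list_size, set_size,
#'   universe_size, p_up, p_down, p_both, ease_p, direction, ordered by
#'   ease_p.
#' @export
enrichLists <- function(up, down, collection, universe, p_cutoff = 0.2,
                        categories = NULL, keep_all = FALSE) {
  .stopIfNot(length(universe) > 0, "universe must be non-empty")
  .stopIfNot(all(up %in% universe) && all(down %in% universe),
             "query lists must be subsets of the universe")
  sets <- geneSets(collection)
  if (!is.null(categories))
    sets <- sets[setCategories(collection)[names(sets)] %in% categories]
  up <- unique(up); down <- unique(down); comb <- union(up, down)
  N <- length(universe)
  rows <- lapply(names(sets), function(pid) {
    members <- intersect(sets[[pid]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k_up <- length(intersect(up, members))
    k_dn <- length(intersect(down, members))
    k_cb <- length(intersect(comb, members))
    p_up <- easeScore(k_up, length(up), K, N)
    p_dn <- easeScore(k_dn, length(down), K, N)
    p_cb <- easeScore(k_cb, length(comb), K, N)
    pass_up <- p_up < p_cutoff; pass_dn <- p_dn < p_cutoff; pass_cb <- p_cb < p_cutoff
    direction <- if (pass_up && pass_dn) "both"
      else if (pass_up) "up"
      else if (pass_dn) "down"
      else if (pass_cb) "both"
      else "none"
    pick <- switch(direction,
                   up = c(k_up, length(up), p_up),
                   down = c(k_dn, length(down), p_dn),
                   c(k_cb, length(comb), p_cb))
    data.frame(pathway_id = pid, overlap = as.integer(pick[1]),
               list_size = as.integer(pick[2]), set_size = K,
               universe_size = N, p_up = p_up, p_down = p_dn, p_both = p_cb,
               ease_p = pick[3], direction = direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway_id = character(), overlap = integer(),
                      list_size = integer(), set_size = integer(),
                      universe_size = integer(), p_up = numeric(),
                      p_down = numeric(), p_both = numeric(),
                      ease_p = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (!keep_all) out <- out[out$direction != "none", , drop = FALSE]
  out <- out[order(out$ease_p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathways eligible for activity indexing at an enrichment FDR
#'
#' Benjamini-Hochberg adjustment of the combined-list EASE p-values from a
#' \code{\link{enrichLists}} run with \code{keep_all = TRUE}; pathways with
#' adjusted p below \code{fdr} are eligible. The adjustment procedure is a
#' configurable choice (\code{method = "none"} thresholds raw p instead).
#'
#' @param enrich_table data.frame from \code{enrichLists(..., keep_all = TRUE)}.
#' @param fdr eligibility threshold (study convention: 0.10).
#' @param method \code{"BH"} or \code{"none"}.
#' @return Character vector of eligible pathway ids.
#' @export
eligiblePathways <- function(enrich_table, fdr = 0.10, method = c("BH", "none")) {
  method <- match.arg(method)
  p <- enrich_table$p_both
  adj <- if (method == "BH") stats::p.adjust(p, "BH") else p
  sort(enrich_table$pathway_id[adj < fdr])
}
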