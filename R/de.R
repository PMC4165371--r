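#' Present-call detection filter
#'
#' Retains a gene iff it is called present in at least
#' \code{min_present_fraction} of the samples; the conventional microarray
#' rule of discarding probes flagged absent on at least 80\% of chips
#' corresponds to the default threshold of 0.2.
#'
#' @param flags logical matrix, genes x samples; TRUE = present call.
#' @param min_present_fraction minimum fraction of present calls in (0, 1].
#' @return Character vector of retained gene ids (rownames of \code{flags}).
#' @examples
#' fl <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE,
#'                TRUE, TRUE, TRUE, TRUE, TRUE), 2, 5, byrow = TRUE,
#'              dimnames = list(c("gA", "gB"), NULL))
#' filterByDetection(fl, 0.2)
#' @export
filterByDetection <- function(flags, min_present_fraction = 0.2) {
  .stopIfNot(is.matrix(flags) && nrow(flags) > 0 && ncol(flags) > 0,
             "flags must be a non-empty genes x samples matrix")
  .stopIfNot(min_present_fraction > 0 && min_present_fraction <= 1,
             "min_present_fraction must lie in (0, 1]")
  rownames(flags)[rowMeans(flags) >= min_present_fraction]
}

# Tusher-style fudge factor: the s-percentile minimising the coefficient of
# variation of window-wise MADs of d across the distribution of s.
.chooseS0 <- function(diff, s, method = c("tusher", "percentile"), s0_quantile = 0.05) {
  method <- match.arg(method)
  if (method == "percentile") return(unname(quantile(s, s0_quantile)))
  alphas <- seq(0, 1, by = 0.05)
  cand <- unname(quantile(s, alphas))
  windows <- cut(rank(s, ties.method = "first"), breaks = 100, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- diff / (s + s0)
    v <- tapply(d, windows, mad)
    v <- v[is.finite(v)]
    if (mean(v) == 0) Inf else sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

# Class-1 indicator columns for every permutation used: exhaustive over all
# choose(n, n1) arrangements when that count <= n_perm, sampled otherwise.
.permIndicators <- function(n, n1, n_perm) {
  total <- choose(n, n1)
  if (total <= n_perm) {
    idx <- combn(n, n1)
    W <- matrix(0, n, ncol(idx))
    W[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- 1
  } else {
    W <- vapply(seq_len(n_perm), function(b) {
      w <- numeric(n); w[sample.int(n, n1)] <- 1; w
    }, numeric(n))
  }
  W
}

.samD <- function(X, X2, W1, n1, n2, s0) {
  nsum <- n1 + n2
  S1 <- X %*% W1
  Q1 <- X2 %*% W1
  m1 <- S1 / n1
  m2 <- (rowSums(X) - S1) / n2        # rowSums recycles over columns of S1
  ss <- (Q1 - n1 * m1^2) + ((rowSums(X2) - Q1) - n2 * m2^2)
  ss[ss < 0] <- 0
  s <- sqrt((1 / n1 + 1 / n2) * ss / (nsum - 2))
  d <- (m1 - m2) / (s + s0)
  d[!is.finite(d)] <- 0                # constant genes with s0 = 0
  list(d = d, s = s, m1 = m1, m2 = m2)
}

#' SAM two-class unpaired differential expression with permutation FDR
#'
#' Computes the moderated relative difference d = (mean1 - mean2) / (s + s0)
#' per gene, where s is the gene-wise pooled standard error and s0 a fudge
#' factor chosen by Tusher's coefficient-of-variation procedure (or a fixed
#' percentile of s). False discovery rates come from class-label
#' permutations: for each gene the q-value is the median, over permutations,
#' of the number of permuted |d*| values exceeding its observed |d|, divided
#' by the number of observed exceedances, capped at 1 and monotonized along
#' the |d| ranking. All label arrangements are enumerated exhaustively when
#' their count does not exceed \code{n_perm}.
#'
#' @param x \linkS4class{ExpressionMatrix} or genes x samples matrix.
#' @param labels two-level factor (or coercible) over the samples; the
#'   contrast is level 1 minus level 2.
#' @param n_perm number of label permutations (>= 100 recommended).
#' @param seed integer RNG seed.
#' @param s0_method \code{"tusher"} or \code{"percentile"}.
#' @param s0_quantile percentile of s used when \code{s0_method = "percentile"}.
#' @return data.frame with columns gene_id, d, s, fold_change (difference of
#'   class means on the log scale), q_value, direction.
#' @examples
#' m <- matrix(rnorm(200 * 8), 200, 8,
#'             dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
#' m[1, 1:4] <- m[1, 1:4] + 5
#' res <- samTwoClass(m, rep(c("A", "B"), each = 4), n_perm = 100, seed = 1)
#' head(res[order(-abs(res$d)), ], 3)
#' @export
samTwoClass <- function(x, labels, n_perm = 1000L, seed = 1L,
                        s0_method = c("tusher", "percentile"), s0_quantile = 0.05) {
  X <- exprValues(x)
  labels <- factor(labels)
  .stopIfNot(nlevels(labels) == 2L, "labels must have exactly two levels")
  .stopIfNot(length(labels) == ncol(X), "one label per sample is required")
  n1 <- sum(labels == levels(labels)[1]); n2 <- sum(labels == levels(labels)[2])
  .stopIfNot(n1 >= 2L && n2 >= 2L, "each class needs at least 2 samples")
  .stopIfNot(n_perm >= 2L, "n_perm too small")
  .stopIfNot(all(is.finite(X)), "expression values must be finite")

  # observed statistics on columns ordered as given
  w_obs <- as.numeric(labels == levels(labels)[1])
  X2 <- X^2
  obs0 <- .samD(X, X2, matrix(w_obs, ncol = 1), n1, n2, s0 = 0)
  s0 <- .chooseS0(obs0$m1 - obs0$m2, obs0$s, method = match.arg(s0_method),
                  s0_quantile = s0_quantile)
  obs <- .samD(X, X2, matrix(w_obs, ncol = 1), n1, n2, s0 = s0)
  d_obs <- drop(obs$d)

  set.seed(as.integer(seed))
  W1 <- .permIndicators(ncol(X), n1, n_perm)
  d_perm <- .samD(X, X2, W1, n1, n2, s0 = s0)$d

  # median permutation exceedance count per observed |d| threshold
  ad <- abs(d_obs)
  ord <- order(ad, decreasing = TRUE)
  thr <- ad[ord]
  exceed <- vapply(seq_len(ncol(d_perm)), function(b) {
    sorted <- sort(abs(d_perm[, b]))
    length(sorted) - findInterval(thr - 1e-12, sorted)
  }, integer(length(thr)))
  med_exceed <- apply(exceed, 1L, median)
  n_called <- seq_along(thr)                 # observed |d| >= threshold
  q_sorted <- pmin(1, med_exceed / n_called)
  q_sorted <- rev(cummin(rev(q_sorted)))     # monotone non-increasing in |d|
  q <- numeric(length(thr)); q[ord] <- q_sorted

  data.frame(gene_id = rownames(X), d = d_obs, s = drop(obs$s),
             fold_change = drop(obs$m1 - obs$m2), q_value = q,
             direction = ifelse(d_obs > 0, "up", ifelse(d_obs < 0, "down", "null")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially expressed genes at an FDR cutoff
#'
#' @param res data.frame from \code{\link{samTwoClass}}.
#' @param fdr_cutoff q-value threshold (study convention: 0.01).
#' @return list with \code{up} and \code{down} character vectors.
#' @export
selectDe <- function(res, fdr_cutoff = 0.01) {
  .stopIfNot(all(c("gene_id", "d", "q_value") %in% names(res)),
             "res must be a samTwoClass result")
  called <- res$q_value <= fdr_cutoff & res$d != 0
  list(up = res$gene_id[called & res$d > 0],
       down = res$gene_id[called & res$d < 0])
}
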