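# Internal helpers: deterministic seed derivation, permutation enumeration,
# and small numeric utilities shared across modules.

# 32-bit-safe string hash (polynomial rolling hash mod a Mersenne prime).
# Doubles carry the intermediate products exactly (31 * 2^31 < 2^53).
.hashString <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

#' Derive a reproducible sub-seed from a parent seed and a label
#'
#' Used to fan a single global seed out to stages and to individual
#' permutation tests so results do not depend on evaluation order.
#'
#' @param seed integer parent seed.
#' @param label character label (stage name, test identifier, ...).
#' @return An integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, label) {
  as.integer((.hashString(label) + as.double(seed) * 2654435761) %% 2147483647)
}

# All n! permutations of 1..n as an (n! x n) integer matrix; n <= 8 intended.
.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Centered average ranks (ties -> mean rank); keeps permutation-invariant norm.
.centeredRanks <- function(x) {
  r <- rank(x, ties.method = "average")
  r - mean(r)
}

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
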