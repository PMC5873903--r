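# Codewords are stored as non-negative integers whose binary expansion gives
# the pool membership pattern: bit i (value 2^(i-1)) set means the well is
# pipetted into pool i. n_pools <= 30 so everything fits in an R integer.

.tnpool_env <- new.env(parent = emptyenv())

# 16-bit population-count lookup table, built once per session
.pc16 <- function() {
  if (is.null(.tnpool_env$pc16)) {
    pc <- 0L
    for (i in 1:16) pc <- c(pc, pc + 1L)
    .tnpool_env$pc16 <- pc
  }
  .tnpool_env$pc16
}

#' Number of set bits in each codeword integer
#' @param x integer vector of codewords (0 <= x < 2^30)
#' @return integer vector of Hamming weights
#' @keywords internal
popcount <- function(x) {
  pc <- .pc16()
  pc[bitwAnd(x, 65535L) + 1L] + pc[bitwShiftR(x, 16L) + 1L]
}

# lowest set bit of v (v > 0)
.lowbit <- function(v) bitwAnd(v, bitwNot(v - 1L))

#' Next integer with the same Hamming weight (Gosper's hack)
#'
#' Enumerates the constant-weight codewords in increasing integer order,
#' which is colexicographic order on the underlying pool subsets.
#' @param v current codeword (positive integer)
#' @return next codeword of equal weight, or NA if it would exceed .Machine
#' @keywords internal
next_same_weight <- function(v) {
  if (v <= 0L) return(NA_integer_)  # weight-0 class has the single word 0
  u <- .lowbit(v)
  t <- v + u
  if (t > .Machine$integer.max - 1L || t < 0L) return(NA_integer_)
  bitwOr(t, bitwShiftR(bitwXor(v, t) %/% u, 2L))
}

#' Convert codeword integers to 0/1 strings
#'
#' Character position j of the string corresponds to pool j (leftmost = pool 1).
#' @param x integer vector of codewords
#' @param n_pools code length
#' @return character vector of n_pools-character 0/1 strings
#' @export
codeword_to_string <- function(x, n_pools = 24L) {
  bits <- codeword_to_bits(x, n_pools)
  apply(bits, 1L, paste0, collapse = "")
}

#' Convert 0/1 strings back to codeword integers
#' @param s character vector of 0/1 strings
#' @return integer vector of codewords
#' @export
string_to_codeword <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE), function(b) {
    sum(as.integer(b) * bitwShiftL(1L, seq_along(b) - 1L))
  }, integer(1))
}

#' Codeword integers to a sites x pools 0/1 matrix
#' @param x integer vector of codewords
#' @param n_pools code length
#' @return integer matrix, one row per codeword, column j = pool j
#' @keywords internal
codeword_to_bits <- function(x, n_pools = 24L) {
  m <- matrix(0L, nrow = length(x), ncol = n_pools)
  for (j in seq_len(n_pools)) {
    m[, j] <- as.integer(bitwAnd(x, bitwShiftL(1L, j - 1L)) != 0L)
  }
  m
}

# bits (vector or matrix rows) to codeword integer(s)
bits_to_codeword <- function(bits) {
  if (is.matrix(bits)) {
    as.integer(bits %*% bitwShiftL(1L, seq_len(ncol(bits)) - 1L))
  } else {
    sum(as.integer(bits) * bitwShiftL(1L, seq_along(bits) - 1L))
  }
}

#' Pairwise Hamming distances between one codeword and a set
#' @keywords internal
hamming_to_set <- function(x, set) popcount(bitwXor(x, set))

#' Unrank a constant-weight codeword in colexicographic order
#'
#' Returns the codeword of Hamming weight `k` over `n` pools with 0-based
#' colex rank `r` (the combinadic): the subset {c_1 < ... < c_k} of bit
#' positions with rank sum(choose(c_i, i)).
#' @param r 0-based rank, 0 <= r < choose(n, k)
#' @param k Hamming weight
#' @param n code length
#' @return codeword integer
#' @keywords internal
unrank_colex <- function(r, k, n) {
  stopifnot(r >= 0, r < choose(n, k))
  if (k == 0L) return(0L)
  mask <- 0L
  for (i in k:1) {
    ci <- i - 1
    while (ci + 1 < n && choose(ci + 1, i) <= r) ci <- ci + 1
    mask <- bitwOr(mask, bitwShiftL(1L, ci))
    r <- r - choose(ci, i)
  }
  mask
}
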