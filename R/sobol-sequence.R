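# Sobol' low-discrepancy sequence (Gray-code construction) with optional
# seeded digital-shift scrambling. Direction numbers are the published
# Joe & Kuo (2008) initial values for dimensions 2..32 (dimension 1 uses the
# van der Corput sequence); primitive polynomials are stored in the usual
# integer encoding P = 2^s + 2a + 1.

.sobol_poly <- c(3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L, 61L,
                 67L, 91L, 97L, 103L, 109L, 115L, 131L, 137L, 143L, 145L,
                 157L, 167L, 171L, 185L, 191L, 193L, 203L, 211L, 213L)

.sobol_minit <- list(
  c(1), c(1, 3), c(1, 3, 1), c(1, 1, 1), c(1, 1, 3, 3), c(1, 3, 5, 13),
  c(1, 1, 5, 5, 17), c(1, 1, 5, 5, 5), c(1, 1, 7, 11, 19), c(1, 1, 5, 1, 1),
  c(1, 1, 1, 3, 11), c(1, 3, 5, 5, 31), c(1, 3, 3, 9, 7, 49),
  c(1, 1, 1, 15, 21, 21), c(1, 3, 1, 13, 27, 49), c(1, 1, 1, 15, 7, 5),
  c(1, 3, 1, 15, 13, 25), c(1, 1, 5, 5, 19, 61), c(1, 3, 7, 11, 23, 15, 103),
  c(1, 3, 7, 13, 13, 15, 69), c(1, 1, 3, 13, 7, 35, 63),
  c(1, 3, 5, 9, 1, 25, 53), c(1, 3, 1, 13, 9, 35, 107),
  c(1, 3, 1, 5, 27, 61, 31), c(1, 1, 5, 11, 19, 41, 61),
  c(1, 3, 5, 3, 3, 13, 69), c(1, 1, 7, 13, 1, 19, 1),
  c(1, 3, 7, 5, 13, 19, 59), c(1, 1, 3, 9, 25, 29, 41),
  c(1, 3, 5, 13, 23, 1, 55), c(1, 3, 7, 3, 13, 59, 17)
)

.sobol_bits <- 30L

# 30-bit direction integers for one dimension
sobol_directions <- function(dim) {
  L <- .sobol_bits
  if (dim == 1L) return(as.integer(2^(L - seq_len(L))))
  pj <- .sobol_poly[dim - 1L]
  mj <- .sobol_minit[[dim - 1L]]
  s <- length(mj)
  a <- (pj - 2^s - 1) / 2
  v <- integer(L)
  v[seq_len(min(s, L))] <- as.integer(mj[seq_len(min(s, L))] * 2^(L - seq_len(min(s, L))))
  if (L > s) {
    for (k in (s + 1L):L) {
      vk <- bitwXor(v[k - s], v[k - s] %/% as.integer(2^s))
      if (s > 1) for (i in seq_len(s - 1L))
        if (bitwAnd(bitwShiftR(a, s - 1L - i), 1) == 1)
          vk <- bitwXor(vk, v[k - i])
      v[k] <- vk
    }
  }
  v
}

#' Sobol' low-discrepancy points
#'
#' Generates the first `n` points of a Sobol' sequence in `d` dimensions
#' (d <= 32) on the unit hypercube, optionally randomized by a seeded
#' digital-shift scramble (each dimension's integer states are XORed with a
#' random 30-bit word, preserving the sequence's equidistribution).
#'
#' @param n Number of points.
#' @param d Dimension (at most 32).
#' @param seed Optional integer seed for the scramble.
#' @param scramble Apply a digital-shift randomization (default `TRUE`;
#'   `FALSE` gives the deterministic reference sequence starting at 0).
#' @return An `n x d` matrix of points in `[0, 1)`.
#' @export
sobol_points <- function(n, d, seed = NULL, scramble = TRUE) {
  if (d < 1 || d > length(.sobol_poly) + 1L)
    stop(sprintf("sobol_points supports 1 <= d <= %d", length(.sobol_poly) + 1L),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- .sobol_bits
  V <- vapply(seq_len(d), sobol_directions, integer(L))
  shift <- if (scramble) as.integer(floor(stats::runif(d) * 2^L)) else integer(d)
  pts <- matrix(0, n, d)
  state <- integer(d)
  denom <- 2^L
  for (i in seq_len(n)) {
    if (i > 1L) {
      # Gray code: flip the direction of the lowest zero bit of i-2
      c0 <- 1L; ii <- i - 2L
      while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c0 <- c0 + 1L }
      state <- bitwXor(state, V[c0, ])
    }
    pts[i, ] <- bitwXor(state, shift) / denom
  }
  pts
}
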