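# Sobol' low-discrepancy sequence, Gray-code construction with the
# published Joe-Kuo primitive polynomials and initial direction numbers
# (dimensions 1-24; the first dimension is the van der Corput sequence).
# Optional scrambling is a seed-driven random digital shift (XOR), which
# preserves the digital-net structure.

# poly[d]: primitive polynomial over GF(2) as an integer (binary
# coefficients, leading and trailing 1); minit[[d]]: initial m values.
sobol_poly <- c(
  1L, 3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L, 61L, 67L,
  91L, 97L, 103L, 109L, 115L, 131L, 137L, 143L, 145L, 157L
)
sobol_minit <- list(
  1L, 1L, c(1L, 3L), c(1L, 3L, 1L), c(1L, 1L, 1L), c(1L, 1L, 3L, 3L),
  c(1L, 3L, 5L, 13L), c(1L, 1L, 5L, 5L, 17L), c(1L, 1L, 5L, 5L, 5L),
  c(1L, 1L, 7L, 11L, 19L), c(1L, 1L, 5L, 1L, 1L), c(1L, 1L, 1L, 3L, 11L),
  c(1L, 3L, 5L, 5L, 31L), c(1L, 3L, 3L, 9L, 7L, 49L),
  c(1L, 1L, 1L, 15L, 21L, 21L), c(1L, 3L, 1L, 13L, 27L, 49L),
  c(1L, 1L, 1L, 15L, 7L, 5L), c(1L, 3L, 1L, 15L, 13L, 25L),
  c(1L, 1L, 5L, 5L, 19L, 61L), c(1L, 3L, 7L, 11L, 23L, 15L, 103L),
  c(1L, 3L, 7L, 13L, 13L, 15L, 69L), c(1L, 1L, 3L, 13L, 7L, 35L, 63L),
  c(1L, 3L, 5L, 9L, 1L, 25L, 53L), c(1L, 3L, 1L, 13L, 9L, 35L, 107L)
)

sobol_nbits <- 30L

# direction integers v[k] (scaled by 2^(30-k)) for one dimension
sobol_directions <- function(dim, n_bits = sobol_nbits) {
  if (dim == 1) {
    return(bitwShiftL(1L, n_bits - seq_len(n_bits)))
  }
  poly <- sobol_poly[dim]
  m <- sobol_minit[[dim]]
  s <- length(m)
  v <- integer(n_bits)
  for (k in seq_len(min(s, n_bits))) {
    v[k] <- bitwShiftL(m[k], n_bits - k)
  }
  if (n_bits > s) {
    a <- vapply(seq_len(max(s - 1, 0)), function(i) {
      bitwAnd(poly, bitwShiftL(1L, s - i)) > 0
    }, logical(1))
    for (k in (s + 1):n_bits) {
      vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
      if (s > 1) {
        for (i in which(a)) vk <- bitwXor(vk, v[k - i])
      }
      v[k] <- vk
    }
  }
  v
}

#' Sobol' low-discrepancy sample
#'
#' Generates the first `n` points of the Sobol' sequence in `[0, 1)^dim`
#' (Gray-code order, Joe-Kuo direction numbers, up to 24 dimensions).
#' With a seed, each dimension is scrambled by a random digital shift,
#' giving a reproducible randomized quasi-Monte Carlo sample.
#'
#' @param n Number of points.
#' @param dim Dimension (1..24).
#' @param seed Integer seed for the digital-shift scrambling; `NULL` gives
#'   the unscrambled sequence.
#' @return An `n x dim` matrix with entries in `[0, 1)`.
#' @export
sobol_sequence <- function(n, dim, seed = NULL) {
  stopifnot(n >= 1, dim >= 1, dim <= length(sobol_poly))
  V <- vapply(seq_len(dim), sobol_directions, integer(sobol_nbits))
  X <- matrix(0L, nrow = n, ncol = dim)
  x <- integer(dim)
  X[1, ] <- x
  if (n > 1) {
    for (i in 2:n) {
      c_i <- 1L
      val <- i - 2L  # lowest zero bit of (i-2) drives Gray-code update
      while (bitwAnd(val, 1L) == 1L) {
        val <- bitwShiftR(val, 1L)
        c_i <- c_i + 1L
      }
      x <- bitwXor(x, V[c_i, ])
      X[i, ] <- x
    }
  }
  if (!is.null(seed)) {
    shift <- with_seed(seed, {
      as.integer(floor(stats::runif(dim) * 2^sobol_nbits))
    })
    X <- t(apply(X, 1, bitwXor, b = shift))
    if (dim == 1) X <- matrix(X, ncol = 1)
  }
  X / 2^sobol_nbits
}

#' Scale a unit-cube sample into a box
#'
#' @param u Matrix with entries in `[0, 1)`.
#' @param lower,upper Bound vectors (length = `ncol(u)`).
#' @return Matrix of the same shape, scaled into the box.
#' @export
scale_to_bounds <- function(u, lower, upper) {
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}
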