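#' Binomial and trinomial coefficient cache
#'
#' Populates the two integer tables needed by the moment machinery at a given
#' maximum order: binomial coefficients C(n, k) built iteratively as Pascal's
#' triangle, and trinomial coefficients (a|b|c) = (a+b+c)!/(a!b!c!) built as
#' Pascal's pyramid, with no factorial calls. All entries are exact integers
#' in double storage; the builder verifies they stay below 2^53.
#'
#' The supported order range is 0..35: above order 35 the geometric-to-Zernike
#' conversion suffers from large cancellations in double precision and the
#' results are numerically unreliable, so higher orders are rejected
#' throughout the package rather than silently returning garbage.
#'
#' @param N maximum moment order (0..35).
#' @return an object of class `coeff_cache` with elements `N`, `binom`
#'   (matrix, `binom[n+1, k+1]` = C(n, k)) and `trinom` (3D array,
#'   `trinom[a+1, b+1, c+1]` = (a|b|c) for a+b+c <= N).
#' @export
build_coefficient_cache <- function(N) {
  if (!is.numeric(N) || length(N) != 1 || N != round(N) || N < 0 || N > 35) {
    stop("build_coefficient_cache: order must be an integer in 0..35 ",
         "(double precision is unstable above order 35)")
  }
  N <- as.integer(N)
  binom <- matrix(0, N + 1, N + 1)
  binom[, 1] <- 1
  if (N >= 1) {
    for (n in 1:N) {
      for (k in 1:n) {
        binom[n + 1, k + 1] <- binom[n, k] + binom[n, k + 1]
      }
    }
  }
  trinom <- array(0, dim = c(N + 1, N + 1, N + 1))
  trinom[1, 1, 1] <- 1
  if (N >= 1) {
    for (n in 1:N) {
      for (a in 0:n) for (b in 0:(n - a)) {
        c3 <- n - a - b
        v <- 0
        if (a > 0) v <- v + trinom[a, b + 1, c3 + 1]
        if (b > 0) v <- v + trinom[a + 1, b, c3 + 1]
        if (c3 > 0) v <- v + trinom[a + 1, b + 1, c3]
        trinom[a + 1, b + 1, c3 + 1] <- v
      }
    }
  }
  if (max(binom) >= 2^53 || max(trinom) >= 2^53) {
    stop("build_coefficient_cache: cache entry exceeds exact integer range")
  }
  structure(list(N = N, binom = binom, trinom = trinom),
            class = "coeff_cache")
}

#' Number of geometric moments up to a given order
#'
#' Counts the exponent triples (i, j, k) with non-negative entries and
#' i + j + k <= N; equals C(N + 3, 3). At the field's de facto standard order
#' N = 20 there are 1771 geometric moments.
#'
#' @param N moment order (>= 0).
#' @return integer count.
#' @export
count_moment_indices <- function(N) {
  stopifnot(is.numeric(N), length(N) == 1, N >= 0, N == round(N))
  as.integer(round(choose(N + 3, 3)))
}

#' Number of Zernike-Canterakis descriptors up to a given order
#'
#' Counts the (n, l) pairs with 0 <= l <= n <= N and n - l even — one
#' rotation-invariant descriptor per pair. At N = 20 there are 121.
#'
#' @param N moment order (>= 0).
#' @return integer count.
#' @export
descriptor_count <- function(N) {
  stopifnot(is.numeric(N), length(N) == 1, N >= 0, N == round(N))
  as.integer((N + 2)^2 %/% 4)
}

# Prefactor i!j!k!/(i+j+k+3)! = [(i|j|k)(n+1)(n+2)(n+3)]^-1 that converts the
# accumulated per-facet simplex recurrence sums into true monomial volume
# integrals. Factorial-free via the cached trinomials.
moment_prefactor <- function(i, j, k, cache) {
  n <- i + j + k
  1 / (cache$trinom[cbind(i + 1, j + 1, k + 1)] *
         (n + 1) * (n + 2) * (n + 3))
}
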