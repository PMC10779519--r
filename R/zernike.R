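# Package-level memoisation for coefficient tables keyed by order.
.zcmesh_cache <- new.env(parent = emptyenv())
.zcmesh_cache$naive <- list()
.zcmesh_cache$basis <- list()

# --- sparse complex polynomials in x, y, z --------------------------------
# Represented as a list with integer exponent matrix `e` (columns i, j, k)
# and complex coefficient vector `c`. Small and built once per order, so
# plain aggregation is fine.

poly_new <- function(e, c) {
  list(e = matrix(as.integer(e), ncol = 3), c = as.complex(c))
}

poly_collect <- function(p) {
  key <- paste(p$e[, 1], p$e[, 2], p$e[, 3])
  c2 <- rowsum(cbind(Re(p$c), Im(p$c)), key, reorder = FALSE)
  e2 <- p$e[!duplicated(key), , drop = FALSE]
  keep <- abs(c2[, 1]) + abs(c2[, 2]) > 0
  poly_new(e2[keep, , drop = FALSE], complex(real = c2[keep, 1],
                                             imaginary = c2[keep, 2]))
}

poly_add <- function(p, q) {
  poly_collect(list(e = rbind(p$e, q$e), c = c(p$c, q$c)))
}

poly_mul <- function(p, q) {
  np <- length(p$c); nq <- length(q$c)
  ip <- rep(seq_len(np), times = nq)
  iq <- rep(seq_len(nq), each = np)
  poly_collect(list(e = p$e[ip, , drop = FALSE] + q$e[iq, , drop = FALSE],
                    c = p$c[ip] * q$c[iq]))
}

poly_scale <- function(p, s) poly_new(p$e, p$c * s)

# (x^2 + y^2 + z^2)^p expanded with multinomial coefficients.
poly_r2p <- function(p) {
  if (p == 0) return(poly_new(matrix(0L, 1, 3), 1 + 0i))
  g <- expand.grid(a = 0:p, b = 0:p)
  g <- g[g$a + g$b <= p, , drop = FALSE]
  cc <- p - g$a - g$b
  coef <- exp(lfactorial(p) - lfactorial(g$a) - lfactorial(g$b) -
                lfactorial(cc))
  poly_new(cbind(2L * g$a, 2L * g$b, 2L * cc), coef)
}

# Solid harmonic r^l Y_lm(theta, phi) as a complex polynomial in x, y, z,
# with Y_lm orthonormal over the unit sphere. For m < 0 the polynomial is
# obtained from Y_{l,-m} via Y_{l,-m} = (-1)^m conj(Y_lm).
solid_harmonic_poly <- function(l, m) {
  if (m < 0) {
    p <- solid_harmonic_poly(l, -m)
    return(poly_new(p$e, (-1)^(-m) * Conj(p$c)))
  }
  # (x + i y)^m
  u <- 0:m
  pxy <- poly_new(cbind(m - u, u, 0L), choose(m, u) * (1i)^u)
  nlm <- exp(0.5 * (log(2 * l + 1) - log(4 * pi) +
                      lfactorial(l - m) - lfactorial(l + m)))
  acc <- NULL
  for (p in 0:((l - m) %/% 2)) {
    cp <- (-1)^p * exp(lfactorial(2 * l - 2 * p) - l * log(2) -
                         lfactorial(p) - lfactorial(l - p) -
                         lfactorial(l - m - 2 * p))
    zpow <- poly_new(cbind(0L, 0L, l - m - 2 * p), 1 + 0i)
    term <- poly_scale(poly_mul(poly_mul(poly_r2p(p), zpow), pxy), cp)
    acc <- if (is.null(acc)) term else poly_add(acc, term)
  }
  poly_scale(acc, nlm)
}

# Radial Zernike coefficient q_{k l nu}: R_nl(r) = sum_nu q r^(2 nu + l),
# n = 2k + l, normalised so that int_0^1 R_nl^2 r^2 dr = 1/3.
radial_coeffs <- function(n, l) {
  k <- (n - l) %/% 2
  nu <- 0:k
  ((-1)^k / 4^k) * sqrt((2 * l + 4 * k + 3) / 3) * choose(2 * k, k) *
    (-1)^nu * choose(k, nu) *
    exp(lchoose(2 * (k + l + nu) + 1, 2 * k) - lchoose(k + l + nu, k))
}

# Monomial expansion of the Zernike-Canterakis basis function Z_nlm.
zernike_poly <- function(n, l, m) {
  q <- radial_coeffs(n, l)
  h <- solid_harmonic_poly(l, m)
  acc <- NULL
  for (nu in seq_along(q)) {
    term <- poly_scale(poly_mul(poly_r2p(nu - 1), h), q[nu])
    acc <- if (is.null(acc)) term else poly_add(acc, term)
  }
  acc
}

# Coefficient table mapping geometric moments to ZC moments at order N:
# one entry per (n, l, m >= 0) with the flat indices into the (N+1)^3 moment
# array and the conjugated monomial coefficients. Memoised per order.
zc_basis <- function(N) {
  key <- as.character(N)
  if (!is.null(.zcmesh_cache$basis[[key]])) return(.zcmesh_cache$basis[[key]])
  entries <- list()
  n_v <- integer(0); l_v <- integer(0); m_v <- integer(0)
  for (n in 0:N) for (l in seq(n %% 2, n, by = 2)) for (m in 0:l) {
    p <- zernike_poly(n, l, m)
    entries[[length(entries) + 1L]] <- list(
      idx = p$e[, 1] + (N + 1L) * p$e[, 2] + (N + 1L)^2 * p$e[, 3] + 1L,
      coef = Conj(p$c))
    n_v <- c(n_v, n); l_v <- c(l_v, l); m_v <- c(m_v, m)
  }
  basis <- list(N = N, n = n_v, l = l_v, m = m_v, entries = entries)
  .zcmesh_cache$basis[[key]] <- basis
  basis
}

#' Zernike-Canterakis moments from geometric moments
#'
#' Converts the exact geometric moments of a unit-ball shape into complex
#' Zernike-Canterakis moments: the projection of the shape's indicator
#' function onto the orthogonal ZC basis `Z_nlm = R_nl(r) Y_lm(theta, phi)`
#' inside the unit ball, expressed as a linear combination of the monomial
#' integrals. Moments exist for 0 <= n <= N, 0 <= l <= n with n - l even and
#' -l <= m <= l; only m >= 0 is stored, because conjugation symmetry
#' `Omega_nl(-m) = (-1)^m Conj(Omega_nlm)` carries no extra information (use
#' [zc_moment_value] to read any m).
#'
#' @param geom a `geom_moments` object from [geometric_moments].
#' @param cache a [build_coefficient_cache] of matching order.
#' @return an object of class `zc_moments`: list with `order` and aligned
#'   vectors `n`, `l`, `m` (m >= 0) and complex `omega`.
#' @export
zc_moments <- function(geom, cache = NULL) {
  stopifnot(inherits(geom, "geom_moments"))
  N <- geom$order
  if (is.null(cache)) cache <- build_coefficient_cache(N)
  if (!inherits(cache, "coeff_cache") || cache$N != N) {
    stop("zc_moments: cache order does not match the moment order")
  }
  basis <- zc_basis(N)
  flat <- as.vector(geom$values)
  omega <- vapply(basis$entries, function(en) {
    s <- sum(en$coef * flat[en$idx])
    c(Re(s), Im(s))
  }, numeric(2))
  omega <- 3 * complex(real = omega[1, ], imaginary = omega[2, ])
  structure(list(order = N, n = basis$n, l = basis$l, m = basis$m,
                 omega = omega),
            class = "zc_moments")
}

#' Read a single ZC moment, reconstructing negative m
#'
#' @param zcm a `zc_moments` object.
#' @param n,l,m moment indices; m may be negative, in which case the value is
#'   reconstructed from the stored m >= 0 moment by conjugation symmetry.
#' @return a complex scalar.
#' @export
zc_moment_value <- function(zcm, n, l, m) {
  stopifnot(inherits(zcm, "zc_moments"))
  hit <- which(zcm$n == n & zcm$l == l & zcm$m == abs(m))
  if (length(hit) != 1) stop("zc_moment_value: no such moment (n=", n,
                             ", l=", l, ", m=", m, ")")
  if (m >= 0) zcm$omega[hit] else (-1)^m * Conj(zcm$omega[hit])
}

#' Rotation-invariant ZC descriptors (3DZD)
#'
#' Collects, for each (n, l), the ZC moments over m = -l..l into a vector and
#' takes its Euclidean norm — the 3D Zernike descriptor in the sense of
#' Novotni and Klein. Negative-m moments are reconstructed by conjugation
#' symmetry, so the norm is `sqrt(|Omega_nl0|^2 + 2 sum_{m>0} |Omega_nlm|^2)`.
#' The resulting vector of length [descriptor_count] is invariant to proper
#' rotations of the input shape.
#'
#' @param zcm a `zc_moments` object.
#' @return an object of class `zcdv`: list with `order`, `n`, `l`,
#'   non-negative `values`, and a `normalized` flag (FALSE here).
#' @export
zc_descriptors <- function(zcm) {
  stopifnot(inherits(zcm, "zc_moments"))
  key <- paste(zcm$n, zcm$l)
  w <- ifelse(zcm$m == 0, 1, 2)
  ss <- rowsum(w * Mod(zcm$omega)^2, key, reorder = FALSE)
  first <- !duplicated(key)
  structure(list(order = zcm$order, n = zcm$n[first], l = zcm$l[first],
                 values = sqrt(as.vector(ss)), normalized = FALSE),
            class = "zcdv")
}

#' Normalize a ZC descriptor vector to unit sum
#'
#' Divides each descriptor by the sum of all descriptors, so the Manhattan
#' distance between two normalized vectors is bounded by 2. Idempotent.
#'
#' @param zcdv a `zcdv` object with at least one positive entry.
#' @return the normalized `zcdv`.
#' @export
normalize_zcdv <- function(zcdv) {
  stopifnot(inherits(zcdv, "zcdv"))
  s <- sum(zcdv$values)
  if (s <= 0) {
    stop("normalize_zcdv: all-zero descriptor vector (degenerate or empty ",
         "mesh upstream)")
  }
  zcdv$values <- zcdv$values / s
  zcdv$normalized <- TRUE
  zcdv
}

#' @export
print.zcdv <- function(x, ...) {
  cat(sprintf("zcdv: order %d, %d descriptors%s, sum %.6g\n", x$order,
              length(x$values), if (x$normalized) " (normalized)" else "",
              sum(x$values)))
  invisible(x)
}

#' ZC descriptors of a mesh in one call
#'
#' Convenience wrapper: unit-ball scaling (if requested), geometric moments,
#' ZC moments and descriptors.
#'
#' @param mesh a [tri_mesh].
#' @param N moment order (default 20, the field's de facto standard).
#' @param scale if TRUE (default), apply [center_and_scale] with the mesh's
#'   own rmax first; if FALSE the mesh must already sit inside the unit ball.
#' @param normalized return the unit-sum vector (default TRUE).
#' @return a `zcdv` object.
#' @export
mesh_zc_descriptors <- function(mesh, N = 20, scale = TRUE,
                                normalized = TRUE) {
  if (scale) {
    mesh <- center_and_scale(mesh, .Machine$double.eps)
  }
  cache <- build_coefficient_cache(N)
  d <- zc_descriptors(zc_moments(geometric_moments(mesh, N, cache), cache))
  if (normalized) normalize_zcdv(d) else d
}
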