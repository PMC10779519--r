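geom_moments_obj <- function(values, N) {
  structure(list(order = N, values = values), class = "geom_moments")
}

check_unit_ball <- function(mesh, tol = 1e-9) {
  rmax <- sqrt(max(rowSums(mesh$vertices^2)))
  if (rmax > 1 + tol) {
    stop("geometric_moments: vertex outside the unit ball (max norm ",
         format(rmax), "); apply center_and_scale first")
  }
  invisible(rmax)
}

#' Exact geometric moments of a mesh interior
#'
#' Computes the exact volume integrals of the monomials `x^i y^j z^k`
#' (i + j + k <= N) over the interior of a closed triangular mesh by the
#' oriented-tetrahedron decomposition: each facet contributes the integral
#' over the tetrahedron spanned between the origin and its three vertices,
#' with sign given by the facet orientation. Shared recurrences bring the
#' cost per facet to O(N^3). The (0, 0, 0) entry equals the signed mesh
#' volume; the result is independent of facet ordering up to floating-point
#' reassociation.
#'
#' @param mesh a [tri_mesh] whose vertices lie inside the closed unit ball
#'   (tolerance 1e-9 on the vertex norms).
#' @param N moment order (0..35).
#' @param cache optional [build_coefficient_cache] of the same order.
#' @return an object of class `geom_moments`: a list with `order` and
#'   `values`, a `(N+1)^3` array with `values[i+1, j+1, k+1]` the integral of
#'   `x^i y^j z^k`; entries with i + j + k > N are `NA` (undefined).
#' @seealso [geometric_moments_naive] for the direct-expansion oracle.
#' @export
geometric_moments <- function(mesh, N, cache = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (is.null(cache)) cache <- build_coefficient_cache(N)
  if (!inherits(cache, "coeff_cache") || cache$N != N) {
    stop("geometric_moments: cache order does not match N")
  }
  check_unit_ball(mesh)
  raw <- pk_geom_moment_sums(mesh$vertices, mesh$facets, as.integer(N))
  vals <- array(raw, dim = c(N + 1, N + 1, N + 1))
  idx <- moment_index_table(N)
  out <- array(NA_real_, dim = dim(vals))
  pre <- moment_prefactor(idx[, 1], idx[, 2], idx[, 3], cache)
  out[idx + 1L] <- vals[idx + 1L] * pre
  geom_moments_obj(out, N)
}

# All (i, j, k) with i+j+k <= N as a 3-column matrix (0-based exponents).
moment_index_table <- function(N) {
  g <- expand.grid(i = 0:N, j = 0:N, k = 0:N)
  g <- as.matrix(g[g$i + g$j + g$k <= N, , drop = FALSE])
  dimnames(g) <- NULL
  g
}

# Exponent-split table for the direct multinomial expansion at order N,
# built once and memoised: every way of writing x^i y^j z^k as a product of
# per-vertex powers, with its multinomial coefficient and the a!b!c!/(n+3)!
# simplex integral weight.
naive_split_table <- function(N) {
  key <- as.character(N)
  if (!is.null(.zcmesh_cache$naive[[key]])) return(.zcmesh_cache$naive[[key]])
  splits1 <- function(n) {
    s <- expand.grid(p1 = 0:n, p2 = 0:n)
    s <- s[s$p1 + s$p2 <= n, , drop = FALSE]
    cbind(s$p1, s$p2, n - s$p1 - s$p2)
  }
  rows <- list()
  for (i in 0:N) for (j in 0:(N - i)) for (k in 0:(N - i - j)) {
    si <- splits1(i); sj <- splits1(j); sk <- splits1(k)
    gi <- rep(seq_len(nrow(si)), times = nrow(sj) * nrow(sk))
    gj <- rep(rep(seq_len(nrow(sj)), each = nrow(si)), times = nrow(sk))
    gk <- rep(seq_len(nrow(sk)), each = nrow(si) * nrow(sj))
    ex <- cbind(si[gi, , drop = FALSE], sj[gj, , drop = FALSE],
                sk[gk, , drop = FALSE])
    a <- ex[, 1] + ex[, 4] + ex[, 7]
    b <- ex[, 2] + ex[, 5] + ex[, 8]
    cc <- ex[, 3] + ex[, 6] + ex[, 9]
    n <- i + j + k
    lmult <- (lfactorial(i) - lfactorial(ex[, 1]) - lfactorial(ex[, 2]) -
                lfactorial(ex[, 3])) +
             (lfactorial(j) - lfactorial(ex[, 4]) - lfactorial(ex[, 5]) -
                lfactorial(ex[, 6])) +
             (lfactorial(k) - lfactorial(ex[, 7]) - lfactorial(ex[, 8]) -
                lfactorial(ex[, 9]))
    w <- exp(lmult + lfactorial(a) + lfactorial(b) + lfactorial(cc) -
               lfactorial(n + 3))
    rows[[length(rows) + 1L]] <-
      cbind(target = i + (N + 1) * j + (N + 1)^2 * k, ex, w = w)
  }
  tab <- do.call(rbind, rows)
  .zcmesh_cache$naive[[key]] <- tab
  tab
}

#' Geometric moments by direct monomial expansion (oracle)
#'
#' Computes the same exact volume integrals as [geometric_moments], but by
#' the direct route: for each oriented tetrahedron the integrand is expanded
#' multinomially in the three vertex coordinates and each term integrated
#' over the unit simplex in closed form (`a! b! c! / (n+3)!`). This costs
#' O(f N^6) and is intended for small meshes in tests, as an independent
#' correctness oracle for the optimized recurrences.
#'
#' @inheritParams geometric_moments
#' @return a `geom_moments` object, as [geometric_moments].
#' @export
geometric_moments_naive <- function(mesh, N) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (N < 0 || N > 35) stop("geometric_moments_naive: order must be in 0..35")
  check_unit_ball(mesh)
  tab <- naive_split_table(N)
  vals <- numeric((N + 1)^3)
  a <- mesh$vertices[mesh$facets[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$facets[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$facets[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
         a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
         a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  for (t in seq_len(nrow(mesh$facets))) {
    # powers of the three vertex coordinates, exponents 0..N
    pw <- function(val) val^(0:N)
    term <- pw(a[t, 1])[tab[, 2] + 1] * pw(b[t, 1])[tab[, 3] + 1] *
            pw(c3[t, 1])[tab[, 4] + 1] *
            pw(a[t, 2])[tab[, 5] + 1] * pw(b[t, 2])[tab[, 6] + 1] *
            pw(c3[t, 2])[tab[, 7] + 1] *
            pw(a[t, 3])[tab[, 8] + 1] * pw(b[t, 3])[tab[, 9] + 1] *
            pw(c3[t, 3])[tab[, 10] + 1] * tab[, 11]
    acc <- rowsum(term, tab[, 1])
    vals[as.integer(rownames(acc)) + 1L] <-
      vals[as.integer(rownames(acc)) + 1L] + det[t] * acc[, 1]
  }
  out <- array(NA_real_, dim = c(N + 1, N + 1, N + 1))
  idx <- moment_index_table(N)
  flat <- array(vals, dim = c(N + 1, N + 1, N + 1))
  out[idx + 1L] <- flat[idx + 1L]
  geom_moments_obj(out, N)
}
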