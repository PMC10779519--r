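test_that("coefficient cache reproduces binomials and trinomials exactly", {
  cc <- build_coefficient_cache(12)
  # against base R's choose and a factorial oracle
  for (n in 0:12) for (k in 0:n) {
    expect_identical(cc$binom[n + 1, k + 1], choose(n, k))
  }
  expect_identical(cc$trinom[2, 2, 2], 6)        # (1|1|1) = 3!/1!1!1!
  expect_identical(cc$trinom[1, 1, 1], 1)        # (0|0|0)
  tri_oracle <- function(a, b, c) {
    factorial(a + b + c) / (factorial(a) * factorial(b) * factorial(c))
  }
  for (a in 0:6) for (b in 0:(6 - a)) for (c in 0:(6 - a - b)) {
    expect_equal(cc$trinom[a + 1, b + 1, c + 1], tri_oracle(a, b, c))
  }
  expect_error(build_coefficient_cache(36), "35")
  expect_error(build_coefficient_cache(-1), "0..35")
})

test_that("index counts match brute-force enumeration", {
  count_oracle <- function(N) {
    n <- 0
    for (i in 0:N) for (j in 0:(N - i)) for (k in 0:(N - i - j)) n <- n + 1
    n
  }
  desc_oracle <- function(N) {
    n <- 0
    for (nn in 0:N) for (ll in 0:nn) if ((nn - ll) %% 2 == 0) n <- n + 1
    n
  }
  for (N in c(0, 1, 2, 5, 8)) {
    expect_equal(count_moment_indices(N), count_oracle(N))
    expect_equal(descriptor_count(N), desc_oracle(N))
  }
  expect_equal(count_moment_indices(1), 4)
  expect_equal(descriptor_count(2), 4)   # (0,0), (1,1), (2,0), (2,2)
})

test_that("the moment conversion prefactor is factorial-free but exact", {
  cc <- build_coefficient_cache(8)
  expect_equal(zcmesh:::moment_prefactor(0, 0, 0, cc), 1 / 6)
  pre_oracle <- function(i, j, k) {
    factorial(i) * factorial(j) * factorial(k) / factorial(i + j + k + 3)
  }
  for (i in 0:4) for (j in 0:3) for (k in 0:1) {
    expect_equal(zcmesh:::moment_prefactor(i, j, k, cc),
                 pre_oracle(i, j, k))
  }
})

test_that("geometric moments of a scaled box match closed-form integrals", {
  box <- center_and_scale(generate_box_mesh(c(1, 1, 1)), 1e-12)
  h <- 1 / sqrt(3)                      # half-extent after scaling by rmax
  gm <- geometric_moments(box, 4)
  expect_equal(gm$values[1, 1, 1], 8 * h^3, tolerance = 1e-12)
  expect_equal(gm$values[1, 1, 1], mesh_volume(box), tolerance = 1e-9)
  # int x^2 over the box = (2h)^2 * 2 h^3 / 3
  expect_equal(gm$values[3, 1, 1], 8 * h^5 / 3, tolerance = 1e-12)
  # odd moments vanish for centrosymmetric shapes
  expect_lt(abs(gm$values[2, 1, 1]), 1e-12)
  sph <- center_and_scale(generate_sphere_mesh(0.8, 2), 1)
  gs <- geometric_moments(sph, 3)
  expect_lt(max(abs(c(gs$values[2, 1, 1], gs$values[1, 2, 1],
                      gs$values[1, 1, 2]))), 1e-12)
})

test_that("optimized and naive geometric moments agree on random closed meshes", {
  set.seed(7)
  worst <- 0
  for (rep in 1:50) {
    m <- random_tetra()
    N <- sample(4:8, 1)
    g1 <- geometric_moments(m, N)
    g2 <- geometric_moments_naive(m, N)
    worst <- max(worst, max(abs(g1$values - g2$values), na.rm = TRUE))
  }
  expect_lt(worst, 1e-10)
  # and on a larger closed fixture
  sph <- center_and_scale(generate_sphere_mesh(0.9, 2), 1)
  g1 <- geometric_moments(sph, 8)
  g2 <- geometric_moments_naive(sph, 8)
  expect_lt(max(abs(g1$values - g2$values), na.rm = TRUE), 1e-10)
})

test_that("naive moments reproduce the single-tetrahedron definition", {
  m <- random_tetra()
  g <- geometric_moments_naive(m, 2)
  expect_equal(g$values[1, 1, 1], mesh_volume(m), tolerance = 1e-12)
})

test_that("moment domain and cache order are validated", {
  big <- tri_mesh(2 * generate_sphere_mesh(1, 0)$vertices,
                  generate_sphere_mesh(1, 0)$facets)
  expect_error(geometric_moments(big, 4), "unit ball")
  m <- random_tetra()
  expect_error(geometric_moments(m, 4, build_coefficient_cache(5)),
               "order")
  expect_error(zc_moments(geometric_moments(m, 4),
                          build_coefficient_cache(5)), "order")
})

test_that("the ZC basis is orthonormal under exact ball integration", {
  combos <- list(c(0, 0, 0), c(1, 1, 0), c(1, 1, 1), c(2, 0, 0),
                 c(2, 2, 1), c(3, 1, 0), c(3, 3, 3), c(4, 0, 0),
                 c(4, 2, 2), c(5, 3, 1))
  for (i in seq_along(combos)) {
    for (j in seq_len(i)) {
      a <- combos[[i]]; b <- combos[[j]]
      g <- poly_ball_inner(zcmesh:::zernike_poly(a[1], a[2], a[3]),
                           zcmesh:::zernike_poly(b[1], b[2], b[3]))
      expected <- if (i == j) 1 / 3 else 0
      expect_equal(as.complex(g), as.complex(expected), tolerance = 1e-10)
    }
  }
})

test_that("radial polynomials are orthonormal on [0, 1] with weight r^2", {
  # exact polynomial integration of R_nl R_n'l r^2
  radial_inner <- function(n1, n2, l) {
    q1 <- zcmesh:::radial_coeffs(n1, l)
    q2 <- zcmesh:::radial_coeffs(n2, l)
    tot <- 0
    for (a in seq_along(q1)) for (b in seq_along(q2)) {
      pow <- 2 * (a - 1) + 2 * (b - 1) + 2 * l + 2
      tot <- tot + q1[a] * q2[b] / (pow + 1)
    }
    tot
  }
  for (l in 0:4) {
    ns <- seq(l, l + 8, by = 2)
    for (n1 in ns) for (n2 in ns) {
      expect_equal(radial_inner(n1, n2, l),
                   if (n1 == n2) 1 / 3 else 0, tolerance = 1e-8)
    }
  }
})

test_that("ZC moments obey conjugation symmetry against an independent m < 0 route", {
  m <- random_tetra()
  cc <- build_coefficient_cache(6)
  gm <- geometric_moments(m, 6, cc)
  zm <- zc_moments(gm, cc)
  flat <- as.vector(gm$values)
  for (case in list(c(3, 1, -1), c(4, 2, -2), c(5, 3, -1), c(6, 4, -3))) {
    n <- case[1]; l <- case[2]; mm <- case[3]
    # direct projection onto the m < 0 basis polynomial
    p <- zcmesh:::zernike_poly(n, l, mm)
    idx <- p$e[, 1] + 7L * p$e[, 2] + 49L * p$e[, 3] + 1L
    direct <- 3 * sum(Conj(p$c) * flat[idx])
    expect_equal(zc_moment_value(zm, n, l, mm), direct, tolerance = 1e-9)
  }
})

test_that("ZC moments are linear: zero moments give zero descriptors", {
  g0 <- zcmesh:::geom_moments_obj(array(0, dim = c(7, 7, 7)), 6L)
  zm <- zc_moments(g0, build_coefficient_cache(6))
  expect_true(all(Mod(zm$omega) == 0))
  d <- zc_descriptors(zm)
  expect_true(all(d$values == 0))
  expect_error(normalize_zcdv(d), "all-zero")
})

test_that("a single nonzero Omega_000 yields a one-hot descriptor vector", {
  zm <- structure(list(order = 2L, n = c(0L, 1L, 2L, 2L),
                       l = c(0L, 1L, 0L, 2L), m = c(0L, 1L, 0L, 2L),
                       omega = c(-2.5 + 0i, 0i, 0i, 0i)),
                  class = "zc_moments")
  # note: full index set would carry every m; a pruned set suffices here
  d <- zc_descriptors(zm)
  expect_equal(d$values[1], 2.5)
  expect_true(all(d$values[-1] == 0))
})

test_that("sphere meshes have vanishing l > 0 descriptors within triangulation error", {
  ratios <- vapply(3:5, function(sub) {
    s <- center_and_scale(generate_sphere_mesh(0.9, sub), 1)
    d <- mesh_zc_descriptors(s, 20, scale = FALSE, normalized = FALSE)
    max(d$values[d$l > 0]) / d$values[1]
  }, 0)
  expect_lt(ratios[2], 1e-3)             # subdivision 4
  expect_true(all(diff(ratios) < 0))     # shrinks as facets flatten less
  # the (0, 0) moment of a centered ball is 3 V Y00 = 3 V / sqrt(4 pi)
  s <- center_and_scale(generate_sphere_mesh(0.9, 4), 1)
  cc <- build_coefficient_cache(4)
  zm <- zc_moments(geometric_moments(s, 4, cc), cc)
  expect_equal(Re(zc_moment_value(zm, 0, 0, 0)),
               3 * mesh_volume(s) / sqrt(4 * pi), tolerance = 1e-9)
})

test_that("descriptors are invariant to proper rotations of the mesh", {
  set.seed(11)
  base <- make_mesh_fixture("ellipsoid", radii = c(0.9, 0.55, 0.3),
                            subdivisions = 3)
  d0 <- mesh_zc_descriptors(base, 20, scale = FALSE, normalized = TRUE)
  for (rep in 1:3) {
    r <- rot3(1, runif(1, 0, 2 * pi)) %*% rot3(2, runif(1, 0, 2 * pi)) %*%
      rot3(3, runif(1, 0, 2 * pi))
    rotated <- tri_mesh(base$vertices %*% t(r), base$facets)
    dr <- mesh_zc_descriptors(rotated, 20, scale = FALSE, normalized = TRUE)
    expect_lt(delta_z(d0, dr), 1e-6)
  }
})

test_that("normalization is idempotent and preserves proportions", {
  mk <- function(vals) {
    nl <- zcmesh:::descriptor_nl(2)
    structure(list(order = 2L, n = nl$n, l = nl$l, values = vals,
                   normalized = FALSE), class = "zcdv")
  }
  n1 <- normalize_zcdv(mk(c(2, 2, 0, 0)))
  expect_equal(n1$values, c(0.5, 0.5, 0, 0))
  n2 <- normalize_zcdv(mk(c(1, 3, 0, 0)))
  expect_equal(n2$values, c(0.25, 0.75, 0, 0))
  expect_equal(normalize_zcdv(n2)$values, n2$values)
})
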