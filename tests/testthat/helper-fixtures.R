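# Shared fixtures and independent oracles for the test suite.

# A random closed mesh: tetrahedron with vertices in the unit ball,
# positively oriented.
random_tetra <- function() {
  repeat {
    v <- matrix(runif(12, -0.55, 0.55), 4, 3)
    f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
    m <- tri_mesh(v, f)
    vol <- mesh_volume(m)
    if (abs(vol) > 1e-3) {
      if (vol < 0) m <- tri_mesh(v, f[, c(1, 3, 2)])
      return(m)
    }
  }
}

# Closed-form integral of x^a y^b z^c over the unit ball (0 unless all
# exponents are even): surface moment 4*pi*(a-1)!!(b-1)!!(c-1)!!/(a+b+c+1)!!
# integrated radially.
ball_monomial_integral <- function(a, b, c) {
  if (a %% 2 || b %% 2 || c %% 2) return(0)
  dfact <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))
  s <- 4 * pi * dfact(a - 1) * dfact(b - 1) * dfact(c - 1) /
    dfact(a + b + c + 1)
  s / (a + b + c + 3)
}

# <P, Q> over the unit ball for two sparse complex polynomials (zcmesh's
# internal representation), via the closed-form monomial integrals.
poly_ball_inner <- function(p, q) {
  tot <- 0 + 0i
  for (s in seq_along(p$c)) {
    for (t in seq_along(q$c)) {
      e <- p$e[s, ] + q$e[t, ]
      tot <- tot + p$c[s] * Conj(q$c[t]) *
        ball_monomial_integral(e[1], e[2], e[3])
    }
  }
  tot
}

# Brute-force ROC: enumerate candidate thresholds and count rates directly.
brute_force_roc <- function(labels, distances) {
  th <- sort(unique(c(distances, Inf)))
  np <- sum(labels); nn <- sum(!labels)
  tpr <- vapply(th, function(t) sum(labels & distances < t) / np, 0)
  fpr <- vapply(th, function(t) sum(!labels & distances < t) / nn, 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auroc = auroc)
}

# 3D rotation matrix from an axis index and angle.
rot3 <- function(axis, theta) {
  cs <- cos(theta); sn <- sin(theta)
  m <- diag(3)
  ix <- setdiff(1:3, axis)
  m[ix[1], ix[1]] <- cs; m[ix[2], ix[2]] <- cs
  m[ix[1], ix[2]] <- -sn; m[ix[2], ix[1]] <- sn
  m
}

write_temp_pdb <- function(lines) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Write a mesh as an MSMS-format .vert/.face pair (3 header lines each).
write_mock_msms_files <- function(mesh, prefix) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$facets)
  vl <- c("# mock vert", "#", sprintf("%d %d  1.00  1.40", nv, nv),
          sprintf("%9.3f %9.3f %9.3f %7.3f %7.3f %7.3f 0 0 0",
                  mesh$vertices[, 1], mesh$vertices[, 2],
                  mesh$vertices[, 3], 0, 0, 1))
  fl <- c("# mock face", "#", sprintf("%d %d  1.00  1.40", nf, nf),
          sprintf("%7d %7d %7d 1 1", mesh$facets[, 1], mesh$facets[, 2],
                  mesh$facets[, 3]))
  writeLines(vl, paste0(prefix, ".vert"))
  writeLines(fl, paste0(prefix, ".face"))
  invisible(prefix)
}

# A mock surface binary: copies pre-generated .vert/.face files to the
# requested output prefix, counts its invocations, and optionally fails
# whenever -all_components is present (to exercise the retry rule).
make_mock_msms <- function(dir, source_prefix, count_file,
                           fail_with_all_components = FALSE) {
  script <- file.path(dir, "mock_msms")
  lines <- c(
    "#!/bin/sh",
    sprintf("echo run >> '%s'", count_file),
    "prefix=''; prev=''",
    "for a in \"$@\"; do",
    if (fail_with_all_components) {
      "  if [ \"$a\" = '-all_components' ]; then exit 1; fi"
    },
    "  if [ \"$prev\" = '-of' ]; then prefix=\"$a\"; fi",
    "  prev=\"$a\"",
    "done",
    sprintf("cp '%s.vert' \"$prefix.vert\"", source_prefix),
    sprintf("cp '%s.face' \"$prefix.face\"", source_prefix))
  writeLines(lines, script)
  Sys.chmod(script, "0755")
  script
}

# Synthetic protein_features with prescribed components, for distance and
# retrieval tests that do not need the full pipeline.
fake_features <- function(zc_values, size = c(10, 8, 6), volume = 1000,
                          hist_bins = NULL, id = "x") {
  nl <- zcmesh:::descriptor_nl(2)
  v <- rep(0, 4)
  v[seq_along(zc_values)] <- zc_values
  zcdv <- structure(list(order = 2L, n = nl$n, l = nl$l,
                         values = v / sum(v), normalized = TRUE),
                    class = "zcdv")
  if (is.null(hist_bins)) hist_bins <- c(0, 3, 5, 3, 0, 0)
  h <- structure(list(values = hist_bins, bin_width = 2,
                      upper_limit = 2 * length(hist_bins), state = "raw"),
                 class = "zc_histogram")
  h <- smooth_histogram(h)
  protein_features(zcdv, h, structure(size, class = "size_triple"),
                   volume, metadata = list(id = id))
}
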