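#' Distance histogram of guide effective atoms
#'
#' Histogram of the distances of the (already aligned/centered) guide
#' points to the origin. Bin b (b = 0, 1, ...) counts points with distance
#' in `[bin_width * b, bin_width * (b + 1))`; the default 2 Å bins span the
#' 0-1000 Å range. Distances at or beyond the upper limit raise an error —
#' raise `upper_limit` for very large complexes.
#'
#' @param points a [point_cloud] or n x 3 matrix, centered at the origin by
#'   the outlier-detection transform.
#' @param bin_width bin width in Å (default 2).
#' @param upper_limit histogram range in Å (default 1000).
#' @return an object of class `zc_histogram`: list with `values` (counts per
#'   bin), `bin_width`, `upper_limit` and `state = "raw"`.
#' @export
distance_histogram <- function(points, bin_width = 2, upper_limit = 1000) {
  pc <- as_point_cloud(points)
  if (nrow(pc$coords) == 0) {
    stop("distance_histogram: empty point set")
  }
  d <- sqrt(rowSums(pc$coords^2))
  if (any(d >= upper_limit)) {
    stop("distance_histogram: distance ", format(max(d)),
         " beyond the histogram range; increase upper_limit")
  }
  nbin <- ceiling(upper_limit / bin_width)
  b <- floor(d / bin_width) + 1L
  values <- tabulate(b, nbins = nbin)
  structure(list(values = as.numeric(values), bin_width = bin_width,
                 upper_limit = upper_limit, state = "raw"),
            class = "zc_histogram")
}

#' Smooth and normalize a distance histogram
#'
#' Savitzky-Golay convolution with a third-order polynomial and window
#' length five: the kernel (-3, 12, 17, 12, -3)/35 applied over a mirrored
#' (reflective) boundary extension, followed by clipping of any negative
#' values to zero and normalization to unit sum — in that order. The mirror
#' extension reproduces constant histograms exactly and keeps the counts
#' near bin 0, where real proteins have mass, from leaking out of range.
#' The smoothing damps the local zigzags caused by effective-atom placement
#' noise while keeping the overall distribution.
#'
#' @param h a raw `zc_histogram`.
#' @return the histogram with `state = "smoothed"` and values summing to 1.
#' @export
smooth_histogram <- function(h) {
  stopifnot(inherits(h, "zc_histogram"))
  if (h$state != "raw") {
    stop("smooth_histogram: histogram is already smoothed")
  }
  if (sum(h$values) == 0) {
    stop("smooth_histogram: all-zero histogram (no guide atoms)")
  }
  v <- sg_smooth_mirror(h$values)
  v[v < 0] <- 0
  h$values <- v / sum(v)
  h$state <- "smoothed"
  h
}

# SG(5, 3) kernel from signal::sgolay, applied over a whole-sample mirror
# extension (x[0] = x[2], x[-1] = x[3], symmetric at the right end).
sg_smooth_mirror <- function(x) {
  n <- length(x)
  if (n < 3) stop("smooth_histogram: histogram too short to smooth")
  kern <- as.numeric(signal::sgolay(p = 3, n = 5)[3, ])  # central row
  left <- x[c(3, 2)]
  right <- x[c(n - 1, n - 2)]
  pad <- c(left, x, right)
  vapply(seq_len(n), function(i) sum(kern * pad[i:(i + 4)]), 0)
}

#' Per-axis size of an aligned point cloud
#'
#' Population standard deviation of the aligned guide points along each
#' coordinate axis, sorted in descending order. Together with the mesh
#' volume this re-injects the size information that the unit-ball scaling
#' removes from the ZC descriptors.
#'
#' @param points aligned guide points ([point_cloud] or matrix), from
#'   [detect_outliers].
#' @return an object of class `size_triple`: numeric length-3,
#'   `sigma_x >= sigma_y >= sigma_z` (Å).
#' @export
size_descriptor <- function(points) {
  pc <- as_point_cloud(points)
  if (nrow(pc$coords) < 2) {
    stop("size_descriptor: need at least 2 points")
  }
  xc <- sweep(pc$coords, 2, colMeans(pc$coords))
  s <- sort(sqrt(colMeans(xc^2)), decreasing = TRUE)
  structure(as.numeric(s), class = "size_triple")
}

#' Unit-ball scale factor
#'
#' The divisor applied to centered coordinates before the ZC moment
#' calculation. Methods:
#' \describe{
#'   \item{rmax}{largest mesh-vertex distance to the centering origin —
#'     always contains the mesh.}
#'   \item{rmax_over_0.7}{largest guide effective-atom distance divided by
#'     0.7, compensating the poor resolution of the ZC basis near the unit
#'     sphere.}
#'   \item{two_rg}{twice the radius of gyration (root-mean-square distance
#'     of the guide effective atoms to their centroid).}
#'   \item{rpca}{the largest radius of the guide-atom confidence ellipsoid,
#'     `s(p, 3) * sigma_x`, p = 0.95 by default.}
#' }
#' All methods except `rmax` are floored at the mesh rmax, because the
#' volume-like moment integrals expect a closed surface entirely inside the
#' unit ball. `1.8rg` is recognised but rejected: for effective atoms it is
#' always too short and degenerates to the rmax floor.
#'
#' @param mesh a [tri_mesh] in the same frame as the guide points.
#' @param guide_points guide effective atoms ([point_cloud] or matrix).
#' @param sizes a [size_descriptor] of the aligned guide points (used by
#'   `rpca`).
#' @param method one of `"rmax"`, `"rmax_over_0.7"`, `"two_rg"`, `"rpca"`.
#' @param p confidence level for `rpca` (default 0.95).
#' @param center centering origin (default: guide centroid).
#' @return the scale factor in Å.
#' @export
scale_factor <- function(mesh, guide_points, sizes,
                         method = c("rpca", "rmax", "rmax_over_0.7",
                                    "two_rg"),
                         p = 0.95, center = NULL) {
  if (length(method) == 1 && identical(method, "1.8rg")) {
    stop("scale_factor: 1.8rg is rejected: with effective atoms it is ",
         "shorter than the mesh rmax and degenerates to the rmax floor; ",
         "use two_rg or rpca instead")
  }
  method <- match.arg(method)
  pc <- as_point_cloud(guide_points)
  if (is.null(center)) center <- colMeans(pc$coords)
  stopifnot(inherits(mesh, "tri_mesh"))
  mesh_rmax <- sqrt(max(rowSums(sweep(mesh$vertices, 2, center)^2)))
  if (method == "rmax") return(mesh_rmax)
  pd2 <- rowSums(sweep(pc$coords, 2, center)^2)
  f <- switch(method,
    rmax_over_0.7 = sqrt(max(pd2)) / 0.7,
    two_rg = 2 * sqrt(mean(rowSums(
      sweep(pc$coords, 2, colMeans(pc$coords))^2))),
    rpca = ellipsoid_radius_multiplier(p, 3) * as.numeric(sizes)[1])
  max(f, mesh_rmax)
}

#' Bundle the features of one structure
#'
#' @param zcdv normalized [zc_descriptors] vector.
#' @param histogram smoothed [distance_histogram].
#' @param size [size_descriptor] triple.
#' @param volume mesh volume prior to unit-ball scaling (Å^3).
#' @param metadata named list (structure id, selection, surface mode, scale
#'   method/value, guide and outlier counts, ...).
#' @return an object of class `protein_features`.
#' @export
protein_features <- function(zcdv, histogram, size, volume,
                             metadata = list()) {
  stopifnot(inherits(zcdv, "zcdv"), inherits(histogram, "zc_histogram"),
            inherits(size, "size_triple"))
  if (!isTRUE(zcdv$normalized)) {
    stop("protein_features: descriptor vector must be normalized")
  }
  if (histogram$state != "smoothed") {
    stop("protein_features: histogram must be smoothed+normalized")
  }
  if (!is.numeric(volume) || volume <= 0) {
    stop("protein_features: volume must be positive")
  }
  structure(list(zcdv = zcdv, histogram = histogram, size = size,
                 volume = volume, metadata = metadata),
            class = "protein_features")
}

#' @export
print.protein_features <- function(x, ...) {
  cat(sprintf(paste0("protein_features: order %d, %d descriptors, volume ",
                     "%.1f A^3, size (%.1f, %.1f, %.1f) A\n"),
              x$zcdv$order, length(x$zcdv$values), x$volume,
              x$size[1], x$size[2], x$size[3]))
  invisible(x)
}

#' Serialize features to and from JSON
#'
#' A single versioned JSON document per structure.
#'
#' @param f a [protein_features] object.
#' @param path file path.
#' @export
write_features_json <- function(f, path) {
  stopifnot(inherits(f, "protein_features"))
  doc <- list(
    schema = "zcmesh/features/1",
    order = f$zcdv$order,
    zcdv = f$zcdv$values,
    histogram = list(values = f$histogram$values,
                     bin_width = f$histogram$bin_width,
                     upper_limit = f$histogram$upper_limit),
    size = as.numeric(f$size),
    volume = f$volume,
    metadata = f$metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features_json
#' @export
read_features_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "zcmesh/features/1")) {
    stop("read_features_json: unknown schema in ", path)
  }
  N <- as.integer(doc$order)
  nl <- descriptor_nl(N)
  zcdv <- structure(list(order = N, n = nl$n, l = nl$l,
                         values = as.numeric(doc$zcdv), normalized = TRUE),
                    class = "zcdv")
  hist <- structure(list(values = as.numeric(doc$histogram$values),
                         bin_width = doc$histogram$bin_width,
                         upper_limit = doc$histogram$upper_limit,
                         state = "smoothed"),
                    class = "zc_histogram")
  protein_features(zcdv, hist,
                   structure(as.numeric(doc$size), class = "size_triple"),
                   doc$volume, as.list(doc$metadata))
}

# (n, l) index pairs in storage order.
descriptor_nl <- function(N) {
  n <- integer(0); l <- integer(0)
  for (nn in 0:N) for (ll in seq(nn %% 2, nn, by = 2)) {
    n <- c(n, nn); l <- c(l, ll)
  }
  list(n = n, l = l)
}
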