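#' Align a point cloud with its principal axes
#'
#' Centers the points on their mean and rotates them so the covariance is
#' diagonal with per-axis variances sorted in descending order — the first
#' steps of PCA, with the optimal rotation obtained from the singular value
#' decomposition of the covariance matrix. The rotation is forced to be
#' proper (determinant +1) by negating one axis when the SVD returns a
#' reflection.
#'
#' @param points a [point_cloud] or an n x 3 coordinate matrix (n >= 4,
#'   non-collinear).
#' @return list with `points` (aligned [point_cloud]), `rotation` (3x3
#'   proper orthogonal matrix R) and `translation` (length-3 vector t), such
#'   that an aligned coordinate is `R x + t`.
#' @export
align_principal_axes <- function(points) {
  pc <- as_point_cloud(points)
  x <- pc$coords
  if (nrow(x) < 4) {
    stop("align_principal_axes: need at least 4 points")
  }
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  cv <- crossprod(xc) / nrow(xc)           # population covariance
  sv <- svd(cv)
  if (sv$d[1] <= 0 || sv$d[3] / sv$d[1] < 1e-12) {
    stop("align_principal_axes: degenerate geometry (rank-deficient ",
         "covariance)")
  }
  u <- sv$u
  if (det(u) < 0) u[, 3] <- -u[, 3]
  rot <- t(u)
  aligned <- xc %*% u
  list(points = point_cloud(aligned, pc$labels),
       rotation = rot,
       translation = as.numeric(-rot %*% center))
}

as_point_cloud <- function(points) {
  if (inherits(points, "point_cloud")) points else point_cloud(points)
}

#' Confidence-ellipsoid radius multiplier
#'
#' The factor s by which the per-axis standard deviations are multiplied to
#' obtain the radii of the axis-aligned confidence ellipsoid at probability
#' p: the square root of the chi-squared quantile with `dims` degrees of
#' freedom. At p = 0.95 in three dimensions s is approximately 2.795483.
#'
#' @param p confidence level, 0 < p < 1.
#' @param dims number of dimensions (>= 1).
#' @return the multiplier s.
#' @export
ellipsoid_radius_multiplier <- function(p, dims = 3) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    stop("ellipsoid_radius_multiplier: p must lie in (0, 1)")
  }
  stopifnot(dims >= 1)
  sqrt(qchisq(p, df = dims))
}

#' Iterative PCA confidence-ellipsoid outlier detection
#'
#' Finds points that protrude from the main body of a cloud (for proteins:
#' effective atoms of disordered termini and other exposed fragments). Each
#' round aligns the current guide points with their principal axes, draws
#' the axis-aligned confidence ellipsoid with radii `s * sigma_d` (sigma_d =
#' per-axis population standard deviation of the guides, s from
#' [ellipsoid_radius_multiplier]), and marks the guides strictly outside the
#' ellipsoid as outliers. Points on the boundary remain guides. The loop
#' runs at most `r` rounds and terminates early when a round captures no new
#' outlier; once a point is an outlier it stays one. The final guide set is
#' then realigned so the returned transform diagonalises the guide
#' covariance exactly; with `r = 0` no point is flagged and the transform
#' aligns the full set.
#'
#' @param points a [point_cloud] or n x 3 matrix (n >= 4).
#' @param p confidence level (default 0.9).
#' @param r maximum number of rounds (default 3).
#' @return an object of class `outlier_result`: `guide_mask` (logical per
#'   point), `rotation`, `translation` (the final guide alignment, applied
#'   as `R x + t`), `rounds_used` and `aligned_points` (all input points in
#'   the final frame, a [point_cloud]).
#' @export
detect_outliers <- function(points, p = 0.9, r = 3) {
  pc <- as_point_cloud(points)
  n <- nrow(pc$coords)
  if (n < 4) stop("detect_outliers: need at least 4 points")
  stopifnot(r >= 0)
  s <- ellipsoid_radius_multiplier(p, 3)
  guide <- rep(TRUE, n)
  rounds_used <- 0L
  if (r > 0) {
    for (round in seq_len(r)) {
      al <- align_principal_axes(point_cloud(pc$coords[guide, , drop = FALSE]))
      rounds_used <- round
      sig <- sqrt(colMeans(al$points$coords^2))
      if (any(sig == 0)) {
        stop("detect_outliers: degenerate guide geometry")
      }
      all_aligned <- sweep(pc$coords %*% t(al$rotation), 2,
                           -al$translation)
      q <- rowSums(sweep(all_aligned, 2, s * sig, `/`)^2)
      new_out <- guide & q > 1
      if (!any(new_out)) break
      guide <- guide & !new_out
      if (!any(guide)) {
        stop("detect_outliers: all points eliminated (empty guide set)")
      }
    }
  }
  fin <- align_principal_axes(point_cloud(pc$coords[guide, , drop = FALSE]))
  aligned_all <- sweep(pc$coords %*% t(fin$rotation), 2, -fin$translation)
  structure(list(guide_mask = guide,
                 rotation = fin$rotation,
                 translation = fin$translation,
                 rounds_used = rounds_used,
                 aligned_points = point_cloud(aligned_all, pc$labels)),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat(sprintf("outlier_result: %d guides / %d outliers (%d rounds)\n",
              sum(x$guide_mask), sum(!x$guide_mask), x$rounds_used))
  invisible(x)
}
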