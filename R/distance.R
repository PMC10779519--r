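#' Shape-distance configuration
#'
#' The distance family combines the Manhattan distance of normalized ZC
#' descriptor vectors with geometric penalty factors: `z` (descriptors
#' only), `zd` (+ histogram distance), `zds` (* size factor), `zdv`
#' (* volume factor), `zdsv` (both). Values above 2 are clipped to 2 so all
#' metrics share the similarity-tier scale.
#'
#' @param metric one of `"z"`, `"zd"`, `"zds"`, `"zdv"`, `"zdsv"`.
#' @param gamma_s size-factor offset (default -0.05).
#' @param gamma_v volume-factor offset (default -0.1).
#' @param squared_histogram use the sum of squared differences instead of
#'   the Euclidean distance for the histogram term (sensitivity switch;
#'   default FALSE).
#' @return an object of class `distance_config`.
#' @export
distance_config <- function(metric = c("zdsv", "z", "zd", "zds", "zdv"),
                            gamma_s = -0.05, gamma_v = -0.1,
                            squared_histogram = FALSE) {
  metric <- match.arg(metric)
  structure(list(metric = metric, gamma_s = gamma_s, gamma_v = gamma_v,
                 squared_histogram = squared_histogram, clip_at = 2),
            class = "distance_config")
}

zcdv_values <- function(a, allow_raw) {
  if (inherits(a, "zcdv")) {
    if (!allow_raw && !isTRUE(a$normalized)) {
      stop("delta_z: descriptor vectors must be normalized ",
           "(or pass allow_raw = TRUE for raw comparisons)")
    }
    a$values
  } else {
    as.numeric(a)
  }
}

#' Manhattan distance of two ZC descriptor vectors
#'
#' The baseline shape distance: the sum of absolute descriptor differences.
#' For unit-sum normalized vectors it is bounded by 2, attained by one-hot
#' vectors concentrated at different indices. Raw (unnormalized) vectors are
#' accepted with `allow_raw = TRUE` for implementation-comparison use.
#'
#' @param a,b [zc_descriptors] objects (or plain numeric vectors) of equal
#'   length.
#' @param allow_raw permit unnormalized inputs (default FALSE).
#' @return the distance (>= 0; <= 2 for normalized inputs).
#' @export
delta_z <- function(a, b, allow_raw = FALSE) {
  va <- zcdv_values(a, allow_raw)
  vb <- zcdv_values(b, allow_raw)
  if (length(va) != length(vb)) {
    stop("delta_z: descriptor vectors have different lengths (",
         length(va), " vs ", length(vb), ")")
  }
  sum(abs(va - vb))
}

#' Distance between two smoothed residue-distance histograms
#'
#' Euclidean distance between the smoothed+normalized histogram vectors;
#' when the lengths differ the shorter histogram is padded with trailing
#' zeros. The normalization and the square root keep this term from
#' dominating the descriptor distance in the combined metrics. The
#' `squared` reading (sum of squared differences, no square root) is
#' available as a sensitivity switch.
#'
#' @param ha,hb smoothed `zc_histogram` objects with equal bin width.
#' @param squared use the sum of squared differences (default FALSE).
#' @return the distance (0 for identical histograms).
#' @export
delta_d <- function(ha, hb, squared = FALSE) {
  stopifnot(inherits(ha, "zc_histogram"), inherits(hb, "zc_histogram"))
  if (ha$state != "smoothed" || hb$state != "smoothed") {
    stop("delta_d: histograms must be smoothed+normalized first")
  }
  if (ha$bin_width != hb$bin_width) {
    stop("delta_d: histogram bin widths differ")
  }
  n <- max(length(ha$values), length(hb$values))
  va <- c(ha$values, rep(0, n - length(ha$values)))
  vb <- c(hb$values, rep(0, n - length(hb$values)))
  ss <- sum((va - vb)^2)
  if (squared) ss else sqrt(ss)
}

#' Size penalty factor
#'
#' For each axis the larger of the two size coefficients is divided by the
#' smaller, the offset `gamma_s` is added, and the three terms are
#' multiplied. Identical sizes give `(1 + gamma_s)^3`; a negative offset
#' lets the factor reward closely matched sizes.
#'
#' @param size_a,size_b [size_descriptor] triples (all entries > 0).
#' @param gamma_s offset (default -0.05).
#' @return the factor.
#' @export
delta_s <- function(size_a, size_b, gamma_s = -0.05) {
  a <- as.numeric(size_a); b <- as.numeric(size_b)
  stopifnot(length(a) == 3, length(b) == 3)
  if (any(a <= 0) || any(b <= 0)) {
    stop("delta_s: degenerate size (zero standard deviation)")
  }
  prod(pmax(a, b) / pmin(a, b) + gamma_s)
}

#' Volume penalty factor
#'
#' The larger mesh volume divided by the smaller, plus the offset
#' `gamma_v`.
#'
#' @param vol_a,vol_b mesh volumes (Å^3, > 0).
#' @param gamma_v offset (default -0.1).
#' @return the factor.
#' @export
delta_v <- function(vol_a, vol_b, gamma_v = -0.1) {
  if (!is.numeric(vol_a) || !is.numeric(vol_b) || vol_a <= 0 || vol_b <= 0) {
    stop("delta_v: volumes must be positive")
  }
  max(vol_a, vol_b) / min(vol_a, vol_b) + gamma_v
}

#' All shape-distance components for one pair
#'
#' @param fa,fb [protein_features] objects with matching moment order and
#'   histogram bin width.
#' @param cfg a [distance_config].
#' @return named list: `z`, `d`, `s`, `v`, `zd`, and the clipped combined
#'   value under `value` for `cfg$metric`.
#' @export
shape_distances <- function(fa, fb, cfg = distance_config()) {
  stopifnot(inherits(fa, "protein_features"),
            inherits(fb, "protein_features"),
            inherits(cfg, "distance_config"))
  if (fa$zcdv$order != fb$zcdv$order) {
    stop("shape_distances: moment orders differ")
  }
  z <- delta_z(fa$zcdv, fb$zcdv)
  d <- delta_d(fa$histogram, fb$histogram, squared = cfg$squared_histogram)
  s <- delta_s(fa$size, fb$size, cfg$gamma_s)
  v <- delta_v(fa$volume, fb$volume, cfg$gamma_v)
  zd <- z + d
  val <- switch(cfg$metric,
                z = z, zd = zd, zds = zd * s, zdv = zd * v,
                zdsv = zd * s * v)
  list(z = z, d = d, s = s, v = v, zd = zd,
       value = min(val, cfg$clip_at))
}

#' Combined shape distance
#'
#' The configured member of the distance family, clipped at 2.
#'
#' @inheritParams shape_distances
#' @return a scalar distance in `[0, 2]` (for the penalised metrics the
#'   pre-clip value may exceed 2 for dissimilar shapes).
#' @export
combined_distance <- function(fa, fb, cfg = distance_config()) {
  shape_distances(fa, fb, cfg)$value
}

TIER_LABELS <- c("very high similarity", "high similarity",
                 "medium similarity", "low similarity",
                 "very low similarity", "no similarity")
TIER_BOUNDS <- c(0, 0.2, 0.4, 0.6, 0.8, 1, 2)

#' Similarity tier of a clipped shape distance
#'
#' The six-tier scale for normalized-descriptor distances: Tier 1
#' `[0, 0.2)` "very high similarity" up to Tier 6 `[1, 2]` "no similarity".
#' Each tier is a half-open interval `[lower, upper)`; Tier 6 is closed at
#' 2.
#'
#' @param d a distance in `[0, 2]`.
#' @return list with `index` (1-6), `label`, `lower` and `upper`.
#' @export
similarity_tier <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0 || d > 2) {
    stop("similarity_tier: distance must lie in [0, 2]")
  }
  i <- min(findInterval(d, TIER_BOUNDS), 6L)
  list(index = as.integer(i), label = TIER_LABELS[i],
       lower = TIER_BOUNDS[i], upper = TIER_BOUNDS[i + 1])
}

#' Pairwise distance matrix
#'
#' Computes the configured shape distance for each of the n(n-1)/2
#' unordered pairs and mirrors it into a symmetric matrix with a zero
#' diagonal.
#'
#' @param features list of at least two [protein_features].
#' @param cfg a [distance_config].
#' @return symmetric numeric matrix, dimnames from feature metadata ids
#'   when available.
#' @export
pairwise_matrix <- function(features, cfg = distance_config()) {
  n <- length(features)
  if (n < 2) stop("pairwise_matrix: need at least 2 feature sets")
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- combined_distance(features[[i]], features[[j]],
                                              cfg)
    }
  }
  ids <- vapply(features, function(f) {
    id <- f$metadata$id
    if (is.null(id)) "" else as.character(id)
  }, "")
  if (all(nzchar(ids))) dimnames(m) <- list(ids, ids)
  m
}

#' ROC curve and AUROC for retrieval labels
#'
#' Sweeps the similarity threshold over the distances in ascending order
#' ("similar" means distance strictly below the threshold; tied distances
#' are grouped), and reports the false and true positive rates per
#' threshold with the trapezoidal area under the curve.
#'
#' @param pair_labels logical vector: TRUE for pairs from the same class.
#' @param pair_distances numeric vector of distances, aligned with the
#'   labels.
#' @return list with `fpr`, `tpr`, `thresholds` and `auroc`.
#' @export
roc_curve <- function(pair_labels, pair_distances) {
  stopifnot(length(pair_labels) == length(pair_distances))
  lab <- as.logical(pair_labels)
  np <- sum(lab); nn <- sum(!lab)
  if (np == 0 || nn == 0) {
    stop("roc_curve: need at least one positive and one negative pair")
  }
  ord <- order(pair_distances)
  d <- pair_distances[ord]
  l <- lab[ord]
  last <- cumsum(rle(d)$lengths)        # last index of each tied group
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  # point k: similar = distance < thresholds[k]; the first unique distance
  # captures nothing, Inf captures everything
  thresholds <- c(d[last], Inf)
  tpr <- c(0, tp) / np
  fpr <- c(0, fp) / nn
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = thresholds, auroc = auroc)
}

#' Operating points at the similarity-tier boundaries
#'
#' TPR and FPR of the retrieval when "similar" means distance below each
#' Table-of-tiers upper bound (0.2, 0.4, 0.6, 0.8, 1.0, 2.0) — the six
#' marker points drawn on the ROC curves.
#'
#' @inheritParams roc_curve
#' @return data frame with `bound`, `tpr`, `fpr`.
#' @export
tier_operating_points <- function(pair_labels, pair_distances) {
  lab <- as.logical(pair_labels)
  np <- sum(lab); nn <- sum(!lab)
  bounds <- TIER_BOUNDS[-1]
  tpr <- vapply(bounds, function(b) sum(lab & pair_distances < b) / np, 0)
  fpr <- vapply(bounds, function(b) sum(!lab & pair_distances < b) / nn, 0)
  data.frame(bound = bounds, tpr = tpr, fpr = fpr)
}

#' Positive and negative pair counts for grouped labels
#'
#' The labeling stage of the retrieval benchmark: pairs of structures from
#' the same group are the positives. With 450 groups of 5 conformations
#' this yields 4500 positive and 2,525,625 negative pairs.
#'
#' @param labels class label per structure.
#' @return list with `positive`, `negative` and `total` pair counts.
#' @export
label_pair_counts <- function(labels) {
  n <- length(labels)
  sizes <- table(labels)
  pos <- sum(sizes * (sizes - 1) / 2)
  total <- n * (n - 1) / 2
  list(positive = pos, negative = total - pos, total = total)
}
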