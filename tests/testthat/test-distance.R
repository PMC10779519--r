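test_that("descriptor distance is the Manhattan distance with the right bounds", {
  a <- c(0.5, 0.5, 0, 0)
  b <- c(0.25, 0.75, 0, 0)
  expect_equal(delta_z(a, a), 0)
  expect_equal(delta_z(a, b), 0.5)
  onehot1 <- c(1, 0, 0, 0); onehot2 <- c(0, 0, 1, 0)
  expect_equal(delta_z(onehot1, onehot2), 2)
  expect_error(delta_z(a, c(1, 0)), "lengths")
  raw <- structure(list(order = 2L, n = 0L, l = 0L, values = c(1, 2, 3, 4),
                        normalized = FALSE), class = "zcdv")
  expect_error(delta_z(raw, raw), "normalized")
  expect_equal(delta_z(raw, raw, allow_raw = TRUE), 0)
})

test_that("histogram distance is Euclidean with trailing-zero padding", {
  mk <- function(v) {
    h <- structure(list(values = v, bin_width = 2,
                        upper_limit = 2 * length(v), state = "smoothed"),
                   class = "zc_histogram")
    h
  }
  expect_equal(delta_d(mk(c(0.5, 0.5)), mk(c(0.5, 0.5))), 0)
  disjoint <- delta_d(mk(c(1, 0, 0)), mk(c(0, 0, 1)))
  expect_equal(disjoint, sqrt(2))
  long <- mk(c(0.2, 0.8, rep(0, 8)))
  short <- mk(c(0.2, 0.8))
  expect_equal(delta_d(long, short), 0)
  expect_equal(delta_d(mk(c(1, 0)), mk(c(0, 1)), squared = TRUE), 2)
  raw <- structure(list(values = c(1, 2), bin_width = 2, upper_limit = 4,
                        state = "raw"), class = "zc_histogram")
  expect_error(delta_d(raw, raw), "smoothed")
})

test_that("size and volume factors follow the ratio-plus-offset definitions", {
  s1 <- structure(c(5, 4, 3), class = "size_triple")
  expect_equal(delta_s(s1, s1, gamma_s = -0.05), 0.95^3)
  expect_equal(delta_s(s1, s1, gamma_s = -0.05), 0.857375)
  expect_equal(delta_s(s1, s1, gamma_s = 0), 1)
  s2 <- structure(c(2, 1, 1), class = "size_triple")
  s3 <- structure(c(1, 1, 1), class = "size_triple")
  expect_equal(delta_s(s2, s3, gamma_s = 0), 2)
  expect_error(delta_s(structure(c(0, 1, 1), class = "size_triple"), s1),
               "degenerate")
  expect_equal(delta_v(1000, 1000, gamma_v = -0.1), 0.9)
  expect_equal(delta_v(2000, 1000, gamma_v = -0.1), 1.9)
  expect_equal(delta_v(500, 500, gamma_v = 0), 1)
  expect_error(delta_v(0, 10), "positive")
})

test_that("combined distances assemble the family and clip at 2", {
  fa <- fake_features(c(4, 1, 0, 3), size = c(10, 8, 6), volume = 1000)
  fb <- fake_features(c(3, 2, 1, 2), size = c(10, 8, 6), volume = 1000,
                      hist_bins = c(0, 1, 5, 4, 1, 0))
  comp <- shape_distances(fa, fb, distance_config("zd"))
  expect_equal(comp$zd, comp$z + comp$d)
  expect_lt(comp$zd, 2)
  expect_equal(combined_distance(fa, fb, distance_config("zd")), comp$zd)
  # zds = zd * (1 + gamma_s)^3 for identical sizes
  expect_equal(combined_distance(fa, fb, distance_config("zds")),
               comp$zd * 0.857375)
  # a dissimilar pair with strong penalties clips to 2
  fc <- fake_features(c(0, 0, 0, 1), size = c(30, 8, 6), volume = 4000)
  expect_equal(combined_distance(fa, fc, distance_config("zdsv")), 2)
  # symmetry and zero self-distance for all five metrics
  for (m in c("z", "zd", "zds", "zdv", "zdsv")) {
    cfg <- distance_config(m)
    expect_equal(combined_distance(fa, fb, cfg),
                 combined_distance(fb, fa, cfg))
    self <- combined_distance(fa, fa, cfg)
    expect_lt(abs(self - if (m %in% c("z", "zd")) 0 else 0), 1e-12)
  }
})

test_that("a worked example: zd 0.5 with matched geometry lands mid-family", {
  # delta_z 0.5, identical histograms/sizes/volumes
  fa <- fake_features(c(2, 2, 0, 0))
  fb <- fake_features(c(1, 3, 0, 0))
  expect_equal(combined_distance(fa, fb, distance_config("z")), 0.5)
  expect_equal(combined_distance(fa, fb, distance_config("zds")),
               0.5 * 0.857375)
  expect_equal(combined_distance(fa, fb, distance_config("zdv")),
               0.5 * 0.9)
  expect_equal(combined_distance(fa, fb, distance_config("zdsv")),
               0.5 * 0.857375 * 0.9)
})

test_that("similarity tiers partition [0, 2] with half-open bounds", {
  expect_equal(similarity_tier(0)$index, 1)
  expect_equal(similarity_tier(0.201)$index, 2)
  expect_equal(similarity_tier(0.201)$label, "high similarity")
  expect_equal(similarity_tier(0.2)$index, 2)      # lower bound included
  expect_equal(similarity_tier(0.4 - 1e-12)$index, 2)
  expect_equal(similarity_tier(1)$index, 6)
  expect_equal(similarity_tier(2)$index, 6)        # closed at 2
  expect_error(similarity_tier(2.1), "\\[0, 2\\]")
  expect_error(similarity_tier(-0.1), "\\[0, 2\\]")
})

test_that("the pairwise matrix is symmetric with a zero diagonal", {
  set.seed(20)
  feats <- lapply(1:30, function(i) {
    fake_features(runif(4), size = sort(runif(3, 2, 12), decreasing = TRUE),
                  volume = runif(1, 500, 5000), id = paste0("s", i))
  })
  m <- pairwise_matrix(feats, distance_config("zdsv"))
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_equal(sum(upper.tri(m)), 435)   # 30 inputs give C(30, 2) pairs
  expect_error(pairwise_matrix(feats[1], distance_config()), "at least 2")
})

test_that("the ROC sweep matches brute force and external AUC on random instances", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    labels <- runif(n) < 0.3
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[1] <- FALSE
    # ties on purpose: quantised distances
    d <- round(runif(n) + labels * -0.2, 2)
    mine <- roc_curve(labels, d)
    oracle <- brute_force_roc(labels, d)
    expect_equal(mine$auroc, oracle$auroc, tolerance = 1e-12)
    expect_equal(mine$fpr, oracle$fpr)
    expect_equal(mine$tpr, oracle$tpr)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ext <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                            predictor = d,
                                            direction = ">",
                                            quiet = TRUE)))
      expect_equal(mine$auroc, ext, tolerance = 1e-12)
    }
  }
})

test_that("ROC endpoints behave: separation gives 1, ties give 1/2", {
  labels <- c(rep(TRUE, 10), rep(FALSE, 10))
  perfect <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  expect_equal(roc_curve(labels, perfect)$auroc, 1)
  expect_equal(roc_curve(labels, rep(0.5, 20))$auroc, 0.5)
  expect_error(roc_curve(rep(TRUE, 5), runif(5)), "positive and one negative")
})

test_that("grouped labeling counts positive and negative pairs correctly", {
  labels <- rep(seq_len(450), each = 5)
  pc <- label_pair_counts(labels)
  expect_equal(pc$positive, 4500)
  expect_equal(pc$negative, 2525625)
  expect_equal(pc$total, choose(2250, 2))
})

test_that("tier operating points count rates at the six boundaries", {
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  d <- c(0.1, 0.5, 0.3, 1.5)
  tp <- tier_operating_points(labels, d)
  expect_equal(nrow(tp), 6)
  expect_equal(tp$tpr, c(0.5, 0.5, 1, 1, 1, 1))
  expect_equal(tp$fpr, c(0, 0.5, 0.5, 0.5, 0.5, 1))
})
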