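test_that("the discrete sphere contains the expected lattice points", {
  se2 <- sphere_element(2)
  expect_equal(nrow(se2), 33)
  expect_true(all(rowSums(se2^2) <= 4))
  expect_equal(nrow(sphere_element(1)), 7)
  # symmetric: every offset has its negation
  expect_setequal(
    unname(apply(se2, 1, paste, collapse = ",")),
    unname(apply(-se2, 1, paste, collapse = ","))
  )
})

test_that("weight maps are linear back-projections of the classifier", {
  set.seed(1)
  tens <- lapply(1:25, function(i) array(rnorm(6 * 5 * 4), c(6, 5, 4)))
  mp <- fit_mpca(tens, 1.0)
  p <- prod(mp$core_dims)
  sel <- structure(
    list(indices = c(3L, 8L), fisher_scores = c(1, 0.5), k = 2L),
    class = "selected_features"
  )
  make_model <- function(w) {
    structure(
      list(view = "SA", w = w, b = 0, platt = c(intercept = 0, slope = 1),
        selected = sel, n_features = 2L
      ),
      class = "prognostic_model"
    )
  }
  m0 <- feature_weight_map(make_model(c(0, 0)), mp)
  expect_true(all(m0$weights == 0))

  m1 <- feature_weight_map(make_model(c(1, 0)), mp)
  m2 <- feature_weight_map(make_model(c(0, 2)), mp)
  m12 <- feature_weight_map(make_model(c(1, 2)), mp)
  expect_equal(m12$weights, m1$weights + m2$weights, tolerance = 1e-12)

  # a single feature back-projects to the rank-one outer product of its
  # mode basis vectors
  j <- mp$feature_order[sel$indices[1]]
  sub <- arrayInd(j, mp$core_dims)
  outer3 <- outer(
    outer(mp$mode_bases[[1]][, sub[1]], mp$mode_bases[[2]][, sub[2]]),
    mp$mode_bases[[3]][, sub[3]]
  )
  expect_equal(m1$weights, outer3, tolerance = 1e-10)

  # the map is the gradient of the decision value: <map, x - mean> = dv - b
  x <- tens[[3]]
  feats <- mpca_project(mp, x)[sel$indices]
  expect_equal(
    sum(m12$weights * (x - mp$mean_tensor)),
    sum(c(1, 2) * feats),
    tolerance = 1e-8
  )
})

test_that("closing with the sphere is extensive and clusters form correctly", {
  m <- array(FALSE, c(20, 20, 12))
  m[8:12, 8:12, 4:8] <- TRUE
  w <- array(0, c(20, 20, 12))
  w[m] <- 1
  w[2, 2, 1] <- 0.9 # isolated voxel
  w <- w + array(rnorm(length(w), sd = 1e-6), dim(w))
  smap <- structure(list(view = "SA", weights = w), class = "saliency_map")

  # threshold keeps the 126 strongest voxels; the isolated one is dropped by
  # min_size, the block survives as one cluster of exactly 125
  cl <- threshold_and_cluster(smap, percentile = 1 - 126 / sum(w > 0), min_size = 5)
  pos <- cl$clusters[cl$clusters$sign > 0, ]
  expect_equal(nrow(pos), 1)
  expect_equal(pos$size, 125)
  expect_true(all(cl$labels[m] == pos$id))
  expect_equal(pos$frame_min, 4)
  expect_equal(pos$frame_max, 8)

  # an isolated voxel with min_size above 1 yields no cluster
  w2 <- array(rnorm(20 * 20 * 12, sd = 1e-6), c(20, 20, 12))
  w2[5, 5, 5] <- 10
  s2 <- structure(list(view = "SA", weights = w2), class = "saliency_map")
  cl2 <- threshold_and_cluster(s2, percentile = 0.999, min_size = 40)
  expect_true(is.null(cl2$clusters) || !any(cl2$clusters$sign > 0 & cl2$clusters$size >= 40))

  # closing never removes mask voxels (extensivity)
  closed <- cinempca:::binary_closing(m, sphere_element(2))
  expect_true(all(closed[m]))
})

test_that("regional profiles aggregate signed weights per frame", {
  S <- 16
  T <- 6
  masks <- list(
    RV = matrix(FALSE, S, S), LV = matrix(FALSE, S, S), septum = matrix(FALSE, S, S)
  )
  masks$RV[2:5, 2:5] <- TRUE
  masks$LV[10:13, 10:13] <- TRUE
  masks$septum[7:9, 7:9] <- TRUE

  # uniform map: every profile is the constant
  su <- structure(list(view = "SA", weights = array(0.7, c(S, S, T))),
    class = "saliency_map"
  )
  pu <- temporal_regional_profile(su, masks)
  expect_true(all(pu$weight == 0.7))
  expect_equal(nrow(pu), 3 * T)

  # signal only in the septum at frames 3-4 peaks there, others stay flat
  w <- array(0, c(S, S, T))
  for (t in 3:4) w[, , t] <- masks$septum * 2
  ss <- structure(list(view = "SA", weights = w), class = "saliency_map")
  ps <- temporal_regional_profile(ss, masks)
  sep <- ps[ps$region == "septum", ]
  expect_true(which.max(sep$weight) %in% 3:4)
  expect_true(all(ps$weight[ps$region != "septum"] == 0))

  # permuting the mask order permutes rows only
  p2 <- temporal_regional_profile(ss, masks[c(3, 1, 2)])
  expect_equal(
    ps[order(ps$region, ps$frame), c("weight")],
    p2[order(p2$region, p2$frame), c("weight")],
    ignore_attr = TRUE
  )

  masks$LV[8, 8] <- TRUE # overlap with septum
  expect_error(temporal_regional_profile(ss, masks), "disjoint")
  expect_error(
    temporal_regional_profile(ss, list(a = matrix(FALSE, S, S))),
    "empty"
  )
})

test_that("overlays colour exactly the cluster voxels", {
  set.seed(2)
  S <- 24
  T <- 4
  anat <- array(runif(S * S * T), c(S, S, T))
  w <- array(rnorm(S * S * T, sd = 1e-4), c(S, S, T))
  w[4:8, 4:8, 2] <- 5
  w[15:19, 15:19, 2] <- -5
  smap <- structure(list(view = "SA", weights = w), class = "saliency_map")
  smap <- threshold_and_cluster(smap, percentile = 0.99, min_size = 10)
  dir <- withr::local_tempdir()
  paths <- overlay_saliency(anat, smap, frames = c(1, 2), dir = dir)
  expect_length(paths, 2)
  expect_true(all(file.exists(paths)))

  img2 <- png::readPNG(paths[2])
  pos <- smap$labels[, , 2] > 0
  neg <- smap$labels[, , 2] < 0
  pure_red <- img2[, , 1] == 1 & img2[, , 2] == 0 & img2[, , 3] == 0
  pure_blue <- img2[, , 3] == 1 & img2[, , 1] == 0 & img2[, , 2] == 0
  expect_identical(pure_red, pos)
  expect_identical(pure_blue, neg)

  # a frame without clusters renders as plain grayscale
  img1 <- png::readPNG(paths[1])
  expect_true(all(abs(img1[, , 1] - img1[, , 2]) < 1e-6))
  expect_true(all(abs(img1[, , 1] - img1[, , 3]) < 1e-6))

  expect_error(overlay_saliency(anat[1:10, , ], smap, 1, dir), "same space")
})

test_that("flipping the training labels flips every cluster sign", {
  co <- small_cohort()
  pp <- preprocess_studies(cohort_view(co, "SA"), target_size = 32)
  mp <- fit_mpca(unname(pp$tensors), 0.9)
  X <- t(vapply(pp$tensors, function(x) mpca_project(mp, x),
    numeric(prod(mp$core_dims))
  ))
  y <- co$truth$latent_risk > stats::median(co$truth$latent_risk)
  sel <- stepwise_select(X, y, tuning_size = 20, max_k = 8, seed = 3)
  m_pos <- train_svm(X[, sel$indices, drop = FALSE], y, selected = sel, seed = 3)
  m_neg <- train_svm(X[, sel$indices, drop = FALSE], !y, selected = sel, seed = 3)
  s_pos <- feature_weight_map(m_pos, mp)
  s_neg <- feature_weight_map(m_neg, mp)
  expect_equal(s_neg$weights, -s_pos$weights, tolerance = 1e-8)

  c_pos <- threshold_and_cluster(s_pos, min_size = 10)
  c_neg <- threshold_and_cluster(s_neg, min_size = 10)
  expect_identical(c_neg$labels != 0, c_pos$labels != 0)
  expect_identical(c_neg$labels > 0, c_pos$labels < 0)
  expect_identical(c_neg$labels < 0, c_pos$labels > 0)
})
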