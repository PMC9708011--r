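sa_landmarks <- function(x, y) {
  data.frame(
    label = c("superior_insertion_point", "rv_free_wall_inflexion", "mid_lv_lateral_wall"),
    x = x, y = y
  )
}

test_that("z-scoring standardises, is idempotent and affine-invariant", {
  set.seed(1)
  x <- array(rnorm(16 * 16 * 4, mean = 40, sd = 9), c(16, 16, 4))
  z <- zscore_standardize(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(stats::sd(z) - 1), 1e-10)
  expect_identical(dim(z), dim(x))
  expect_equal(zscore_standardize(z), z, tolerance = 1e-10)
  expect_equal(zscore_standardize(3.7 * x + 11), z, tolerance = 1e-10)
  expect_error(zscore_standardize(array(5, c(4, 4, 2))), "constant")
})

test_that("the Procrustes reference recovers the true configuration", {
  lm0 <- sa_landmarks(c(20, 40, 32), c(20, 25, 45))
  ref <- fit_reference(list(lm0, lm0, lm0), "SA")
  expect_equal(unname(ref$reference_landmarks),
    unname(as.matrix(lm0[, c("x", "y")])),
    tolerance = 1e-8
  )

  # rotated copies: residuals after alignment are equal and tiny
  p0 <- as.matrix(lm0[, c("x", "y")])
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p1 <- p0 %*% t(R)
  lm1 <- sa_landmarks(p1[, 1], p1[, 2])
  ref2 <- fit_reference(list(lm0, lm1), "SA")
  r0 <- fit_rigid_transform(p0, ref2$reference_landmarks)$rmsd
  r1 <- fit_rigid_transform(p1, ref2$reference_landmarks)$rmsd
  expect_equal(r0, r1, tolerance = 1e-8)
  expect_lt(r0, 1e-8)

  # jittered landmarks: mean configuration concentrates around the truth
  set.seed(2)
  s <- 1.5
  sets <- lapply(1:100, function(i) {
    sa_landmarks(lm0$x + rnorm(3, sd = s), lm0$y + rnorm(3, sd = s))
  })
  ref3 <- fit_reference(sets, "SA")
  expect_lt(max(abs(ref3$reference_landmarks - p0)), 3 * s / sqrt(100) * 3)

  expect_error(
    fit_reference(list(lm0, sa_landmarks(c(1, 2, 3), c(1, 2, 3))), "SA"),
    "collinear"
  )
})

test_that("rigid registration recovers constructed translations and rotations", {
  set.seed(3)
  lm0 <- sa_landmarks(c(20, 40, 32), c(20, 25, 45))
  ref <- fit_reference(list(lm0, lm0), "SA")
  img <- zscore_standardize(array(rnorm(64 * 64 * 3), c(64, 64, 3)))

  # identity
  reg0 <- register_to_reference(img, lm0, ref)
  expect_lt(abs(reg0$transform[["angle"]]), 1e-10)
  expect_lt(max(abs(reg0$transform[c("tx", "ty")])), 1e-9)
  expect_equal(reg0$tensor, img, tolerance = 1e-6)

  # translation by (+5, -3): recovered transform is (-5, +3)
  lm_t <- sa_landmarks(lm0$x + 5, lm0$y - 3)
  reg_t <- register_to_reference(img, lm_t, ref)
  expect_equal(unname(reg_t$transform[c("tx", "ty")]), c(-5, 3), tolerance = 1e-6)

  # rotation by 30 degrees about the landmark centroid: recovered -30
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p0 <- as.matrix(lm0[, c("x", "y")])
  cen <- colMeans(p0)
  p_r <- sweep(sweep(p0, 2, cen) %*% t(R), 2, cen, "+")
  reg_r <- register_to_reference(img, sa_landmarks(p_r[, 1], p_r[, 2]), ref)
  expect_equal(reg_r$transform[["angle"]] * 180 / pi, -30, tolerance = 0.1)

  # the fitted transform beats a grid of perturbed rigid transforms
  fitted <- fit_rigid_transform(p_r, ref$reference_landmarks)
  for (da in c(-5, -2, 2, 5) * pi / 180) {
    for (dt in list(c(-2, 0), c(2, 0), c(0, -2), c(0, 2))) {
      Rp <- matrix(c(cos(fitted$angle + da), sin(fitted$angle + da),
        -sin(fitted$angle + da), cos(fitted$angle + da)
      ), 2, 2)
      moved <- p_r %*% t(Rp) + matrix(fitted$t + dt, 3, 2, byrow = TRUE)
      res <- sqrt(mean(rowSums((moved - ref$reference_landmarks)^2)))
      expect_gt(res, fitted$rmsd)
    }
  }

  bad <- lm0
  bad$label[1] <- "unknown"
  expect_error(register_to_reference(img, bad, ref), "labels")
})

test_that("elliptical masking zeroes the outside and keeps the inside", {
  lm0 <- sa_landmarks(c(20, 44, 32), c(18, 26, 46))
  ref <- fit_reference(list(lm0, lm0), "SA")
  x <- array(1, c(64, 64, 3))

  # covering ellipse: identity
  ref_big <- ref
  ref_big$mask_params <- list(center = c(31.5, 31.5), semi_axes = c(200, 200), orientation = 0)
  expect_equal(as.vector(apply_elliptical_mask(x, ref_big)), as.vector(x))

  # pixel count matches the ellipse area within 2%
  ref_ab <- ref
  ref_ab$mask_params <- list(center = c(31.5, 31.5), semi_axes = c(20, 12), orientation = 0)
  masked <- apply_elliptical_mask(x, ref_ab)
  expect_lt(abs(sum(masked[, , 1]) - pi * 20 * 12) / (pi * 20 * 12), 0.02)
  # centre voxel retained, outside voxels exactly zero in every frame
  expect_equal(masked[32, 32, 2], 1)
  expect_true(all(masked[1, , ] == 0))

  ref_none <- ref
  ref_none$mask_params <- list(center = c(-500, -500), semi_axes = c(3, 3), orientation = 0)
  expect_error(apply_elliptical_mask(x, ref_none), "no voxels")
})

test_that("local-mean downsampling preserves means and composes", {
  x <- array(rnorm(256 * 256 * 3), c(256, 256, 3))
  y <- downsample_tensor(x, 32)
  expect_identical(dim(y), c(32L, 32L, 3L))
  expect_equal(mean(y), mean(x), tolerance = 1e-12)

  cst <- downsample_tensor(array(4.2, c(64, 64, 5)), 32)
  expect_true(all(cst == 4.2))

  a <- downsample_tensor(downsample_tensor(x, 128), 64)
  b <- downsample_tensor(x, 64)
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(b^2)), 0.05)

  expect_error(downsample_tensor(x, 48), "target_size")
  expect_error(downsample_tensor(array(0, c(16, 16, 2)), 32), "exceeds")
})

test_that("the full chain keeps the fixed stage order and mask invariant", {
  co <- small_cohort()
  pp <- preprocess_studies(cohort_view(co, "SA")[1:10], target_size = 32)
  expect_identical(dim(pp$tensors[[1]]), c(32L, 32L, 10L))
  # masked-out corners are exactly zero across all frames
  expect_true(all(pp$tensors[[1]][1, 1, ] == 0))
  expect_true(all(pp$tensors[[5]][32, 32, ] == 0))
  expect_equal(nrow(pp$transforms), 10)
  # a frozen reference reproduces identical outputs for the same study
  pp2 <- preprocess_studies(cohort_view(co, "SA")[1:10],
    target_size = 32, reference = pp$reference
  )
  expect_identical(pp$tensors, pp2$tensors)
})
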