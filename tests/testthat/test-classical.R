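test_that("group GLM reproduces hand-computed one-sample statistics", {
  vals <- c(0.2, 0.4, 0.6, 0.8)
  arrs <- lapply(vals, function(v) {
    a <- array(rnorm(27), dim = c(3, 3, 3)); a[2, 2, 2] <- v; a
  })
  set.seed(3)
  glm <- fit_group_glm(images_from_arrays(arrs))
  expect_equal(glm$beta_hat$values[2, 2, 2], 0.5)
  expect_equal(glm$resid_var$values[2, 2, 2], var(vals))
  expect_equal(glm$tmap$values[2, 2, 2], 0.5 / sqrt(var(vals) / 4),
               tolerance = 1e-12)
  expect_equal(glm$tmap$values[2, 2, 2], 3.873, tolerance = 1e-3)
  expect_equal(glm$df, 3L)
})

test_that("degenerate voxels follow the zero-variance convention", {
  a1 <- array(0, dim = c(2, 2, 2)); a2 <- a1
  a1[1, 1, 1] <- 1; a2[1, 1, 1] <- 1 # equal nonzero values
  glm <- fit_group_glm(images_from_arrays(list(a1, a2)))
  expect_equal(glm$tmap$values[2, 2, 2], 0)       # all zero
  expect_equal(glm$tmap$values[1, 1, 1], Inf)     # constant nonzero
  expect_true(glm$zero_var[1, 1, 1])
  expect_false(glm$usable[1, 1, 1])
  expect_error(fit_group_glm(images_from_arrays(list(a1))), "at least 2")
})

test_that("t-map equals a brute-force per-voxel computation", {
  set.seed(17)
  for (rep in 1:3) {
    n <- sample(3:8, 1)
    arrs <- lapply(seq_len(n), function(i)
      array(rnorm(125), dim = c(5, 5, 5)))
    glm <- fit_group_glm(images_from_arrays(arrs))
    Y <- simplify2array(arrs) # 5x5x5xn
    t_oracle <- apply(Y, 1:3, function(v) mean(v) / (sd(v) / sqrt(n)))
    expect_equal(glm$tmap$values, t_oracle, tolerance = 1e-12)
  }
})

test_that("EC densities reduce to the t survival function in 0-D", {
  u <- seq(-2, 10, by = 0.25)
  expect_equal(expected_euler(u, 15, c(1, 0, 0, 0)),
               pt(u, 15, lower.tail = FALSE), tolerance = 1e-10)
  # vanishing at high thresholds, for full resel vectors too
  resels <- c(1, 30, 300, 1200)
  expect_lt(expected_euler(40, 15, resels), 1e-6)
  # nonincreasing in the high-threshold regime where EC approximates FWE
  eg <- expected_euler(seq(2.5, 10, by = 0.05), 15, resels)
  expect_true(all(diff(eg) <= 0))
})

test_that("voxelwise FWE threshold honours its limiting cases", {
  # single voxel, point search region: no multiplicity
  expect_equal(fwe_voxel_threshold(15, c(1, 0, 0, 0), V = 1, alpha = 0.05),
               qt(0.05, 15, lower.tail = FALSE), tolerance = 1e-6)
  # negligible resels: Bonferroni rules
  tb <- fwe_voxel_threshold(15, c(0, 0, 0, 1e-12), V = 1000, alpha = 0.05)
  expect_equal(tb, qt(0.05 / 1000, 15, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_gt(tb, 5); expect_lt(tb, 5.5)
  # threshold tightens as df falls
  resels <- c(1, 20, 150, 800)
  ts <- vapply(3:30, fwe_voxel_threshold, numeric(1), resels = resels,
               V = 20000, alpha = 0.05)
  expect_true(all(diff(ts) <= 1e-9))
})

test_that("resel counts match the box-mask closed form", {
  grid <- volume_grid(c(10, 10, 10), c(2, 2, 2))
  mask <- brain_mask(array(TRUE, dim = c(10, 10, 10)), grid)
  r <- resel_counts(mask, c(2, 2, 2))
  expect_equal(unname(r[4]), 1000 / 8, tolerance = 1e-9)
  expect_equal(unname(r[1]), 1) # Euler characteristic of a solid box
  expect_error(resel_counts(mask, c(0, 2, 2)))
})

test_that("smoothness estimation recovers the kernel FWHM", {
  # white noise: forward differences put the floor at sqrt(2 log 2) ~ 1.18
  est_w <- vapply(1:5, function(s) {
    ds <- generate_subject_images(synthetic_spec(
      grid_shape = c(20, 20, 20), mask_shape = "box", n_subjects = 8,
      smooth_fwhm_voxels = 0, seed = 400 + s))
    glm <- fit_group_glm(ds)
    estimate_smoothness(glm, ds)$fwhm_voxels
  }, numeric(3))
  expect_true(all(abs(rowMeans(est_w) - sqrt(2 * log(2))) < 0.1))

  # smoothed at FWHM 3: estimate within [2.5, 3.5] per axis
  est_s <- vapply(1:10, function(s) {
    ds <- generate_subject_images(synthetic_spec(
      grid_shape = c(30, 30, 24), mask_shape = "box", n_subjects = 8,
      smooth_fwhm_voxels = 3, seed = 500 + s))
    glm <- fit_group_glm(ds)
    estimate_smoothness(glm, ds)$fwhm_voxels
  }, numeric(3))
  expect_true(all(est_s >= 2.5 & est_s <= 3.5))

  # n = 2 cannot support residual smoothness estimation
  ds2 <- generate_subject_images(synthetic_spec(
    grid_shape = c(12, 12, 10), n_subjects = 2, seed = 1))
  expect_error(estimate_smoothness(fit_group_glm(ds2), ds2), "n >= 3")
})

test_that("clusterwise inference handles empty and extreme extents", {
  # null-ish data thresholded very high: empty result, not an error
  ds <- generate_subject_images(synthetic_spec(
    grid_shape = c(16, 16, 12), mask_shape = "box", n_subjects = 6,
    smooth_fwhm_voxels = 2, seed = 31))
  glm <- fit_group_glm(ds)
  sm <- estimate_smoothness(glm, ds)
  res <- clusterwise_inference(glm, sm, classical_spec(
    "clusterwise", cdt_p = 1e-9))
  expect_equal(survived_count(res), 0L)
  expect_equal(nrow(res$clusters), 0L)

  # cluster FWE p decreases monotonically with extent and respects the
  # Poisson bound 1 - exp(-E[m]) as extent -> 0
  u <- qt(0.001, 15, lower.tail = FALSE)
  resels <- c(1, 20, 150, 800)
  k <- c(0.01, 0.1, 0.5, 1, 2, 5, 10, 50)
  p <- vapply(k, bayesppm:::cluster_fwe_p, numeric(1), u = u, df = 15,
              resels = resels)
  expect_true(all(diff(p) < 0))
  Em <- expected_euler(u, 15, resels)
  expect_true(all(p <= 1 - exp(-Em) + 1e-12))
  expect_lt(p[length(p)], 1e-6)
})

test_that("voxelwise FWE set is nested in the uncorrected CDT set", {
  ds <- small_blob_dataset(seed = 77)
  glm <- fit_group_glm(ds)
  sm <- estimate_smoothness(glm, ds)
  vox <- voxelwise_inference(glm, sm, classical_spec("voxelwise_fwe"))
  cdt <- glm$tmap$values > qt(0.001, glm$df, lower.tail = FALSE)
  expect_true(all(!vox$active | cdt))
  expect_gte(vox$thresholds_used$t_star,
             qt(0.001, glm$df, lower.tail = FALSE))
})

test_that("a strong planted effect survives voxelwise FWE", {
  ds <- small_blob_dataset(seed = 7, d_true = 2)
  glm <- fit_group_glm(ds)
  sm <- estimate_smoothness(glm, ds)
  vox <- voxelwise_inference(glm, sm, classical_spec("voxelwise_fwe"))
  expect_gt(sum(vox$active & ds$truth$active), 0)
  # and the cluster route finds it too, with a significant extent
  clu <- clusterwise_inference(glm, sm, classical_spec("clusterwise"))
  expect_gt(survived_count(clu), 0)
  expect_true(any(clu$clusters_candidate$fwe_p < 0.05))
})
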