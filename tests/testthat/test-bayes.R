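test_that("moments estimator of cB follows its closed form and clamps", {
  # Var_v(beta) = 0.5, mean resid_var/n = 0.2 -> cB = 0.3
  glm <- fake_glm(beta = c(0, 1), resid_var = c(0.8, 0.8), n = 4)
  expect_equal(estimate_prior_variance(glm)$cB, 0.5 - 0.2)
  # Var_v(beta) = 0.1 < 0.2 -> clamped at 0
  glm2 <- fake_glm(beta = c(0, sqrt(0.2)), resid_var = c(0.8, 0.8), n = 4)
  expect_equal(estimate_prior_variance(glm2)$cB, 0)
  expect_error(estimate_prior_variance(fake_glm(1, 1, 4)), "at least 2")
  expect_error(estimate_prior_variance(glm, method = "reml"),
               "not implemented")
})

test_that("cB is recovered from hierarchical-model simulations", {
  set.seed(12)
  V <- 20000; n <- 16; cB <- 0.25
  est <- vapply(1:10, function(i) {
    beta <- rnorm(V, 0, sqrt(cB))
    Y <- matrix(rnorm(V * n, beta, 1), V, n)
    m <- rowMeans(Y)
    v <- rowSums((Y - m)^2) / (n - 1)
    glm <- fake_glm(array(m, c(V, 1, 1)), array(v, c(V, 1, 1)), n)
    estimate_prior_variance(glm)$cB
  }, numeric(1))
  expect_lt(abs(mean(est) / cB - 1), 0.05)
})

test_that("effect-size thresholds scale the prior SD by Cohen's d", {
  prior <- shrinkage_prior(sd = 0.0518)
  expect_identical(es_threshold(prior, 0.5), 0.0259)
  expect_identical(es_threshold(prior, 1.0), 0.0518)
  expect_equal(es_threshold(prior, 0.2), 0.2 * 0.0518)
  expect_equal(es_threshold(shrinkage_prior(cB = 0), 0.8), 0)
  expect_error(es_threshold(prior, 0))
  expect_error(shrinkage_prior(cB = 1, sd = 1), "exactly one")
})

test_that("conjugate posterior matches the worked example and limits", {
  glm <- fake_glm(beta = c(0.5, 0), resid_var = c(1, 1), n = 16)
  post <- compute_posterior(glm, shrinkage_prior(cB = 0.25))
  expect_equal(post$post_var$values[1, 1, 1], 0.05, tolerance = 1e-12)
  expect_equal(post$post_mean$values[1, 1, 1], 0.4, tolerance = 1e-12)
  expect_identical(post$post_mean$values[2, 1, 1], 0) # zero mean stays zero

  # flat-prior limit: posterior reverts to the sampling distribution
  flat <- compute_posterior(glm, shrinkage_prior(cB = 1e12))
  expect_equal(flat$post_mean$values[1, 1, 1], 0.5, tolerance = 1e-6)
  expect_equal(flat$post_var$values[1, 1, 1], 1 / 16, tolerance = 1e-6)

  expect_error(compute_posterior(glm, shrinkage_prior(cB = 0)),
               "degenerate prior")
})

test_that("posterior identities hold against an independent closed form", {
  set.seed(101)
  m <- 10000
  beta <- rnorm(m); v <- rexp(m) + 0.01
  n <- sample(4:40, m, replace = TRUE)
  cB <- rexp(m) + 0.01
  for (i in c(1:50, sample(m, 200))) {
    glm <- fake_glm(beta[i], v[i], n[i])
    post <- compute_posterior(glm, shrinkage_prior(cB = cB[i]))
    # independent route: shrinkage-weight form of the conjugate update
    w <- cB[i] / (cB[i] + v[i] / n[i])
    expect_equal(post$post_mean$values[1, 1, 1], w * beta[i],
                 tolerance = 1e-10)
    expect_equal(post$post_var$values[1, 1, 1], w * v[i] / n[i],
                 tolerance = 1e-10)
  }
  # vectorised check of all 10^4 tuples through the formulas themselves
  pv <- 1 / (1 / cB + n / v)
  pm <- pv * (n / v) * beta
  expect_equal(pm, beta * cB / (cB + v / n), tolerance = 1e-10)
  expect_equal(pv, (cB * v / n) / (cB + v / n), tolerance = 1e-10)
})

test_that("log odds follow the normal posterior tail", {
  glm <- fake_glm(beta = c(0.5, 0.25), resid_var = c(1, 1), n = 16)
  post <- compute_posterior(glm, shrinkage_prior(cB = 0.25))
  lo <- log_odds_map(post, gamma = 0.25)
  # worked case: post N(0.4, 0.05), gamma 0.25
  z <- (0.25 - 0.4) / sqrt(0.05)
  p1 <- pnorm(z, lower.tail = FALSE)
  expect_equal(lo$values[1, 1, 1], log(p1 / (1 - p1)), tolerance = 1e-10)
  expect_equal(lo$values[1, 1, 1], 1.092, tolerance = 1e-3)
  # gamma equal to the posterior mean gives even odds
  expect_equal(log_odds_map(post, gamma = 0.2)$values[2, 1, 1], 0,
               tolerance = 1e-10)
  # strictly decreasing in gamma
  los <- vapply(seq(0, 1, by = 0.05), function(g)
    log_odds_map(post, g)$values[1, 1, 1], numeric(1))
  expect_true(all(diff(los) < 0))
  # clipping bounds extreme evidence
  glm2 <- fake_glm(beta = 100, resid_var = 0.01, n = 16)
  post2 <- compute_posterior(glm2, shrinkage_prior(cB = 1e4))
  expect_equal(log_odds_map(post2, 0.1)$values[1, 1, 1], 40)
  expect_error(log_odds_map(post, gamma = -1))
})

test_that("posterior maps shrink toward zero everywhere", {
  ds <- small_blob_dataset(seed = 55)
  glm <- fit_group_glm(ds)
  prior <- estimate_prior_variance(glm)
  post <- compute_posterior(glm, prior)
  use <- glm$usable
  expect_true(all(abs(post$post_mean$values[use]) <=
                    abs(glm$beta_hat$values[use]) + 1e-12))
  expect_true(all(post$post_var$values[use] <=
                    pmin(prior$cB, glm$resid_var$values[use] / glm$n) +
                    1e-12))
  expect_true(all(post$post_var$values[use] > 0))
})

test_that("active sets are nested across tau and across d", {
  ds <- small_blob_dataset(seed = 91, d_true = 1.5)
  glm <- fit_group_glm(ds)
  prior <- estimate_prior_variance(glm)
  post <- compute_posterior(glm, prior)
  gamma <- es_threshold(prior, 0.5)
  lo <- log_odds_map(post, gamma)
  act <- lapply(c(3, 5, 10), function(tau)
    bayes_threshold(lo, bayes_spec(d = 0.5, tau = tau, gamma = gamma),
                    ds$mask)$active)
  expect_true(all(!act[[3]] | act[[2]]))
  expect_true(all(!act[[2]] | act[[1]]))
  act_d <- lapply(c(0.2, 0.5, 0.8), function(d) {
    g <- es_threshold(prior, d)
    bayes_threshold(log_odds_map(post, g),
                    bayes_spec(d = d, tau = 3, gamma = g), ds$mask)$active
  })
  expect_true(all(!act_d[[3]] | act_d[[2]]))
  expect_true(all(!act_d[[2]] | act_d[[1]]))
})

test_that("extent filtering drops small clusters only when requested", {
  ds <- small_blob_dataset(seed = 14, d_true = 2)
  glm <- fit_group_glm(ds)
  res0 <- bayes_inference(glm, bayes_spec(d = 0.5, tau = 3))
  big <- max(res0$clusters$size_voxels)
  res_k <- bayes_inference(glm, bayes_spec(d = 0.5, tau = 3,
                                           extent_voxels = big))
  expect_true(all(res_k$clusters$size_voxels >= big))
  expect_lte(survived_count(res_k), survived_count(res0))
})

test_that("in-blob evidence accumulates with sample size", {
  ds <- small_blob_dataset(seed = 23, d_true = 2, n = 16)
  mean_lo <- vapply(c(4, 8, 16), function(n) {
    sub <- subject_image_set(ds$images[seq_len(n)], ds$mask)
    glm <- fit_group_glm(sub)
    res <- bayes_inference(glm, bayes_spec(d = 0.5, tau = 5))
    mean(res$logodds$values[ds$truth$active])
  }, numeric(1))
  expect_true(!is.unsorted(mean_lo))
})
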