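#' One-sample group GLM on contrast images
#'
#' Mass-univariate second-level model: at each voxel the n subject contrast
#' values are one sample; the fit returns the sample mean, the unbiased
#' sample variance (divisor n - 1), and t = mean / sqrt(var / n) with
#' df = n - 1. Degenerate voxels follow the convention: var = 0 and
#' mean = 0 gives t = 0; var = 0 and mean != 0 gives t = +/-Inf and the
#' voxel is flagged (`zero_var`) and excluded from smoothness and prior
#' estimation.
#'
#' @param images a `subject_image_set`.
#' @return An object of class `group_glm_result` with fields `beta_hat`,
#'   `resid_var`, `tmap` (all [stat_volume()]), `df`, `n`, `mask`,
#'   `zero_var` (logical array), `usable` (in-mask voxels with positive
#'   variance).
#' @export
fit_group_glm <- function(images) {
  stopifnot(inherits(images, "subject_image_set"))
  n <- length(images$images)
  if (n < 2L) stop("need at least 2 images")
  grid <- images$grid
  Y <- vapply(images$images, function(im) as.numeric(im$values),
              numeric(prod(grid$shape)))
  m <- rowMeans(Y)
  v <- rowSums((Y - m)^2) / (n - 1)
  t <- rep(0, length(m))
  pos <- v > 0
  t[pos] <- m[pos] / sqrt(v[pos] / n)
  zero_var <- !pos & m != 0
  t[zero_var] <- sign(m[zero_var]) * Inf
  inside <- as.vector(images$mask$inside)
  usable <- array(inside & pos, dim = grid$shape)
  structure(list(
    beta_hat = stat_volume(array(m, dim = grid$shape), grid, "contrast"),
    resid_var = stat_volume(array(v, dim = grid$shape), grid, "contrast"),
    tmap = stat_volume(array(t, dim = grid$shape), grid, "t"),
    df = n - 1L, n = n, mask = images$mask,
    zero_var = array(zero_var, dim = grid$shape),
    usable = usable), class = "group_glm_result")
}

#' @export
print.group_glm_result <- function(x, ...) {
  cat(sprintf("group_glm_result: n = %d, df = %d, V = %d\n",
              x$n, x$df, x$mask$V))
  invisible(x)
}

# counts of in-mask points, edges, faces and cubes of the voxel lattice
mask_topology <- function(inside) {
  d <- dim(inside)
  sx <- inside[-d[1], , , drop = FALSE] & inside[-1, , , drop = FALSE]
  sy <- inside[, -d[2], , drop = FALSE] & inside[, -1, , drop = FALSE]
  sz <- inside[, , -d[3], drop = FALSE] & inside[, , -1, drop = FALSE]
  fxy <- sx[, -d[2], , drop = FALSE] & sx[, -1, , drop = FALSE]
  fxz <- sx[, , -d[3], drop = FALSE] & sx[, , -1, drop = FALSE]
  fyz <- sy[, , -d[3], drop = FALSE] & sy[, , -1, drop = FALSE]
  cub <- fxy[, , -d[3], drop = FALSE] & fxy[, , -1, drop = FALSE]
  list(P = sum(inside), Ex = sum(sx), Ey = sum(sy), Ez = sum(sz),
       Fxy = sum(fxy), Fxz = sum(fxz), Fyz = sum(fyz), C = sum(cub))
}

#' Resel counts of a search region
#'
#' Summarises the mask geometry relative to the field smoothness as resel
#' ("resolution element") counts R0..R3. R0 is the Euler characteristic of
#' the mask and R1/R2 come from the standard lattice point/edge/face/cube
#' counting; R3 is the mask volume in FWHM-cubes, `V * prod(1/fwhm)`.
#'
#' @param mask a [brain_mask()].
#' @param fwhm_voxels per-axis smoothness FWHM in voxels (length 3).
#' @return Numeric vector `c(R0, R1, R2, R3)`.
#' @export
resel_counts <- function(mask, fwhm_voxels) {
  stopifnot(length(fwhm_voxels) == 3L, all(fwhm_voxels > 0))
  tp <- mask_topology(mask$inside)
  r <- 1 / fwhm_voxels
  R0 <- tp$P - (tp$Ex + tp$Ey + tp$Ez) + (tp$Fxy + tp$Fxz + tp$Fyz) - tp$C
  R1 <- (tp$Ex - tp$Fxy - tp$Fxz + tp$C) * r[1] +
    (tp$Ey - tp$Fxy - tp$Fyz + tp$C) * r[2] +
    (tp$Ez - tp$Fxz - tp$Fyz + tp$C) * r[3]
  R2 <- (tp$Fxy - tp$C) * r[1] * r[2] + (tp$Fxz - tp$C) * r[1] * r[3] +
    (tp$Fyz - tp$C) * r[2] * r[3]
  R3 <- tp$P * r[1] * r[2] * r[3]
  c(R0 = R0, R1 = R1, R2 = R2, R3 = R3)
}

#' Estimate field smoothness from standardized residuals
#'
#' Per-axis FWHM of the error field, estimated from the variance of forward
#' spatial differences of the standardized residual fields: with
#' `lambda_axis = pooled Var(d e / d axis) / Var(e)`,
#' `FWHM_axis = sqrt(4 log 2 / lambda_axis)` voxels. Residuals are
#' standardized per voxel to unit sum of squares across subjects, and
#' pooling runs over all in-mask voxel pairs adjacent along the axis.
#' Unsmoothed white noise yields FWHM about 1.18 voxels (the
#' forward-difference floor), not 0.
#'
#' @param glm a `group_glm_result`.
#' @param images the `subject_image_set` the GLM was fitted to.
#' @return An object of class `smoothness_estimate` with `fwhm_voxels`
#'   (length 3), `resels` (R0..R3 via [resel_counts()]), and `lambda`.
#' @export
estimate_smoothness <- function(glm, images) {
  n <- glm$n
  if (n < 3L) stop("smoothness estimation needs n >= 3")
  grid <- images$grid
  use <- glm$usable
  m <- glm$beta_hat$values
  ssr <- glm$resid_var$values * (n - 1)
  lam <- numeric(3)
  U <- lapply(images$images, function(im) {
    u <- (im$values - m) / sqrt(ssr)
    u[!use] <- NA_real_
    u
  })
  for (axis in 1:3) {
    pair <- use & shift_pad(use, axis)
    if (!any(pair)) stop("unsmooth-estimable: no in-mask pairs along axis ",
                         axis)
    s2 <- 0
    for (u in U) {
      d <- shift_pad(u, axis) - u
      s2 <- s2 + sum(d[pair]^2)
    }
    lam[axis] <- s2 / sum(pair)
    if (!is.finite(lam[axis]) || lam[axis] <= 0)
      stop("unsmooth-estimable: degenerate residual field along axis ", axis)
  }
  fwhm <- sqrt(4 * log(2) / lam)
  structure(list(fwhm_voxels = fwhm,
                 resels = resel_counts(glm$mask, fwhm),
                 lambda = lam),
            class = "smoothness_estimate")
}

# like shift1 but keeps the original shape, padding with FALSE/NA
shift_pad <- function(a, axis) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else NA_real_, dim = d)
  switch(axis,
         out[seq_len(d[1] - 1), , ] <- a[-1, , , drop = FALSE],
         out[, seq_len(d[2] - 1), ] <- a[, -1, , drop = FALSE],
         out[, , seq_len(d[3] - 1)] <- a[, , -1, drop = FALSE])
  out
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("smoothness_estimate: FWHM = (%s) voxels, R3 = %.1f resels\n",
              paste(sprintf("%.2f", x$fwhm_voxels), collapse = ", "),
              x$resels[4]))
  invisible(x)
}

# d-dimensional Euler characteristic densities of a Student-t field
# (Worsley et al. 1996), as used for random-field-theory FWE control
t_ec_density <- function(u, df, d) {
  base <- (1 + u^2 / df)^(-(df - 1) / 2)
  switch(d + 1L,
         stats::pt(u, df, lower.tail = FALSE),
         sqrt(4 * log(2)) / (2 * pi) * base,
         (4 * log(2)) / (2 * pi)^1.5 * base * u *
           exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2),
         (4 * log(2))^1.5 / (2 * pi)^2 * base *
           ((df - 1) / df * u^2 - 1))
}

#' Expected Euler characteristic of a thresholded t field
#'
#' `E[EC(u)] = sum_d R_d rho_d(u, df)` with `rho_d` the d-dimensional EC
#' densities of a Student-t random field. For high thresholds this
#' approximates the familywise probability of any suprathreshold voxel.
#'
#' @param u t-value threshold (vectorised).
#' @param df degrees of freedom (>= 1).
#' @param resels resel counts R0..R3 (length 4), e.g. from
#'   [resel_counts()].
#' @return Expected Euler characteristic at each `u`.
#' @export
expected_euler <- function(u, df, resels) {
  stopifnot(df >= 1, length(resels) == 4L)
  resels[1] * t_ec_density(u, df, 0L) +
    resels[2] * t_ec_density(u, df, 1L) +
    resels[3] * t_ec_density(u, df, 2L) +
    resels[4] * t_ec_density(u, df, 3L)
}

#' Voxelwise FWE-corrected t threshold
#'
#' The familywise threshold is the smaller of the random-field-theory
#' threshold (the `u` solving `E[EC(u)] = alpha`, found by bisection on
#' [0, 50] to 1e-8) and the Bonferroni threshold at `alpha / V`, mirroring
#' the standard SPM behaviour; it is never below the uncorrected one-sided
#' threshold at `alpha`.
#'
#' @param df degrees of freedom.
#' @param resels resel counts R0..R3.
#' @param V number of in-mask voxels.
#' @param alpha familywise error rate (default 0.05).
#' @return The corrected t threshold.
#' @export
fwe_voxel_threshold <- function(df, resels, V, alpha = 0.05) {
  stopifnot(V >= 1, alpha > 0, alpha < 1)
  t_bonf <- stats::qt(alpha / V, df, lower.tail = FALSE)
  f <- function(u) expected_euler(u, df, resels) - alpha
  # E[EC] is unimodal in u (the 3-D density term is negative near 0), so
  # bracket the high-threshold root from the last u with f > 0
  grid_u <- seq(0, 50, by = 0.25)
  fg <- f(grid_u)
  t_rft <- if (fg[length(fg)] > 0) 50
  else if (!any(fg > 0)) Inf # E[EC] never reaches alpha: Bonferroni rules
  else {
    lo <- grid_u[max(which(fg > 0))]
    hi <- 50
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-8) break
    }
    (lo + hi) / 2
  }
  max(min(t_rft, t_bonf), stats::qt(alpha, df, lower.tail = FALSE))
}

#' Classical inference settings
#'
#' @param mode `"voxelwise_fwe"` or `"clusterwise"`.
#' @param alpha familywise error rate (default 0.05).
#' @param cdt_p uncorrected cluster-forming threshold p (default 0.001;
#'   clusterwise mode only).
#' @param direction +1 for positive effects (contrast "1"), -1 for the
#'   reverse contrast.
#' @param connectivity cluster connectivity (6, 18 or 26; default 18).
#' @return An object of class `classical_spec`.
#' @export
classical_spec <- function(mode = c("voxelwise_fwe", "clusterwise"),
                           alpha = 0.05, cdt_p = 0.001, direction = 1,
                           connectivity = 18L) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, cdt_p > 0, cdt_p < 1,
            direction %in% c(-1, 1))
  structure(list(mode = mode, alpha = alpha, cdt_p = cdt_p,
                 direction = direction,
                 connectivity = as.integer(connectivity)),
            class = "classical_spec")
}

# cluster-extent FWE p-value under Gaussian random field theory
# (Friston et al. 1994): P(max cluster >= k) with k in resels
cluster_fwe_p <- function(k_resels, u, df, resels) {
  Em <- max(expected_euler(u, df, resels), .Machine$double.xmin)
  En <- max(resels[4] * stats::pt(u, df, lower.tail = FALSE),
            .Machine$double.xmin)
  beta <- (gamma(2.5) * Em / En)^(2 / 3)
  p_k <- exp(-beta * k_resels^(2 / 3))
  1 - exp(-Em * p_k)
}

make_activation <- function(active, method, thresholds, values, glm, spec) {
  lab <- label_clusters(active, connectivity = spec$connectivity,
                        values = values, grid = glm$beta_hat$grid)
  structure(list(active = active, method = method,
                 thresholds_used = thresholds, clusters = lab$table,
                 labels = lab$labels, mask = glm$mask),
            class = "activation_result")
}

#' @export
print.activation_result <- function(x, ...) {
  cat(sprintf("activation_result[%s]: %d survived voxels in %d clusters\n",
              x$method, sum(x$active), nrow(x$clusters)))
  invisible(x)
}

#' Voxelwise FWE-corrected inference
#'
#' Thresholds the group t-map at the FWE-corrected height
#' [fwe_voxel_threshold()]; a voxel survives when
#' `direction * t > t*`.
#'
#' @param glm a `group_glm_result`.
#' @param sm a `smoothness_estimate`.
#' @param spec a [classical_spec()] with `mode = "voxelwise_fwe"`.
#' @return An `activation_result` (binary map, thresholds used, cluster
#'   table for reporting).
#' @export
voxelwise_inference <- function(glm, sm, spec) {
  stopifnot(spec$mode == "voxelwise_fwe")
  tstar <- fwe_voxel_threshold(glm$df, sm$resels, glm$mask$V, spec$alpha)
  t <- spec$direction * glm$tmap$values
  active <- glm$mask$inside & !is.na(t) & t > tstar
  make_activation(active, "voxelwise_fwe",
                  list(t_star = tstar, alpha = spec$alpha,
                       direction = spec$direction,
                       fwhm_voxels = sm$fwhm_voxels, V = glm$mask$V),
                  t, glm, spec)
}

#' Cluster-extent FWE inference
#'
#' Forms candidate clusters above the uncorrected cluster-defining
#' threshold (one-sided p < `cdt_p` in t units) and keeps those whose
#' extent is significant at the cluster-level FWE rate `alpha` under the
#' Gaussian-random-field cluster-size distribution.
#'
#' @inheritParams voxelwise_inference
#' @param spec a [classical_spec()] with `mode = "clusterwise"`.
#' @return An `activation_result`; the cluster table's `fwe_p` column holds
#'   each candidate cluster's corrected p-value.
#' @export
clusterwise_inference <- function(glm, sm, spec) {
  stopifnot(spec$mode == "clusterwise")
  u <- stats::qt(spec$cdt_p, glm$df, lower.tail = FALSE)
  t <- spec$direction * glm$tmap$values
  exc <- glm$mask$inside & !is.na(t) & t > u
  thresholds <- list(cdt = u, cdt_p = spec$cdt_p, alpha = spec$alpha,
                     direction = spec$direction,
                     fwhm_voxels = sm$fwhm_voxels)
  lab <- label_clusters(exc, connectivity = spec$connectivity, values = t,
                        grid = glm$beta_hat$grid)
  tab <- lab$table
  if (nrow(tab)) {
    k_res <- tab$size_voxels * prod(1 / sm$fwhm_voxels)
    tab$fwe_p <- vapply(k_res, cluster_fwe_p, numeric(1), u = u,
                        df = glm$df, resels = sm$resels)
    keep <- tab$cluster_id[tab$fwe_p < spec$alpha]
    active <- array(lab$labels %in% keep, dim = dim(exc))
  } else {
    active <- exc
  }
  res <- make_activation(active, "clusterwise", thresholds, t, glm, spec)
  # report all candidate clusters with their corrected p, not only winners
  res$clusters_candidate <- tab
  res
}
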