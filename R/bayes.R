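#' Global shrinkage prior
#'
#' The empirical-Bayes second-level model places a zero-mean Gaussian prior
#' with one global variance `cB` on every voxel's effect; `sqrt(cB)` is the
#' prior SD of the effect in contrast units and is conventionally read as a
#' Cohen's d of 1.0 for effect-size thresholding.
#'
#' @param cB prior variance of the per-voxel effect (>= 0, contrast^2).
#' @param sd alternatively, the prior SD `sqrt(cB)`; exactly one of `cB`
#'   and `sd` must be given.
#' @param method estimation method tag (`"moments"`; `"reml"` reserved).
#' @param V_used number of voxels the estimate was pooled over.
#' @return An object of class `shrinkage_prior` with fields `cB`, `sd`,
#'   `method`, `V_used`.
#' @export
shrinkage_prior <- function(cB = NULL, sd = NULL, method = "moments",
                            V_used = 2L) {
  if (is.null(cB) == is.null(sd))
    stop("give exactly one of cB and sd")
  if (is.null(cB)) {
    stopifnot(sd >= 0)
    cB <- sd^2
  } else {
    stopifnot(cB >= 0)
    sd <- sqrt(cB)
  }
  structure(list(cB = cB, sd = sd, method = method,
                 V_used = as.integer(V_used)),
            class = "shrinkage_prior")
}

#' @export
print.shrinkage_prior <- function(x, ...) {
  cat(sprintf("shrinkage_prior: cB = %.6g (sd %.6g), %s over %d voxels\n",
              x$cB, x$sd, x$method, x$V_used))
  invisible(x)
}

#' Estimate the prior variance by method of moments
#'
#' Under the hierarchical model `beta_hat_v ~ N(beta_v, sigma_v^2 / n)`,
#' `beta_v ~ N(0, cB)`, the between-voxel variance of the sample means
#' exceeds the average sampling variance by `cB`; the moments estimator is
#' `cB = max(0, Var_v(beta_hat_v) - mean_v(resid_var_v) / n)` over in-mask
#' voxels with positive residual variance (variance divisor V - 1).
#'
#' @param glm a `group_glm_result`.
#' @param method `"moments"` (the `"reml"` tag is reserved, unimplemented).
#' @return A [shrinkage_prior()].
#' @export
estimate_prior_variance <- function(glm, method = "moments") {
  method <- match.arg(method, c("moments", "reml"))
  if (method == "reml") stop("reml prior estimation is not implemented")
  use <- glm$usable & is.finite(glm$beta_hat$values)
  V <- sum(use)
  if (V < 2L) stop("need at least 2 usable voxels to estimate cB")
  b <- glm$beta_hat$values[use]
  cB <- max(0, stats::var(b) - mean(glm$resid_var$values[use]) / glm$n)
  shrinkage_prior(cB = cB, method = method, V_used = V)
}

#' Effect-size threshold from a Cohen's-d multiplier
#'
#' Resolves the effect-size threshold `gamma = d * sqrt(cB)` in contrast
#' units: the prior SD `sqrt(cB)` plays the role of Cohen's d = 1.0, so
#' d = 0.5 asks for half the prior SD (e.g. 0.0259 when `sqrt(cB)` =
#' 0.0518).
#'
#' @param prior a [shrinkage_prior()] (or a bare numeric `cB`).
#' @param d Cohen's-d multiplier (> 0); 0.2/0.5/0.8 are the conventional
#'   small/medium/large effect sizes.
#' @return The threshold `gamma` in contrast units.
#' @export
es_threshold <- function(prior, d) {
  stopifnot(d > 0)
  if (is.numeric(prior)) prior <- shrinkage_prior(cB = prior)
  d * prior$sd
}

#' Conjugate posterior maps
#'
#' Per-voxel Gaussian conjugate update of the shrinkage prior with the
#' voxel's own data: posterior precision `1/cB + n/resid_var`, posterior
#' mean `post_var * (n/resid_var) * beta_hat`. Voxels with zero residual
#' variance are flagged and excluded (NA in the posterior maps).
#'
#' @param glm a `group_glm_result`.
#' @param prior a [shrinkage_prior()] with `cB > 0`.
#' @return An object of class `posterior_maps` with `post_mean` and
#'   `post_var` ([stat_volume()]), `prior`, `glm`.
#' @export
compute_posterior <- function(glm, prior) {
  stopifnot(inherits(prior, "shrinkage_prior"))
  if (prior$cB <= 0)
    stop("degenerate prior (cB = 0); no Bayesian map: all prior mass at 0")
  grid <- glm$beta_hat$grid
  v <- glm$resid_var$values
  prec_data <- ifelse(v > 0, glm$n / v, NA_real_)
  post_var <- 1 / (1 / prior$cB + prec_data)
  post_mean <- post_var * prec_data * glm$beta_hat$values
  structure(list(post_mean = stat_volume(post_mean, grid, "posterior_mean"),
                 post_var = stat_volume(post_var, grid, "posterior_var"),
                 prior = prior, glm = glm),
            class = "posterior_maps")
}

#' Log posterior odds map
#'
#' At each voxel, with posterior `N(post_mean, post_var)` and effect-size
#' threshold `gamma`, computes `P1 = P(direction * effect > gamma | data)`
#' and returns `log(P1 / (1 - P1))`. Under equal prior odds for
#' H1 (effect > gamma) and H0 this log posterior odds equals the log Bayes
#' factor ("logBF"). Values are clipped to [-40, 40], beyond the double
#' precision resolution of the normal CDF and far past any threshold in
#' use.
#'
#' @param post a `posterior_maps` object.
#' @param gamma effect-size threshold in contrast units (>= 0), e.g. from
#'   [es_threshold()].
#' @param direction +1 or -1.
#' @return A [stat_volume()] of kind `"logodds"` (NA at flagged voxels).
#' @export
log_odds_map <- function(post, gamma, direction = 1) {
  stopifnot(gamma >= 0, direction %in% c(-1, 1))
  pv <- post$post_var$values
  if (any(pv[post$glm$usable] <= 0, na.rm = TRUE))
    stop("non-positive posterior variance at an in-mask voxel")
  z <- (gamma - direction * post$post_mean$values) / sqrt(pv)
  lo <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) -
    stats::pnorm(z, log.p = TRUE)
  lo <- pmin(pmax(lo, -40), 40)
  stat_volume(array(lo, dim = post$glm$beta_hat$grid$shape),
              post$glm$beta_hat$grid, "logodds")
}

#' Bayesian thresholding settings
#'
#' Joint effect-size + log-odds criterion: a voxel is active when its log
#' posterior odds of exceeding the effect-size threshold `gamma = d *
#' sqrt(cB)` is above `tau`. Guideline defaults are d = 0.5 (medium
#' effect) and tau = 5 (very strong evidence); tau = 3 marks strong
#' evidence and 10 is the stricter tool default. The voxel extent
#' threshold defaults to 0 (no cluster-size filtering).
#'
#' @param d Cohen's-d multiplier for the effect-size threshold.
#' @param tau log-odds ("logBF") threshold.
#' @param direction +1 or -1.
#' @param extent_voxels minimum cluster size (default 0).
#' @param gamma resolved threshold in contrast units; normally left NULL
#'   and resolved against the data's prior via [es_threshold()].
#' @return An object of class `bayes_spec`.
#' @export
bayes_spec <- function(d = 0.5, tau = 5, direction = 1, extent_voxels = 0L,
                       gamma = NULL) {
  stopifnot(d > 0, direction %in% c(-1, 1), extent_voxels >= 0)
  structure(list(d = d, tau = tau, direction = direction,
                 extent_voxels = as.integer(extent_voxels), gamma = gamma),
            class = "bayes_spec")
}

#' Threshold a log-odds map
#'
#' `active = {logodds > tau}` within the mask; when `extent_voxels > 0`,
#' clusters smaller than the extent are dropped.
#'
#' @param logodds a [stat_volume()] of kind `"logodds"`.
#' @param spec a [bayes_spec()] with `gamma` resolved.
#' @param mask a [brain_mask()].
#' @param connectivity cluster connectivity for the cluster table.
#' @return An object of class `bayes_activation` (also
#'   `activation_result`): `active`, `logodds`, `spec`, `clusters`.
#' @export
bayes_threshold <- function(logodds, spec, mask, connectivity = 18L) {
  lo <- logodds$values
  active <- mask$inside & !is.na(lo) & lo > spec$tau
  lab <- label_clusters(active, connectivity = connectivity, values = lo,
                        grid = logodds$grid)
  if (spec$extent_voxels > 0L && nrow(lab$table)) {
    keep <- lab$table$cluster_id[lab$table$size_voxels >= spec$extent_voxels]
    active <- array(lab$labels %in% keep, dim = dim(active))
    lab <- label_clusters(active, connectivity = connectivity, values = lo,
                          grid = logodds$grid)
  }
  structure(list(active = active, method = "bayes", logodds = logodds,
                 spec = spec, clusters = lab$table, labels = lab$labels,
                 mask = mask,
                 thresholds_used = list(d = spec$d, gamma = spec$gamma,
                                        tau = spec$tau,
                                        direction = spec$direction,
                                        extent_voxels = spec$extent_voxels)),
            class = c("bayes_activation", "activation_result"))
}

#' End-to-end Bayesian second-level inference
#'
#' Convenience wrapper: estimates the shrinkage prior from the GLM,
#' resolves `gamma = d * sqrt(cB)`, computes the conjugate posterior and
#' log-odds map, and thresholds it.
#'
#' @param glm a `group_glm_result`.
#' @param spec a [bayes_spec()].
#' @param connectivity cluster connectivity for reporting.
#' @return A `bayes_activation`; `thresholds_used` additionally records
#'   `cB`.
#' @export
bayes_inference <- function(glm, spec = bayes_spec(), connectivity = 18L) {
  prior <- estimate_prior_variance(glm)
  if (prior$cB <= 0)
    stop("degenerate prior (cB = 0); no Bayesian map")
  spec$gamma <- es_threshold(prior, spec$d)
  post <- compute_posterior(glm, prior)
  lo <- log_odds_map(post, spec$gamma, spec$direction)
  act <- bayes_threshold(lo, spec, glm$mask, connectivity = connectivity)
  act$thresholds_used$cB <- prior$cB
  act$prior <- prior
  act$posterior <- post
  act
}
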