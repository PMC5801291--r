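#' Method specifications for the evaluation harness
#'
#' Lightweight descriptions of the inference methods compared by the
#' robustness and sample-size experiments. Each carries a `label` used in
#' tidy outputs.
#'
#' @param alpha familywise error rate.
#' @param cdt_p cluster-forming threshold (uncorrected p).
#' @param direction +1 or -1.
#' @param connectivity cluster connectivity.
#' @return A `method_spec` list with a `type` field.
#' @name method_specs
NULL

#' @rdname method_specs
#' @export
method_clusterwise <- function(alpha = 0.05, cdt_p = 0.001, direction = 1,
                               connectivity = 18L) {
  structure(list(type = "clusterwise", label = "clusterwise",
                 spec = classical_spec("clusterwise", alpha = alpha,
                                       cdt_p = cdt_p, direction = direction,
                                       connectivity = connectivity)),
            class = "method_spec")
}

#' @rdname method_specs
#' @export
method_voxelwise <- function(alpha = 0.05, direction = 1,
                             connectivity = 18L) {
  structure(list(type = "voxelwise_fwe", label = "voxelwise_fwe",
                 spec = classical_spec("voxelwise_fwe", alpha = alpha,
                                       direction = direction,
                                       connectivity = connectivity)),
            class = "method_spec")
}

#' @rdname method_specs
#' @param d,tau,extent_voxels Bayesian thresholds (see [bayes_spec()]).
#' @export
method_bayes <- function(d = 0.5, tau = 5, direction = 1,
                         extent_voxels = 0L) {
  structure(list(type = "bayes",
                 label = sprintf("bayes_d%g_tau%g", d, tau),
                 spec = bayes_spec(d = d, tau = tau, direction = direction,
                                   extent_voxels = extent_voxels)),
            class = "method_spec")
}

#' Run a list of inference methods on one dataset
#'
#' Fits the group GLM once, estimates smoothness once if any classical
#' method is requested, and runs every method. Returns the activation
#' results plus the shared fit objects.
#'
#' @param images a `subject_image_set`.
#' @param methods list of `method_spec`s (see [method_specs]).
#' @return A list with `glm`, `smoothness` (or NULL), and `results`, a
#'   named list of `activation_result`s keyed by method label.
#' @export
run_inference <- function(images, methods) {
  stopifnot(length(methods) >= 1L)
  glm <- fit_group_glm(images)
  needs_sm <- any(vapply(methods, function(m)
    m$type %in% c("clusterwise", "voxelwise_fwe"), logical(1)))
  sm <- if (needs_sm) estimate_smoothness(glm, images) else NULL
  results <- lapply(methods, function(m) {
    switch(m$type,
           clusterwise = clusterwise_inference(glm, sm, m$spec),
           voxelwise_fwe = voxelwise_inference(glm, sm, m$spec),
           bayes = bayes_inference(glm, m$spec),
           stop("unknown method type: ", m$type))
  })
  names(results) <- vapply(methods, `[[`, character(1), "label")
  list(glm = glm, smoothness = sm, results = results)
}

as_active_array <- function(x) {
  if (is.logical(x) || is.array(x)) return(as.logical(x))
  if (!is.null(x$active)) return(x$active)
  stop("cannot interpret object as an activation map")
}

#' Count survived voxels
#'
#' @param act an `activation_result` (or logical array).
#' @return Integer count of active voxels.
#' @export
survived_count <- function(act) {
  sum(as_active_array(act), na.rm = TRUE)
}

#' False-alarm rate between a perturbed and an original analysis
#'
#' The fraction of voxels active in the noise-added analysis that were
#' inactive in the original analysis:
#' `|A_noise \ A_orig| / |A_noise|`. Undefined (NA) when the perturbed
#' analysis activates nothing.
#'
#' @param noise_act activation from the noise-added images.
#' @param orig_act activation from the original images.
#' @return A rate in [0, 1], or NA when undefined.
#' @export
false_alarm_rate <- function(noise_act, orig_act) {
  a_n <- as_active_array(noise_act)
  a_o <- as_active_array(orig_act)
  if (length(a_n) != length(a_o)) stop("grid mismatch between activations")
  denom <- sum(a_n)
  if (denom == 0L) return(NA_real_)
  sum(a_n & !a_o) / denom
}

#' Hit rate between a perturbed and an original analysis
#'
#' The fraction of originally active voxels that remain active under the
#' perturbation: `|A_noise intersect A_orig| / |A_orig|`. Undefined (NA)
#' when the original analysis activates nothing.
#'
#' @inheritParams false_alarm_rate
#' @return A rate in [0, 1], or NA when undefined.
#' @export
hit_rate <- function(noise_act, orig_act) {
  a_n <- as_active_array(noise_act)
  a_o <- as_active_array(orig_act)
  if (length(a_n) != length(a_o)) stop("grid mismatch between activations")
  denom <- sum(a_o)
  if (denom == 0L) return(NA_real_)
  sum(a_n & a_o) / denom
}

#' Noise-injection robustness experiment
#'
#' Runs every method once on the original images, then on `R` independently
#' perturbed copies ([inject_noise()] at the given `fraction`, replicate r
#' using seed `seed + r`), and tabulates per-replicate false-alarm and hit
#' rates against the original activations. One perturbed dataset is shared
#' by all methods within a replicate (paired comparison). Study defaults:
#' `R = 10`, `fraction = 0.25`.
#'
#' @param images a `subject_image_set`.
#' @param methods list of `method_spec`s.
#' @param R number of replicates (>= 1).
#' @param fraction noise SD as a fraction of mean absolute in-mask signal.
#' @param seed base RNG seed.
#' @return A data frame of class `noise_eval_result` with columns
#'   `replicate`, `method`, `false_alarm`, `hit`, `seed`; original and
#'   perturbed survived counts are attached as attributes
#'   `orig_counts` / `noise_counts`.
#' @export
noise_robustness_experiment <- function(images, methods, R = 10L,
                                        fraction = 0.25, seed = 1L) {
  stopifnot(R >= 1L)
  orig <- run_inference(images, methods)
  labels <- names(orig$results)
  rows <- vector("list", R)
  noise_counts <- matrix(NA_integer_, R, length(labels),
                         dimnames = list(NULL, labels))
  for (r in seq_len(R)) {
    seed_r <- seed + r
    pert <- inject_noise(images, fraction, seed = seed_r)
    res_r <- tryCatch(run_inference(pert, methods), error = function(e)
      stop("replicate ", r, ": ", conditionMessage(e)))
    rows[[r]] <- data.frame(
      replicate = r, method = labels,
      false_alarm = vapply(labels, function(l)
        false_alarm_rate(res_r$results[[l]], orig$results[[l]]), numeric(1)),
      hit = vapply(labels, function(l)
        hit_rate(res_r$results[[l]], orig$results[[l]]), numeric(1)),
      seed = seed_r, row.names = NULL)
    noise_counts[r, ] <- vapply(res_r$results, survived_count, integer(1))
  }
  out <- do.call(rbind, rows)
  attr(out, "orig_counts") <- vapply(orig$results, survived_count,
                                     integer(1))
  attr(out, "noise_counts") <- noise_counts
  attr(out, "fraction") <- fraction
  class(out) <- c("noise_eval_result", "data.frame")
  out
}

#' Incremental sample-size sweep
#'
#' For each of `P` random subject orders, refits every method on the first
#' n subjects for n = 2..N, re-estimating all data-dependent quantities
#' (smoothness, cB, gamma) from the included subjects, and records
#' per-method survived counts plus the t and log-odds values at the voxel
#' nearest `target_mm`. Methods that cannot run at a given n (classical
#' smoothness estimation needs n >= 3) yield NA counts rather than
#' aborting the sweep. Study defaults: `P = 10`, target (-4, 48, 12) mm.
#'
#' @param images a `subject_image_set` with N >= 3 subjects.
#' @param methods list of `method_spec`s; the first `bayes` entry supplies
#'   the log-odds trajectory.
#' @param P number of random orders.
#' @param target_mm mm coordinate of the tracked voxel (must be in-mask).
#' @param seed RNG seed for the subject orders.
#' @return A list of class `sweep_result`: `results` (data frame with
#'   columns `permutation`, `n`, `method`, `count`, `t_at_voxel`,
#'   `logodds_at_voxel`) and `orders` (P x N matrix of subject orders).
#' @export
sample_size_sweep <- function(images, methods, P = 10L,
                              target_mm = c(-4, 48, 12), seed = 1L) {
  N <- length(images$images)
  stopifnot(P >= 1L, N >= 3L)
  idx <- mm_to_voxel(target_mm, images$grid) + 1L
  if (!images$mask$inside[idx[1], idx[2], idx[3]])
    stop("target voxel is outside the mask")
  orders <- with_seed(seed, t(vapply(seq_len(P), function(p) sample(N),
                                     integer(N))))
  labels <- vapply(methods, `[[`, character(1), "label")
  bayes_label <- labels[vapply(methods, function(m) m$type == "bayes",
                               logical(1))][1]
  rows <- list()
  for (p in seq_len(P)) {
    ord <- orders[p, ]
    for (n in 2:N) {
      sub <- subject_image_set(images$images[ord[seq_len(n)]], images$mask)
      glm <- fit_group_glm(sub)
      t_v <- glm$tmap$values[idx[1], idx[2], idx[3]]
      counts <- rep(NA_integer_, length(methods))
      lo_v <- NA_real_
      res <- tryCatch(run_inference(sub, methods), error = function(e) NULL)
      if (is.null(res)) {
        # classical smoothness needs n >= 3; run what can run
        res <- tryCatch(
          run_inference(sub, Filter(function(m) m$type == "bayes", methods)),
          error = function(e) NULL)
      }
      if (!is.null(res)) {
        got <- match(names(res$results), labels)
        counts[got] <- vapply(res$results, survived_count, integer(1))
        if (!is.na(bayes_label) && bayes_label %in% names(res$results))
          lo_v <- res$results[[bayes_label]]$logodds$values[idx[1], idx[2],
                                                           idx[3]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        permutation = p, n = n, method = labels, count = counts,
        t_at_voxel = t_v, logodds_at_voxel = lo_v, row.names = NULL)
    }
  }
  structure(list(results = do.call(rbind, rows), orders = orders,
                 target_mm = target_mm, target_voxel = idx - 1L,
                 P = P, seed = seed),
            class = "sweep_result")
}

#' Write the tidy noise-evaluation table
#'
#' Columns: replicate, method, false_alarm, hit, seed.
#' @param x a `noise_eval_result`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_noise_eval <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write the sweep results and subject orders
#'
#' Writes `sweep.csv` (permutation, n, method, count, t_at_voxel,
#' logodds_at_voxel) and `orders.csv` (one row per permutation).
#' @param x a `sweep_result`.
#' @param dir output directory.
#' @return Invisibly, the two paths.
#' @export
write_sweep_result <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "sweep.csv")
  p2 <- file.path(dir, "orders.csv")
  utils::write.csv(x$results, p1, row.names = FALSE)
  ord <- as.data.frame(x$orders)
  names(ord) <- paste0("entry_", seq_len(ncol(ord)))
  ord <- cbind(permutation = seq_len(nrow(ord)), ord)
  utils::write.csv(ord, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
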