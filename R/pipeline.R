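#' Load and validate a run configuration
#'
#' YAML configuration driving an end-to-end run. Structure:
#' \preformatted{
#' input:
#'   synthetic: {grid_shape, voxel_size_mm, n_subjects, sigma_between,
#'               smooth_fwhm_voxels, blobs: [{center, radius, d_true}],
#'               mask_shape, seed}
#'   # or
#'   nifti_dir: path/to/contrast/images
#'   mask: path/to/mask.nii      # optional with nifti_dir
#' methods:
#'   - {type: clusterwise, alpha: 0.05, cdt_p: 0.001}
#'   - {type: voxelwise_fwe, alpha: 0.05}
#'   - {type: bayes, d: 0.5, tau: 5}
#' evaluation:                    # optional
#'   noise: {R: 10, fraction: 0.25, seed: 1}
#'   # or sweep: {P: 10, target_mm: [-4, 48, 12], seed: 1}
#' output_dir: path
#' }
#' Validation errors name the offending field path.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$input)) stop("config error at input: missing")
  if (is.null(cfg$input$synthetic) && is.null(cfg$input$nifti_dir))
    stop("config error at input: need synthetic or nifti_dir")
  if (!is.null(cfg$input$nifti_dir) && !dir.exists(cfg$input$nifti_dir))
    stop("config error at input.nifti_dir: directory not found: ",
         cfg$input$nifti_dir)
  if (is.null(cfg$methods) || length(cfg$methods) < 1L)
    stop("config error at methods: need at least one method")
  for (i in seq_along(cfg$methods)) {
    m <- cfg$methods[[i]]
    if (is.null(m$type) ||
        !m$type %in% c("clusterwise", "voxelwise_fwe", "bayes"))
      stop(sprintf("config error at methods[%d].type: must be one of %s", i,
                   "clusterwise, voxelwise_fwe, bayes"))
  }
  if (!is.null(cfg$evaluation) &&
      !identical(cfg$evaluation, "none") &&
      is.null(cfg$evaluation$noise) && is.null(cfg$evaluation$sweep))
    stop("config error at evaluation: need noise, sweep, or none")
  if (is.null(cfg$output_dir))
    stop("config error at output_dir: missing")
  structure(cfg, class = "run_config")
}

config_methods <- function(cfg) {
  lapply(cfg$methods, function(m) {
    args <- m[setdiff(names(m), "type")]
    switch(m$type,
           clusterwise = do.call(method_clusterwise, args),
           voxelwise_fwe = do.call(method_voxelwise, args),
           bayes = do.call(method_bayes, args))
  })
}

config_images <- function(cfg) {
  if (!is.null(cfg$input$synthetic)) {
    spec <- synthetic_spec_from_list(cfg$input$synthetic)
    generate_subject_images(spec)
  } else {
    read_subject_dir(cfg$input$nifti_dir, cfg$input$mask)
  }
}

log_jsonl <- function(con, stage, ...) {
  rec <- c(list(stage = stage,
                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
}

#' Run the survived-voxel comparison
#'
#' Executes every configured method on the configured dataset and writes a
#' one-row report (one column per method, cell = survived-voxel count),
#' per-method binary masks (NIfTI) and cluster tables (CSV), and a
#' JSON-lines run log capturing all data-dependent thresholds (FWHM, t*,
#' CDT, cB, gamma) and seeds.
#'
#' @param cfg a `run_config` (from [load_run_config()]) or a path to one.
#' @return The report as a one-row data frame (invisibly written to
#'   `report.csv` in `output_dir`).
#' @export
run_comparison <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  cfg <- validate_run_config(cfg)
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  logcon <- file(file.path(out, "run_log.jsonl"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  t0 <- proc.time()[["elapsed"]]
  images <- config_images(cfg)
  log_jsonl(logcon, "input", n_subjects = length(images$images),
            V = images$mask$V,
            seed = if (!is.null(cfg$input$synthetic))
              cfg$input$synthetic$seed else NULL,
            wall_s = proc.time()[["elapsed"]] - t0)
  methods <- config_methods(cfg)
  fit <- run_inference(images, methods)
  counts <- integer(0)
  for (label in names(fit$results)) {
    res <- fit$results[[label]]
    counts[label] <- survived_count(res)
    mask_vol <- stat_volume(res$active + 0, images$grid, "contrast")
    write_nifti(mask_vol, file.path(out, paste0("mask_", label, ".nii.gz")))
    write_cluster_table(res$clusters,
                        file.path(out, paste0("clusters_", label, ".csv")))
    if (!is.null(res$logodds))
      write_nifti(res$logodds,
                  file.path(out, paste0("logodds_", label, ".nii.gz")))
    log_jsonl(logcon, paste0("method_", label),
              survived = counts[[label]],
              thresholds = res$thresholds_used,
              wall_s = proc.time()[["elapsed"]] - t0)
  }
  write_nifti(fit$glm$tmap, file.path(out, "tmap.nii.gz"))
  if (!is.null(fit$smoothness))
    log_jsonl(logcon, "smoothness",
              fwhm_voxels = fit$smoothness$fwhm_voxels,
              resels = unname(fit$smoothness$resels),
              wall_s = proc.time()[["elapsed"]] - t0)
  report <- as.data.frame(as.list(counts))
  names(report) <- names(counts)
  report <- cbind(data.frame(dataset = if (!is.null(cfg$input$synthetic))
    "synthetic" else cfg$input$nifti_dir), report)
  utils::write.csv(report, file.path(out, "report.csv"), row.names = FALSE)
  log_jsonl(logcon, "report", wall_s = proc.time()[["elapsed"]] - t0)
  report
}

#' Run the configured evaluation protocol
#'
#' Dispatches to [noise_robustness_experiment()] (writing
#' `noise_eval.csv`) or [sample_size_sweep()] (writing `sweep.csv` and
#' `orders.csv`) according to the config's `evaluation` section; with
#' `evaluation: none` (or absent) this is a no-op that logs why.
#'
#' @param cfg a `run_config` or a path to one.
#' @return The `noise_eval_result` or `sweep_result`, or NULL for `none`.
#' @export
run_evaluation <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  cfg <- validate_run_config(cfg)
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  logcon <- file(file.path(out, "eval_log.jsonl"), open = "at")
  on.exit(close(logcon), add = TRUE)
  ev <- cfg$evaluation
  if (is.null(ev) || identical(ev, "none")) {
    log_jsonl(logcon, "evaluation", note = "no evaluation configured; no-op")
    return(invisible(NULL))
  }
  images <- config_images(cfg)
  methods <- config_methods(cfg)
  if (!is.null(ev$noise)) {
    a <- ev$noise
    res <- noise_robustness_experiment(
      images, methods,
      R = if (is.null(a$R)) 10L else a$R,
      fraction = if (is.null(a$fraction)) 0.25 else a$fraction,
      seed = if (is.null(a$seed)) 1L else a$seed)
    write_noise_eval(res, file.path(out, "noise_eval.csv"))
    log_jsonl(logcon, "evaluation", protocol = "noise",
              R = nrow(attr(res, "noise_counts")),
              fraction = attr(res, "fraction"),
              seeds = unique(res$seed))
    res
  } else {
    a <- ev$sweep
    res <- sample_size_sweep(
      images, methods,
      P = if (is.null(a$P)) 10L else a$P,
      target_mm = if (is.null(a$target_mm)) c(-4, 48, 12) else
        unlist(a$target_mm),
      seed = if (is.null(a$seed)) 1L else a$seed)
    write_sweep_result(res, out)
    log_jsonl(logcon, "evaluation", protocol = "sweep", P = res$P,
              target_mm = res$target_mm, seed = res$seed)
    res
  }
}
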