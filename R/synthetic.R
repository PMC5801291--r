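#' Planted activation blob
#'
#' A spherical region of elevated mean contrast. `d_true` is the effect
#' amplitude in units of the between-subject standard deviation, i.e. the
#' true Cohen's d of the planted effect.
#'
#' @param center_voxel 0-based voxel index of the sphere centre (length 3).
#' @param radius_voxels sphere radius in voxels (> 0).
#' @param d_true effect amplitude in between-subject SD units.
#' @return An object of class `activation_blob`.
#' @export
activation_blob <- function(center_voxel, radius_voxels, d_true) {
  stopifnot(length(center_voxel) == 3L, radius_voxels > 0)
  structure(list(center_voxel = as.integer(center_voxel),
                 radius_voxels = as.numeric(radius_voxels),
                 d_true = as.numeric(d_true)),
            class = "activation_blob")
}

#' Specification of a synthetic second-level dataset
#'
#' Describes the stand-in for a set of first-level contrast images: a grid,
#' a subject count, spatially smooth Gaussian between-subject noise with SD
#' `sigma_between`, and planted [activation_blob()]s. Defaults give a
#' desk-scale study: a 40x48x34 grid at 2 mm (65,280 voxels) with an
#' inscribed ellipsoid mask (about 33,000 in-mask voxels), 16 subjects, and
#' noise smoothness of 3 voxels FWHM.
#'
#' @param grid_shape,voxel_size_mm grid geometry (see [volume_grid()]).
#' @param n_subjects number of subjects (>= 2).
#' @param sigma_between between-subject SD of the contrast (> 0).
#' @param smooth_fwhm_voxels FWHM of the Gaussian smoothing kernel applied
#'   to the noise fields, in voxels (0 = white noise).
#' @param blobs list of [activation_blob()]s.
#' @param mask_shape `"ellipsoid"` (inscribed) or `"box"` (whole grid).
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_shape = c(40, 48, 34),
                           voxel_size_mm = c(2, 2, 2),
                           n_subjects = 16,
                           sigma_between = 1,
                           smooth_fwhm_voxels = 3,
                           blobs = list(),
                           mask_shape = c("ellipsoid", "box"),
                           seed = 1L) {
  mask_shape <- match.arg(mask_shape)
  if (n_subjects < 2) stop("n_subjects must be >= 2 (one-sample t needs df >= 1)")
  if (sigma_between <= 0) stop("sigma_between must be > 0")
  if (smooth_fwhm_voxels < 0) stop("smooth_fwhm_voxels must be >= 0")
  if (length(blobs) && inherits(blobs, "activation_blob")) blobs <- list(blobs)
  grid <- volume_grid(grid_shape, voxel_size_mm)
  structure(list(grid = grid, n_subjects = as.integer(n_subjects),
                 sigma_between = sigma_between,
                 smooth_fwhm_voxels = smooth_fwhm_voxels,
                 blobs = blobs, mask_shape = mask_shape,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Read a synthetic-data specification from YAML
#'
#' Keys: `grid_shape`, `voxel_size_mm`, `n_subjects`, `sigma_between`,
#' `smooth_fwhm_voxels`, `blobs` (list of `center`, `radius`, `d_true`),
#' `mask_shape`, `seed`.
#'
#' @param path YAML file path.
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic_spec_from_list(y)
}

synthetic_spec_from_list <- function(y) {
  blobs <- lapply(y$blobs, function(b)
    activation_blob(b$center, b$radius, b$d_true))
  args <- list(blobs = blobs)
  for (k in c("grid_shape", "voxel_size_mm", "n_subjects", "sigma_between",
              "smooth_fwhm_voxels", "mask_shape", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(synthetic_spec, args)
}

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

gauss_kernel <- function(fwhm) {
  if (fwhm <= 0) return(1)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w / sum(w)
}

# banded convolution matrix (zero boundary); n x n
kernel_matrix <- function(n, w) {
  r <- (length(w) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in -r:r) {
    i <- seq_len(n)
    ok <- i + j >= 1L & i + j <= n
    K[cbind(i[ok], (i + j)[ok])] <- w[j + r + 1L]
  }
  K
}

# separable 3-D Gaussian smoothing by per-axis matrix products
smooth_gaussian3d <- function(arr, fwhm_voxels) {
  if (fwhm_voxels <= 0) return(arr)
  w <- gauss_kernel(fwhm_voxels)
  d <- dim(arr)
  K1 <- kernel_matrix(d[1], w)
  arr <- array(K1 %*% matrix(arr, d[1], d[2] * d[3]), dim = d)
  K2 <- kernel_matrix(d[2], w)
  arr <- aperm(array(K2 %*% matrix(aperm(arr, c(2, 1, 3)),
                                   d[2], d[1] * d[3]),
                     dim = d[c(2, 1, 3)]), c(2, 1, 3))
  K3 <- kernel_matrix(d[3], w)
  arr <- aperm(array(K3 %*% matrix(aperm(arr, c(3, 1, 2)),
                                   d[3], d[1] * d[2]),
                     dim = d[c(3, 1, 2)]), c(2, 3, 1))
  arr
}

# one unit-variance smooth Gaussian field: white noise on a padded grid,
# smoothed, cropped (so the interior is exactly stationary), and divided by
# the closed-form SD of the smoothed field
smooth_unit_field <- function(shape, fwhm_voxels) {
  if (fwhm_voxels <= 0)
    return(array(stats::rnorm(prod(shape)), dim = shape))
  w <- gauss_kernel(fwhm_voxels)
  r <- (length(w) - 1L) %/% 2L
  pshape <- shape + 2L * r
  e <- array(stats::rnorm(prod(pshape)), dim = pshape)
  e <- smooth_gaussian3d(e, fwhm_voxels)
  e <- e[(r + 1):(r + shape[1]), (r + 1):(r + shape[2]),
         (r + 1):(r + shape[3]), drop = FALSE]
  e / sqrt(sum(w^2))^3
}

default_mask <- function(grid, mask_shape) {
  if (mask_shape == "box")
    return(brain_mask(array(TRUE, dim = grid$shape), grid))
  s <- grid$shape
  cx <- (s - 1) / 2
  ax <- pmax((s - 1) / 2, 0.5)
  idx <- arrayInd(seq_len(prod(s)), s) - 1L
  inside <- ((idx[, 1] - cx[1]) / ax[1])^2 + ((idx[, 2] - cx[2]) / ax[2])^2 +
    ((idx[, 3] - cx[3]) / ax[3])^2 <= 1
  brain_mask(array(inside, dim = s), grid)
}

blob_voxels <- function(blob, shape) {
  ctr <- blob$center_voxel
  r <- blob$radius_voxels
  lo <- pmax(ctr - ceiling(r), 0L)
  hi <- pmin(ctr + ceiling(r), shape - 1L)
  if (any(lo > hi)) stop("blob lies outside the grid")
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                             z = lo[3]:hi[3]))
  d2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2
  g <- g[d2 <= r^2, , drop = FALSE]
  (g[, 3]) * shape[1] * shape[2] + (g[, 2]) * shape[1] + g[, 1] + 1L
}

#' Generate synthetic per-subject contrast images
#'
#' Each subject's image is `M + E_i`: a shared mean map `M` equal to
#' `d_true * sigma_between` inside each planted blob and 0 elsewhere, plus
#' an independent noise field `E_i` obtained by smoothing Gaussian white
#' noise with an isotropic kernel of FWHM `smooth_fwhm_voxels` and scaling
#' it so its marginal SD equals `sigma_between` (the generator smooths on a
#' padded grid and crops, so the field is stationary and the closed-form
#' rescaling is exact). Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A `subject_image_set` with an extra field `truth`, a `truth_map`
#'   whose `active` array marks the union of blob interiors (intersected
#'   with the mask); the truth map depends only on the spec geometry, not
#'   on the seed.
#' @export
generate_subject_images <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- spec$grid
  mask <- default_mask(grid, spec$mask_shape)
  M <- array(0, dim = grid$shape)
  active <- array(FALSE, dim = grid$shape)
  for (b in spec$blobs) {
    ctr1 <- b$center_voxel + 1L
    if (any(b$center_voxel < 0L) || any(b$center_voxel > grid$shape - 1L) ||
        !mask$inside[ctr1[1], ctr1[2], ctr1[3]])
      stop("blob centre outside the mask")
    lin <- blob_voxels(b, grid$shape)
    lin <- lin[mask$inside[lin]]
    M[lin] <- b$d_true * spec$sigma_between
    active[lin] <- TRUE
  }
  images <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(i) {
      E <- smooth_unit_field(grid$shape, spec$smooth_fwhm_voxels) *
        spec$sigma_between
      stat_volume(M + E, grid, kind = "contrast")
    })
  })
  out <- subject_image_set(images, mask)
  out$truth <- structure(list(grid = grid, active = active),
                         class = "truth_map")
  out
}

#' Inject additive Gaussian noise into each subject image
#'
#' Implements the perturbation protocol used for robustness evaluation:
#' each image independently receives iid Gaussian noise at in-mask voxels
#' with SD equal to `fraction` times that image's mean signal strength,
#' taken as the mean absolute in-mask value (contrast images are signed, so
#' a plain mean could be near zero and degenerate). Out-of-mask voxels are
#' untouched. The study setting is `fraction = 0.25`.
#'
#' @param images a `subject_image_set`.
#' @param fraction noise SD as a fraction of mean absolute in-mask signal
#'   (>= 0).
#' @param seed integer RNG seed.
#' @return A new `subject_image_set` on the same grid and mask.
#' @export
inject_noise <- function(images, fraction, seed = 1L) {
  stopifnot(inherits(images, "subject_image_set"))
  if (fraction < 0) stop("fraction must be >= 0")
  if (fraction == 0) return(images)
  inside <- images$mask$inside
  nin <- sum(inside)
  out <- with_seed(seed, {
    lapply(images$images, function(im) {
      s <- fraction * mean(abs(im$values[inside]))
      v <- im$values
      v[inside] <- v[inside] + stats::rnorm(nin, sd = s)
      stat_volume(v, im$grid, kind = "contrast")
    })
  })
  res <- subject_image_set(out, images$mask)
  res
}
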