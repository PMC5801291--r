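#' Voxel grid geometry
#'
#' A `volume_grid` describes the sampling lattice shared by all volumes in an
#' analysis: the number of voxels per axis, the physical voxel sizes in mm,
#' and a 4x4 affine mapping 0-based voxel indices to mm coordinates (NIfTI
#' convention).
#'
#' If no affine is supplied, an axis-aligned one is built from
#' `voxel_size_mm` and `origin_mm` (the mm coordinate of voxel (0,0,0)). The
#' default origin for the package's default 40x48x34 grid at 2 mm is
#' (-40, -44, -24), an MNI-like bounding box that keeps typical frontal
#' coordinates such as (-4, 48, 12) inside the volume.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric vector of length 3, voxel edge lengths in mm.
#' @param affine optional 4x4 matrix mapping 0-based voxel indices to mm.
#' @param origin_mm mm coordinate of voxel (0,0,0); ignored when `affine`
#'   is given.
#' @return An object of class `volume_grid` with fields `shape`,
#'   `voxel_size_mm`, `affine`.
#' @examples
#' g <- volume_grid(c(40, 48, 34))
#' mm_to_voxel(c(-4, 48, 12), g)
#' @export
volume_grid <- function(shape, voxel_size_mm = c(2, 2, 2), affine = NULL,
                        origin_mm = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(affine)) {
    if (is.null(origin_mm)) {
      origin_mm <- c(-40, -44, -24) * voxel_size_mm * shape /
        (c(2, 2, 2) * c(40, 48, 34))
      # for non-default grids this just centres a proportional bounding box
    }
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(voxel_size_mm, 3, 3)
    affine[1:3, 4] <- origin_mm
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps)
    stop("affine must be invertible")
  colnorm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(colnorm - voxel_size_mm) > 1e-6 * voxel_size_mm))
    stop("affine column norms do not match voxel_size_mm")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels, %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$affine - b$affine) <= tol * (1 + abs(b$affine)))
}

#' Scalar volume on a grid
#'
#' A `stat_volume` couples a 3-D numeric array to its [volume_grid()] and a
#' tag describing the quantity it stores (per-subject contrast, group t, z,
#' log posterior odds, posterior mean or posterior variance).
#'
#' @param values numeric 3-D array, dimensions equal to `grid$shape`.
#' @param grid a [volume_grid()].
#' @param kind one of `"contrast"`, `"t"`, `"z"`, `"logodds"`,
#'   `"posterior_mean"`, `"posterior_var"`.
#' @return An object of class `stat_volume`.
#' @export
stat_volume <- function(values, grid, kind = "contrast") {
  kind <- match.arg(kind, c("contrast", "t", "z", "logodds",
                            "posterior_mean", "posterior_var"))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
    stop("values shape does not match grid shape")
  structure(list(values = values, grid = grid, kind = kind),
            class = "stat_volume")
}

#' @export
print.stat_volume <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("stat_volume[%s]: %s voxels, range [%.4g, %.4g]\n", x$kind,
              paste(x$grid$shape, collapse = "x"), rng[1], rng[2]))
  invisible(x)
}

#' Brain mask
#'
#' Logical per-voxel map of the search region; `V` is the in-mask voxel
#' count, the search volume used by multiple-comparison corrections.
#'
#' @param inside logical 3-D array matching `grid$shape`.
#' @param grid a [volume_grid()].
#' @return An object of class `brain_mask` with fields `inside`, `grid`, `V`.
#' @export
brain_mask <- function(inside, grid) {
  inside <- array(as.logical(inside), dim = grid$shape)
  V <- sum(inside)
  if (V < 1L) stop("mask must contain at least one voxel")
  structure(list(inside = inside, grid = grid, V = V),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("brain_mask: V = %d of %d voxels\n", x$V, prod(x$grid$shape)))
  invisible(x)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert mm coordinates to voxel indices
#'
#' Applies the inverse of the grid affine and rounds half away from zero.
#' Indices are 0-based (NIfTI convention); add 1 to index R arrays.
#'
#' @param coord_mm numeric vector of length 3 (mm).
#' @param grid a [volume_grid()].
#' @return integer vector of length 3 (0-based voxel index).
#' @export
mm_to_voxel <- function(coord_mm, grid) {
  stopifnot(length(coord_mm) == 3L)
  v <- solve(grid$affine, c(as.numeric(coord_mm), 1))[1:3]
  idx <- as.integer(round_half_away(v))
  if (any(idx < 0L) || any(idx > grid$shape - 1L))
    stop(sprintf("coordinate (%s) mm maps outside the grid",
                 paste(coord_mm, collapse = ", ")))
  idx
}

#' Convert voxel indices to mm coordinates
#'
#' @param idx0 0-based voxel index (length 3, or an n x 3 matrix).
#' @param grid a [volume_grid()].
#' @return mm coordinates, same shape as the input.
#' @export
voxel_to_mm <- function(idx0, grid) {
  if (is.matrix(idx0)) {
    mm <- grid$affine %*% rbind(t(idx0), 1)
    return(t(mm[1:3, , drop = FALSE]))
  }
  (grid$affine %*% c(as.numeric(idx0), 1))[1:3]
}
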