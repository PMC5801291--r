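#' Read a single-volume NIfTI image
#'
#' Loads a 3-D NIfTI-1/2 image (.nii or .nii.gz) into a [stat_volume()].
#' The voxel sizes are taken from the affine column norms so that grid
#' geometry and affine are always consistent. Trailing singleton dimensions
#' are squeezed; genuinely 4-D files are rejected, since second-level input
#' is one contrast image per subject.
#'
#' @param path path to an existing NIfTI file.
#' @param kind tag for the stored quantity (see [stat_volume()]); the file
#'   format does not record this, so the caller declares it.
#' @return A [stat_volume()].
#' @export
read_nifti <- function(path, kind = "contrast") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    extra <- d[-(1:3)]
    if (any(extra != 1L))
      stop("expected 3-D volume, got ", length(d), "-D image with ",
           prod(extra), " volumes: ", path)
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) stop("expected 3-D volume: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (!all(is.finite(aff))) stop("non-finite affine in ", path)
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- volume_grid(d, voxel_size_mm = vox, affine = aff)
  stat_volume(array(as.numeric(img), dim = d), grid, kind = kind)
}

#' Write a volume to NIfTI
#'
#' Writes a [stat_volume()] to disk as float32 with the grid affine stored
#' in both the sform and qform. NaN values (conventionally used outside the
#' analysis mask) are preserved.
#'
#' @param vol a [stat_volume()].
#' @param path output path (.nii or .nii.gz).
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "stat_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$grid$voxel_size_mm
  img <- RNifti::`sform<-`(img, structure(vol$grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$grid$affine, code = 2L))
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = "float")
    TRUE
  }, error = function(e) stop("cannot write NIfTI to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a brain mask from NIfTI
#'
#' Nonzero, finite voxels are inside the mask.
#'
#' @param path path to a NIfTI file.
#' @return A [brain_mask()].
#' @export
read_mask <- function(path) {
  vol <- read_nifti(path, kind = "contrast")
  inside <- is.finite(vol$values) & vol$values != 0
  brain_mask(inside, vol$grid)
}

#' Read a directory of per-subject contrast images
#'
#' Loads every `.nii`/`.nii.gz` file in `dir` (sorted by filename) as one
#' subject's contrast image, checks that all share one grid, and pairs them
#' with a mask (from `mask_path`, or the voxels finite and nonzero in every
#' image when no mask file is given).
#'
#' @param dir directory containing one 3-D NIfTI per subject.
#' @param mask_path optional path to a mask NIfTI on the same grid.
#' @return A `subject_image_set`.
#' @export
read_subject_dir <- function(dir, mask_path = NULL) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) < 2L)
    stop("need at least 2 contrast images in ", dir)
  images <- lapply(files, read_nifti, kind = "contrast")
  grid <- images[[1L]]$grid
  for (im in images[-1L])
    if (!same_grid(im$grid, grid)) stop("grid mismatch across images in ", dir)
  if (!is.null(mask_path)) {
    mask <- read_mask(mask_path)
    if (!same_grid(mask$grid, grid)) stop("mask grid mismatch")
  } else {
    inside <- Reduce(`&`, lapply(images, function(im)
      is.finite(im$values) & im$values != 0))
    mask <- brain_mask(inside, grid)
  }
  subject_image_set(images, mask)
}

#' Bundle per-subject images with a mask
#'
#' @param images list of [stat_volume()] objects (kind `"contrast"`), one
#'   per subject, sharing one grid.
#' @param mask a [brain_mask()] on the same grid.
#' @return An object of class `subject_image_set`.
#' @export
subject_image_set <- function(images, mask) {
  if (length(images) < 2L) stop("need at least 2 subject images")
  grid <- images[[1L]]$grid
  for (im in images)
    if (!same_grid(im$grid, grid)) stop("grid mismatch across subject images")
  if (!same_grid(mask$grid, grid)) stop("mask grid mismatch")
  structure(list(images = images, mask = mask, grid = grid),
            class = "subject_image_set")
}

#' @export
print.subject_image_set <- function(x, ...) {
  cat(sprintf("subject_image_set: n = %d subjects, V = %d in-mask voxels\n",
              length(x$images), x$mask$V))
  invisible(x)
}
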