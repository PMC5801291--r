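# shared fixtures and independent oracles

# brute-force BFS flood fill, independent of the package's igraph labeling
flood_fill_oracle <- function(binary, connectivity) {
  dims <- dim(binary)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  l1 <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = l1 == 1,
                      "18" = l1 >= 1 & l1 <= 2,
                      "26" = l1 >= 1), , drop = FALSE]
  labels <- array(0L, dim = dims)
  lab <- 0L
  for (lin in which(binary)) {
    if (labels[lin] > 0L) next
    lab <- lab + 1L
    queue <- lin
    labels[lin] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- ijk + offs[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        nlin <- (nb[3] - 1) * dims[1] * dims[2] + (nb[2] - 1) * dims[1] + nb[1]
        if (binary[nlin] && labels[nlin] == 0L) {
          labels[nlin] <- lab
          queue <- c(queue, nlin)
        }
      }
    }
  }
  labels
}

# canonical form of a labeling: each voxel tagged by its cluster's smallest
# linear index, so two labelings agree iff they induce the same partition
canonical_partition <- function(labels) {
  out <- array(0L, dim = dim(labels))
  act <- which(labels > 0L)
  if (!length(act)) return(out)
  reps <- tapply(act, labels[act], min)
  out[act] <- as.integer(reps[as.character(labels[act])])
  out
}

# subject image set built directly from a list of 3-D arrays
images_from_arrays <- function(arrs, mask_inside = NULL,
                               voxel_size_mm = c(2, 2, 2)) {
  grid <- volume_grid(dim(arrs[[1]]), voxel_size_mm)
  if (is.null(mask_inside)) mask_inside <- array(TRUE, dim = grid$shape)
  subject_image_set(lapply(arrs, stat_volume, grid = grid,
                           kind = "contrast"),
                    brain_mask(mask_inside, grid))
}

# minimal group_glm_result with prescribed per-voxel means and variances
fake_glm <- function(beta, resid_var, n) {
  beta <- as.array(beta); resid_var <- as.array(resid_var)
  if (length(dim(beta)) == 1L) {
    d <- c(length(beta), 1L, 1L)
    beta <- array(beta, d); resid_var <- array(resid_var, d)
  }
  grid <- volume_grid(dim(beta), c(2, 2, 2))
  tval <- ifelse(resid_var > 0, beta / sqrt(resid_var / n), 0)
  mask <- brain_mask(array(TRUE, dim = grid$shape), grid)
  structure(list(beta_hat = stat_volume(beta, grid, "contrast"),
                 resid_var = stat_volume(resid_var, grid, "contrast"),
                 tmap = stat_volume(tval, grid, "t"),
                 df = n - 1L, n = n, mask = mask,
                 zero_var = array(FALSE, dim = grid$shape),
                 usable = array(resid_var > 0, dim = grid$shape)),
            class = "group_glm_result")
}

# small smooth dataset with one planted blob, reused across tests
small_blob_dataset <- function(seed = 42, d_true = 2, n = 16,
                               shape = c(20, 20, 16)) {
  ctr <- as.integer(shape / 2)
  generate_subject_images(synthetic_spec(
    grid_shape = shape, n_subjects = n, sigma_between = 1,
    smooth_fwhm_voxels = 2,
    blobs = list(activation_blob(ctr, 3, d_true)),
    mask_shape = "box", seed = seed))
}
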