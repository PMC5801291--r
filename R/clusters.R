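#' Neighborhood offsets for 3-D connectivity
#'
#' 6 = faces, 18 = faces + edges, 26 = faces + edges + corners. Only the
#' lexicographically positive half is returned when `half = TRUE` (each
#' unordered neighbor pair once).
#' @noRd
conn_offsets <- function(connectivity, half = FALSE) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  l1 <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = l1 == 1,
                 "18" = l1 >= 1 & l1 <= 2,
                 "26" = l1 >= 1)
  g <- g[keep, , drop = FALSE]
  if (half) {
    pos <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
    g <- g[pos, , drop = FALSE]
  }
  g
}

#' Label connected suprathreshold clusters
#'
#' Connected-component labeling of a binary 3-D map under 6-, 18- or
#' 26-neighborhood connectivity, with a deterministic labeling order:
#' clusters are numbered 1, 2, ... by descending size, ties broken by the
#' smallest linear voxel index. The default connectivity 18 (faces + edges)
#' matches the convention common in SPM-style cluster reporting.
#'
#' @param binary logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @param values optional numeric array of the same shape used to locate
#'   each cluster's peak (defaults to the binary map itself).
#' @param grid optional [volume_grid()] used to report peak coordinates in
#'   mm; without it, peaks are reported at 0-based voxel indices.
#' @return A list with `labels` (integer array, 0 = background) and
#'   `table`, a data frame with columns `cluster_id`, `size_voxels`,
#'   `peak_value`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `fwe_p` (NA until
#'   filled by cluster-level inference).
#' @export
label_clusters <- function(binary, connectivity = 18L, values = NULL,
                           grid = NULL) {
  connectivity <- as.integer(connectivity)
  dims <- dim(binary)
  if (is.null(dims) || length(dims) != 3L)
    stop("binary must be a 3-D array")
  binary <- array(as.logical(binary) & !is.na(binary), dim = dims)
  if (is.null(values)) values <- binary + 0
  act <- which(binary)
  labels <- array(0L, dim = dims)
  empty_tab <- data.frame(cluster_id = integer(0), size_voxels = integer(0),
                          peak_value = numeric(0), peak_x_mm = numeric(0),
                          peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                          fwe_p = numeric(0))
  if (length(act) == 0L)
    return(list(labels = labels, table = empty_tab))
  pos <- integer(prod(dims))
  pos[act] <- seq_along(act)
  ind <- arrayInd(act, dims)
  offs <- conn_offsets(connectivity, half = TRUE)
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(offs))) {
    ni <- ind[, 1] + offs[r, 1]
    nj <- ind[, 2] + offs[r, 2]
    nk <- ind[, 3] + offs[r, 3]
    ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] &
      nk >= 1L & nk <= dims[3]
    if (!any(ok)) next
    nlin <- (nk[ok] - 1L) * dims[1] * dims[2] + (nj[ok] - 1L) * dims[1] +
      ni[ok]
    hit <- binary[nlin]
    if (!any(hit)) next
    efrom <- c(efrom, pos[act[ok][hit]])
    eto <- c(eto, pos[nlin[hit]])
  }
  if (length(efrom)) {
    g <- igraph::make_graph(as.vector(rbind(efrom, eto)), n = length(act),
                            directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(act)
  }
  size <- tabulate(memb)
  minidx <- rep(Inf, length(size))
  mi <- tapply(act, memb, min)
  minidx[as.integer(names(mi))] <- mi
  ord <- order(-size, minidx)
  relab <- integer(length(size))
  relab[ord] <- seq_along(ord)
  memb <- relab[memb]
  labels[act] <- memb
  n_cl <- length(size)
  vals_act <- values[act]
  peak_val <- peak_lin <- numeric(n_cl)
  for (cl in seq_len(n_cl)) {
    sel <- memb == cl
    v <- vals_act[sel]
    pk <- which(v == max(v))
    lin <- act[sel][pk]
    peak_val[cl] <- max(v)
    peak_lin[cl] <- min(lin)
  }
  pk_ind0 <- arrayInd(peak_lin, dims) - 1L
  if (!is.null(grid)) pk_mm <- voxel_to_mm(pk_ind0, grid)
  else pk_mm <- pk_ind0
  tab <- data.frame(cluster_id = seq_len(n_cl),
                    size_voxels = as.integer(tabulate(memb)),
                    peak_value = peak_val,
                    peak_x_mm = pk_mm[, 1], peak_y_mm = pk_mm[, 2],
                    peak_z_mm = pk_mm[, 3], fwe_p = NA_real_)
  list(labels = labels, table = tab)
}

#' Write a cluster table to CSV
#'
#' @param table data frame as returned in `label_clusters()$table`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cluster_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
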