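#' Read / write 3D image stacks as multi-page TIFF
#'
#' One TIFF file per time point, one page per z slice, intensities stored as
#' 32-bit float. Voxel size is not carried by plain TIFF, so it is supplied
#' at read time.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   an [image_stack()].
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) abort("`stack` must be an image_stack.")
  d <- dim(stack$voxels)
  pages <- map(seq_len(d[3]), ~ t(stack$voxels[, , .x]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @param voxel_size Micrometres per voxel per axis, attached on read.
#' @param time_index,dt Frame metadata attached on read.
#' @export
read_stack <- function(path, voxel_size = c(1, 1, 1), time_index = 0L,
                       dt = 2) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  first <- pages[[1]]
  vox <- array(0, c(ncol(first), nrow(first), nz))
  for (z in seq_len(nz)) vox[, , z] <- t(pages[[z]])
  image_stack(vox, voxel_size = voxel_size, time_index = time_index, dt = dt)
}

#' Write / read a displacement grid as CSV
#'
#' One row per mesh node; the mesh geometry (dimensions, node spacing, voxel
#' size) is stored as repeated constant columns so the CSV is
#' self-contained.
#'
#' @param grid A [displacement_grid()].
#' @param path CSV path.
#' @return `write_displacements()` returns `path` invisibly;
#'   `read_displacements()` returns a [displacement_grid()].
#' @export
write_displacements <- function(grid, path) {
  if (!inherits(grid, "displacement_grid")) {
    abort("`grid` must be a displacement_grid.")
  }
  md <- attr(grid, "mesh_dims")
  ns <- attr(grid, "node_spacing")
  vs <- attr(grid, "voxel_size")
  df <- as_tibble(grid)
  df$mesh_nx <- md[1]; df$mesh_ny <- md[2]; df$mesh_nz <- md[3]
  df$spacing_x <- ns[1]; df$spacing_y <- ns[2]; df$spacing_z <- ns[3]
  df$voxel_x <- vs[1]; df$voxel_y <- vs[2]; df$voxel_z <- vs[3]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_displacements
#' @export
read_displacements <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  md <- c(df$mesh_nx[1], df$mesh_ny[1], df$mesh_nz[1])
  ns <- c(df$spacing_x[1], df$spacing_y[1], df$spacing_z[1])
  vs <- c(df$voxel_x[1], df$voxel_y[1], df$voxel_z[1])
  nodes <- select(df, -dplyr::starts_with("mesh_"),
                  -dplyr::starts_with("spacing_"),
                  -dplyr::starts_with("voxel_"))
  displacement_grid(nodes, mesh_dims = md, node_spacing = ns, voxel_size = vs)
}

#' Write / read a spectra matrix as CSV
#'
#' Long-format CSV: first column `ppm`, one column per sample.
#'
#' @param spectra A [spectra_matrix()].
#' @param path CSV path.
#' @return `write_spectra()` returns `path` invisibly; `read_spectra()`
#'   returns a [spectra_matrix()] in state `"raw"`.
#' @export
write_spectra <- function(spectra, path) {
  sm <- as_spectra_matrix(spectra)
  df <- data.frame(ppm = sm$ppm_axis, t(sm$X))
  names(df) <- c("ppm", paste0("sample_", seq_len(nrow(sm$X))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path)
  spectra_matrix(df$ppm, t(as.matrix(df[, -1, drop = FALSE])))
}
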