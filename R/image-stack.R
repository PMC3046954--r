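#' Image stack container
#'
#' A 3D voxel grid with physical calibration, per-slice alignment offsets and
#' per-slice photon gains. Voxels are stored as an array with dimensions
#' `(ny, nx, nz)`; slice `k` is `voxels[, , k]` with rows indexing y and
#' columns indexing x.
#'
#' @param voxels 3D numeric array `(ny, nx, nz)` of nonnegative intensities.
#' @param pixel_size_nm lateral calibration.
#' @param z_step_nm axial slice spacing.
#' @param per_slice_gain optional numeric vector, one positive gain per slice.
#' @param per_slice_offsets optional integer matrix `nz x 2` of applied
#'   `(dy, dx)` shifts.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_nm = 75.7, z_step_nm = 420,
                        per_slice_gain = NULL, per_slice_offsets = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (ny, nx, nz)", call. = FALSE)
  nz <- dim(voxels)[3]
  if (is.null(per_slice_gain)) per_slice_gain <- rep(1, nz)
  if (is.null(per_slice_offsets))
    per_slice_offsets <- matrix(0L, nz, 2, dimnames = list(NULL, c("dy", "dx")))
  structure(list(voxels = voxels, pixel_size_nm = pixel_size_nm,
                 z_step_nm = z_step_nm, per_slice_gain = per_slice_gain,
                 per_slice_offsets = per_slice_offsets),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d px, %d slices (pixel %g nm, z %g nm)\n",
              d[2], d[1], d[3], x$pixel_size_nm, x$z_step_nm))
  cat(sprintf("  intensity range [%.3g, %.3g], gains [%.3g, %.3g]\n",
              min(x$voxels), max(x$voxels),
              min(x$per_slice_gain), max(x$per_slice_gain)))
  invisible(x)
}

#' Read and write image stacks as multi-page TIFF
#'
#' Values are scaled into \[0, 1\] for storage (TIFF convention of the tiff
#' package); the scale factor is recorded so `read_stack()` restores the
#' original units.
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   an `image_stack`.
#' @export
write_stack <- function(stack, path) {
  v <- stack$voxels
  scale <- max(v, 1e-12)
  slices <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(scale = scale, pixel_size_nm = stack$pixel_size_nm,
               z_step_nm = stack$z_step_nm,
               per_slice_gain = stack$per_slice_gain)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(scale = 1, pixel_size_nm = 75.7, z_step_nm = 420,
         per_slice_gain = NULL)
  v <- array(0, c(dim(slices[[1]])[1:2], length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    if (length(dim(s)) == 3L) s <- s[, , 1]
    v[, , k] <- s
  }
  v <- v * as.numeric(meta$scale)
  image_stack(v, pixel_size_nm = as.numeric(meta$pixel_size_nm),
              z_step_nm = as.numeric(meta$z_step_nm),
              per_slice_gain = if (is.null(meta$per_slice_gain)) NULL else
                as.numeric(unlist(meta$per_slice_gain)))
}
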