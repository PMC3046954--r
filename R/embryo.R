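#' Embryo model describing geometry, calibration and developmental stage
#'
#' Describes the idealised half-embryo represented by a rendered image stack:
#' an ellipse of egg length `length_um` and width `width_um` in the
#' midsagittal plane, imaged with lateral pixel size `pixel_size_nm` and
#' axial step `z_step_nm`. The `stage` is a nuclear-cycle label (3--14), and
#' `geometry_mode` selects the mRNA spatial layout: `"wedge"` is the
#' interior-enriched anterior cone seen in cleavage-stage embryos, `"cup"`
#' the cortical shell covering the anterior pole from blastoderm stages on.
#'
#' @param length_um egg length L in micrometres (anterior-posterior).
#' @param width_um minor (dorsoventral) diameter in micrometres.
#' @param pixel_size_nm lateral pixel calibration in nanometres.
#' @param z_step_nm axial slice spacing in nanometres.
#' @param stage nuclear-cycle label, integer in 3..14.
#' @param geometry_mode `"wedge"` or `"cup"`.
#' @return An object of class `embryo_model`.
#' @examples
#' embryo_model(stage = 12, geometry_mode = "cup")
#' @export
embryo_model <- function(length_um = 500, width_um = 180,
                         pixel_size_nm = 75.7, z_step_nm = 420,
                         stage = 4, geometry_mode = c("wedge", "cup")) {
  geometry_mode <- match.arg(geometry_mode)
  stopifnot_scalar(length_um, "length_um")
  stopifnot_scalar(width_um, "width_um")
  stopifnot_scalar(pixel_size_nm, "pixel_size_nm")
  stopifnot_scalar(z_step_nm, "z_step_nm")
  if (length_um <= width_um)
    stop("length_um must exceed width_um", call. = FALSE)
  stage <- as.integer(stage)
  if (is.na(stage) || stage < 3L || stage > 14L)
    stop("stage must be an integer nuclear cycle in 3..14", call. = FALSE)
  structure(list(length_um = length_um, width_um = width_um,
                 pixel_size_nm = pixel_size_nm, z_step_nm = z_step_nm,
                 stage = stage, geometry_mode = geometry_mode),
            class = "embryo_model")
}

#' Desk-scale embryo model for reduced synthetic stacks
#'
#' A convenience configuration in which one lateral pixel corresponds to
#' 1 um, so that the full 500 um egg length fits in a ~512-pixel stack.
#' The PSF-to-pixel ratio of the rendering defaults is preserved, so the
#' detection algorithm behaves as on full-scale data.
#'
#' @param stage nuclear-cycle label.
#' @param geometry_mode mRNA layout; defaults to `"wedge"` for stages before
#'   nuclear cycle 7 and `"cup"` otherwise.
#' @return An `embryo_model`.
#' @export
reduced_embryo_model <- function(stage = 4, geometry_mode = NULL) {
  if (is.null(geometry_mode))
    geometry_mode <- if (stage < 7) "wedge" else "cup"
  embryo_model(length_um = 500, width_um = 180,
               pixel_size_nm = 1000, z_step_nm = 1000,
               stage = stage, geometry_mode = geometry_mode)
}

#' @export
print.embryo_model <- function(x, ...) {
  cat(sprintf(
    "<embryo_model> L = %g um, width = %g um, pixel %g nm, z-step %g nm\n",
    x$length_um, x$width_um, x$pixel_size_nm, x$z_step_nm))
  cat(sprintf("  nuclear cycle %d, geometry '%s'\n", x$stage,
              x$geometry_mode))
  invisible(x)
}

# Half-width of the midsagittal ellipse at fractional egg length ap in [0,1],
# in micrometres.
embryo_half_width_um <- function(model, ap) {
  b <- model$width_um / 2
  t <- pmin(pmax(2 * ap - 1, -1), 1)
  b * sqrt(pmax(0, 1 - t^2))
}

# Layout of the embryo within a stack of nx columns: the AP axis spans
# length_px pixels starting at x0_px (1-based pixel coordinates), centred
# vertically at yc_px.
stack_layout <- function(model, dims) {
  ny <- dims[1]; nx <- dims[2]
  um_per_px <- model$pixel_size_nm / 1000
  length_px <- model$length_um / um_per_px
  if (length_px > nx - 2)
    stop("stack x-dimension too small for embryo length", call. = FALSE)
  if (model$width_um / um_per_px > ny - 2)
    stop("stack y-dimension too small for embryo width", call. = FALSE)
  list(x0_px = (nx - length_px) / 2 + 1, length_px = length_px,
       yc_px = (ny + 1) / 2, um_per_px = um_per_px)
}

#' Rasterise the midsagittal embryo outline as a binary mask
#'
#' @param model an [embryo_model()].
#' @param dims integer `c(ny, nx)` of the target image.
#' @return Logical matrix with `TRUE` inside the embryo ellipse.
#' @export
embryo_mask <- function(model, dims) {
  lay <- stack_layout(model, dims)
  a <- lay$length_px / 2
  b <- (model$width_um / 2) / lay$um_per_px
  xc <- lay$x0_px + a
  yc <- lay$yc_px
  x <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  y <- matrix(seq_len(dims[1]), dims[1], dims[2])
  ((x - xc) / a)^2 + ((y - yc) / b)^2 <= 1
}
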