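#' Extract the anterior-posterior axis from an overview image
#'
#' Thresholds the low-magnification overview to a binary embryo mask (or
#' accepts a logical mask directly), finds the principal axis of the mask
#' pixels, and places the poles at the extremal projections onto it. The egg
#' length L is the pole-to-pole distance. Fails on degenerate (near
#' circular) or non-elliptical (low solidity) masks.
#'
#' @param overview numeric matrix (thresholded at `threshold`) or logical
#'   mask.
#' @param threshold binarisation threshold for numeric input; default half
#'   the maximum.
#' @param anterior_hint unit-ish vector `(x, y)`; the pole with the larger
#'   projection onto this direction is called anterior. Default: the
#'   leftmost pole (anterior at low x).
#' @param min_elongation minimum major/minor axis ratio (rejects circles).
#' @param min_solidity minimum area / convex hull area.
#' @return An object of class `axis_registration` with `anterior_xy`,
#'   `posterior_xy` (pixel coordinates `(x, y)`), `L` (pixels), the unit
#'   `axis` vector and the `mask`.
#' @export
extract_axis <- function(overview, threshold = NULL,
                         anterior_hint = c(-1, 0),
                         min_elongation = 1.2, min_solidity = 0.8) {
  mask <- if (is.logical(overview)) overview else {
    thr <- threshold %||% (max(overview) / 2)
    overview > thr
  }
  if (!any(mask)) stop("empty embryo mask", call. = FALSE)
  ij <- which(mask, arr.ind = TRUE)
  pts <- cbind(x = ij[, 2], y = ij[, 1])
  # solidity: mask area over convex hull area
  hull <- pts[chull(pts), , drop = FALSE]
  hx <- hull[, 1]; hy <- hull[, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (hull_area > 0 && nrow(pts) / hull_area < min_solidity)
    stop("mask not elliptical (solidity < ", min_solidity, ")",
         call. = FALSE)
  ctr <- colMeans(pts)
  cv <- cov(sweep(pts, 2, ctr))
  eg <- eigen(cv, symmetric = TRUE)
  if (sqrt(eg$values[1] / max(eg$values[2], 1e-12)) < min_elongation)
    stop("degenerate mask: no principal axis (near-circular)",
         call. = FALSE)
  ax <- eg$vectors[, 1]
  proj <- as.vector(sweep(pts, 2, ctr) %*% ax)
  p1 <- pts[which.min(proj), ]
  p2 <- pts[which.max(proj), ]
  if (sum((p2 - p1) * anterior_hint) > sum((p1 - p2) * anterior_hint)) {
    tmp <- p1; p1 <- p2; p2 <- tmp
  }
  L <- sqrt(sum((p2 - p1)^2))
  structure(list(anterior_xy = as.numeric(p1), posterior_xy = as.numeric(p2),
                 L = L, axis = (p2 - p1) / L, mask = mask),
            class = "axis_registration")
}

#' @export
print.axis_registration <- function(x, ...) {
  cat(sprintf("<axis_registration> L = %.1f px, anterior (%.1f, %.1f) -> posterior (%.1f, %.1f)\n",
              x$L, x$anterior_xy[1], x$anterior_xy[2],
              x$posterior_xy[1], x$posterior_xy[2]))
  invisible(x)
}

#' Axis registration from a known embryo model (synthetic bypass)
#'
#' For synthetic stacks the generator's layout is known exactly, so the
#' registration can be constructed analytically instead of being extracted
#' from an overview image.
#'
#' @param model an [embryo_model()].
#' @param dims stack dimensions `c(ny, nx)` or `c(ny, nx, nz)`.
#' @return An `axis_registration`.
#' @export
known_registration <- function(model, dims) {
  lay <- stack_layout(model, dims[1:2])
  mask <- embryo_mask(model, dims[1:2])
  structure(list(anterior_xy = c(lay$x0_px, lay$yc_px),
                 posterior_xy = c(lay$x0_px + lay$length_px, lay$yc_px),
                 L = lay$length_px, axis = c(1, 0), mask = mask),
            class = "axis_registration")
}

#' Project particles into fractional embryo coordinates
#'
#' Computes for each particle its fractional egg length `ap_fraction` = x/L
#' (0 at the anterior pole) by projection onto the AP axis, and its
#' fractional distance from the cortex `d_l` = d/L, where d is the distance
#' to the embryo outline in the midsagittal plane (via the distance
#' transform of the registration mask). Particles mapping outside the mask
#' by more than `tolerance_px` are flagged and excluded.
#'
#' @param particles data frame with `x_c`, `y_c` (or `x_px`, `y_px`).
#' @param registration an `axis_registration`.
#' @param tolerance_px allowed excursion outside the mask.
#' @return The particle table with `ap_fraction` and `d_l` columns; excluded
#'   rows are dropped, their count attached as attribute `"n_outside"`.
#' @export
project_particles <- function(particles, registration, tolerance_px = 2) {
  x <- particles$x_c %||% particles$x_px
  y <- particles$y_c %||% particles$y_px
  rel <- cbind(x - registration$anterior_xy[1],
               y - registration$anterior_xy[2])
  ap <- pmin(pmax(as.vector(rel %*% registration$axis) / registration$L, 0), 1)
  dmap <- EBImage::distmap(registration$mask)
  dmap <- dmap@.Data
  xi <- pmin(pmax(round(x), 1), ncol(dmap))
  yi <- pmin(pmax(round(y), 1), nrow(dmap))
  d_px <- dmap[cbind(yi, xi)]
  outside <- d_px == 0
  # allow a small excursion: use distance to mask for outside points
  if (any(outside)) {
    inv <- EBImage::distmap(!registration$mask)@.Data
    excl <- inv[cbind(yi, xi)] > tolerance_px
    outside <- outside & excl
  }
  out <- particles[!outside, , drop = FALSE]
  out$ap_fraction <- ap[!outside]
  out$d_l <- d_px[!outside] / registration$L
  rownames(out) <- NULL
  attr(out, "n_outside") <- sum(outside)
  out
}

#' Binned anterior-posterior distribution of particles
#'
#' Bins particles on x/L into `n_bins` equal half-open intervals (final bin
#' closed) and reports per-bin counts, summed intensity, mean particle
#' intensity and the cumulative intensity fraction.
#'
#' @param particles data frame with `ap_fraction` and `intensity`.
#' @param n_bins number of bins on (0, 1].
#' @return An object of class `ap_distribution`: data frame with
#'   `bin_center`, `count`, `intensity`, `mean_intensity`,
#'   `cumulative_fraction`; attribute `"empty"` flags a zero-particle input.
#' @export
ap_distribution <- function(particles, n_bins = 50) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  if (nrow(particles) == 0) {
    out <- data.frame(bin_center = centers, count = 0, intensity = 0,
                      mean_intensity = NA_real_, cumulative_fraction = NA_real_)
    return(structure(out, class = c("ap_distribution", "data.frame"),
                     empty = TRUE))
  }
  bin <- pmin(findInterval(particles$ap_fraction, edges,
                           rightmost.closed = TRUE), n_bins)
  count <- tabulate(bin, n_bins)
  inten <- vapply(seq_len(n_bins), function(b)
    sum(particles$intensity[bin == b]), numeric(1))
  out <- data.frame(bin_center = centers, count = count, intensity = inten,
                    mean_intensity = ifelse(count > 0, inten / count, NA),
                    cumulative_fraction = cumsum(inten) / sum(inten))
  structure(out, class = c("ap_distribution", "data.frame"), empty = FALSE)
}

#' Cumulative intensity fraction anterior of a position
#'
#' @param particles data frame with `ap_fraction` and `intensity`.
#' @param x_l fractional egg length cut-off.
#' @return Fraction of total intensity at `ap_fraction <= x_l`.
#' @export
intensity_fraction <- function(particles, x_l = 0.2) {
  sum(particles$intensity[particles$ap_fraction <= x_l]) /
    sum(particles$intensity)
}

#' Particle density versus fractional distance from the cortex
#'
#' Bins midsagittal-plane particles on d/L and divides counts by the area
#' (pixel count) of each depth shell of the mask, giving a density per unit
#' area as a function of depth below the surface.
#'
#' @param particles data frame with `d_l` (from [project_particles()]).
#' @param registration an `axis_registration` providing the mask and L.
#' @param n_bins number of depth bins on \[0, max d/L\].
#' @return Data frame of class `depth_profile` with `bin_center`, `count`,
#'   `area_px`, `density`.
#' @export
depth_density <- function(particles, registration, n_bins = 25) {
  dmap <- EBImage::distmap(registration$mask)@.Data
  d_l_map <- dmap[registration$mask] / registration$L
  dmax <- max(c(d_l_map, particles$d_l))
  edges <- seq(0, dmax * (1 + 1e-9), length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bin_p <- pmin(findInterval(particles$d_l, edges, rightmost.closed = TRUE),
                n_bins)
  bin_a <- pmin(findInterval(d_l_map, edges, rightmost.closed = TRUE), n_bins)
  count <- tabulate(bin_p, n_bins)
  area <- tabulate(bin_a, n_bins)
  structure(data.frame(bin_center = centers, count = count, area_px = area,
                       density = ifelse(area > 0, count / area, NA)),
            class = c("depth_profile", "data.frame"))
}

#' Per-embryo and per-stage particle totals
#'
#' @param tables named list of particle tables (one per embryo), each with
#'   an `intensity` column and a `stage` attribute or column.
#' @return List with `per_embryo` (count, total and mean intensity per
#'   embryo) and `per_stage` (mean and SD of the totals by nuclear cycle).
#' @export
stage_summaries <- function(tables) {
  if (!length(tables)) stop("need at least one particle table", call. = FALSE)
  per <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    stage <- attr(tb, "stage", exact = TRUE) %||% tb$stage[1]
    data.frame(embryo = names(tables)[i] %||% as.character(i),
               stage = as.integer(stage), count = nrow(tb),
               total_intensity = sum(tb$intensity),
               mean_intensity = if (nrow(tb)) mean(tb$intensity) else NA_real_)
  }))
  agg <- do.call(rbind, lapply(split(per, per$stage), function(d)
    data.frame(stage = d$stage[1], n_embryos = nrow(d),
               mean_count = mean(d$count), sd_count = sd(d$count),
               mean_total_intensity = mean(d$total_intensity),
               sd_total_intensity = sd(d$total_intensity))))
  rownames(agg) <- NULL
  list(per_embryo = per, per_stage = agg)
}
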