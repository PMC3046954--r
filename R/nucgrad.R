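#' Segment nuclei in a single-channel stack
#'
#' Gaussian-smooths each z-slice, thresholds it (Otsu per slice), and labels
#' connected voxels in 3D. For blastoderm stages (nuclear cycle >= 10) a
#' watershed on the 3D distance transform separates closely spaced nuclei.
#' Objects smaller than `min_volume_frac` of the median object volume are
#' discarded.
#'
#' @param stack an [image_stack()] (DAPI or histone-RFP channel).
#' @param stage nuclear-cycle label; watershed splitting is applied for
#'   `stage >= watershed_from`.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param threshold absolute threshold; default Otsu per slice on the
#'   smoothed image.
#' @param watershed_from stage at which watershed splitting starts.
#' @param min_volume_frac minimum object volume as a fraction of the median.
#' @return Integer 3D array of nucleus labels (0 = background); the number
#'   of nuclei is attached as attribute `"n_nuclei"`.
#' @export
segment_nuclei <- function(stack, stage = 12, smooth_sigma = 1,
                           threshold = NULL, watershed_from = 10,
                           min_volume_frac = 0.3) {
  v <- stack$voxels
  nz <- dim(v)[3]
  sm <- v
  for (k in seq_len(nz))
    sm[, , k] <- conv_sep(v[, , k], gauss_kernel1d(smooth_sigma))
  bin <- array(FALSE, dim(v))
  for (k in seq_len(nz)) {
    s <- sm[, , k]
    thr <- threshold %||% tryCatch({
      rng <- range(s)
      if (diff(rng) < 1e-12) Inf else
        EBImage::otsu(EBImage::Image((s - rng[1]) / diff(rng))) *
          diff(rng) + rng[1]
    }, error = function(e) Inf)
    bin[, , k] <- s > thr
  }
  if (!any(bin)) {
    lab <- array(0L, dim(v))
    attr(lab, "n_nuclei") <- 0L
    return(lab)
  }
  comp <- label_components_3d(bin)
  if (stage >= watershed_from) {
    # split touching nuclei: watershed of the distance transform, taken
    # within each connected component
    ws <- EBImage::watershed(EBImage::distmap(bin), tolerance = 1)
    ws <- array(as.integer(EBImage::imageData(ws)), dim(v))
    pair <- (comp - 1L) * (max(ws) + 1L) + ws
    pair[comp == 0L] <- 0L
    ids <- sort(unique(pair[pair > 0L]))
    lab <- array(0L, dim(v))
    lab[pair > 0L] <- match(pair[pair > 0L], ids)
  } else {
    lab <- comp
  }
  # size screen: discard fragments well below the median object volume
  vol <- tabulate(lab[lab > 0])
  if (length(vol)) {
    small <- which(vol < min_volume_frac * median(vol[vol > 0]))
    if (length(small)) lab[lab %in% small] <- 0L
    # relabel compactly
    ids <- sort(unique(lab[lab > 0]))
    lut <- integer(max(ids, 1))
    lut[ids] <- seq_along(ids)
    lab[lab > 0] <- lut[lab[lab > 0]]
  }
  attr(lab, "n_nuclei") <- length(unique(lab[lab > 0]))
  lab
}

# 3D connected components (6-connectivity): 2D labelling per slice, then
# union-find merging of labels that overlap between adjacent slices.
label_components_3d <- function(bin) {
  d <- dim(bin)
  nz <- d[3]
  lab <- array(0L, d)
  offset <- 0L
  for (k in seq_len(nz)) {
    lk <- EBImage::bwlabel(bin[, , k])
    lk <- array(as.integer(EBImage::imageData(lk)), d[1:2])
    lk[lk > 0L] <- lk[lk > 0L] + offset
    lab[, , k] <- lk
    offset <- max(offset, max(lk))
  }
  if (offset == 0L) {
    attr(lab, "n_nuclei") <- 0L
    return(lab)
  }
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nz - 1L)) {
    a <- lab[, , k]; b <- lab[, , k + 1L]
    both <- a > 0L & b > 0L
    if (!any(both)) next
    for (p in unique(a[both] * (offset + 1L) + b[both])) {
      ra <- find(as.integer(p %/% (offset + 1L)))
      rb <- find(as.integer(p %% (offset + 1L)))
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(offset), find, integer(1))
  ids <- sort(unique(root))
  lab[lab > 0L] <- match(root[lab[lab > 0L]], ids)
  lab
}

#' Measure per-nucleus channel intensities and positions
#'
#' @param labels labelled 3D array from [segment_nuclei()].
#' @param gfp,rfp [image_stack()]s of the gradient and reference channels.
#' @param registration an `axis_registration` (or `NULL`) used to compute
#'   x/L from the centroid; with `NULL`, `ap_fraction` is `NA`.
#' @param z_step_um axial spacing in micrometres used for depth below the
#'   surface (slice 1 is depth 0); default from the gfp stack calibration.
#' @param drop_boundary drop nuclei touching the stack border.
#' @param erode_px erode each nucleus mask laterally by this many pixels
#'   before averaging, so means sample the nuclear core rather than the
#'   partial-volume rim (labels that would vanish keep their full mask).
#' @return Data frame of class `nucleus_records`: `label`, `x_px`, `y_px`,
#'   `z_slice`, `ap_fraction`, `depth_um`, `mean_gfp_raw`, `mean_rfp_raw`,
#'   `volume_vox`.
#' @export
measure_nuclei <- function(labels, gfp, rfp, registration = NULL,
                           z_step_um = NULL, drop_boundary = TRUE,
                           erode_px = 1L) {
  if (!all(dim(labels) == dim(gfp$voxels)) ||
      !all(dim(labels) == dim(rfp$voxels)))
    stop("channel dimensions do not match the label array", call. = FALSE)
  z_step_um <- z_step_um %||% (gfp$z_step_nm / 1000)
  labels_full <- labels
  if (erode_px > 0) {
    core <- labels
    for (k in seq_len(dim(labels)[3])) {
      dmk <- EBImage::distmap(labels[, , k] > 0L)@.Data
      sl <- labels[, , k]
      sl[dmk <= erode_px] <- 0L
      core[, , k] <- sl
    }
    # labels erased entirely by erosion keep their full mask
    gone <- setdiff(unique(labels[labels > 0L]), unique(core[core > 0L]))
    core[array(labels %in% gone, dim(labels))] <-
      labels[array(labels %in% gone, dim(labels))]
    labels <- core
  }
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids))
    return(structure(data.frame(label = integer(), x_px = numeric(),
                                y_px = numeric(), z_slice = numeric(),
                                ap_fraction = numeric(), depth_um = numeric(),
                                mean_gfp_raw = numeric(),
                                mean_rfp_raw = numeric(),
                                volume_vox = integer()),
                     class = c("nucleus_records", "data.frame")))
  idx <- which(labels > 0)
  lab <- labels[idx]
  d <- dim(labels)
  yy <- (idx - 1) %% d[1] + 1
  xx <- ((idx - 1) %/% d[1]) %% d[2] + 1
  zz <- (idx - 1) %/% (d[1] * d[2]) + 1
  gv <- gfp$voxels[idx]; rv <- rfp$voxels[idx]
  agg <- function(v) as.numeric(tapply(v, lab, mean))
  out <- data.frame(label = as.integer(names(tapply(gv, lab, mean))),
                    x_px = agg(xx), y_px = agg(yy), z_slice = agg(zz),
                    ap_fraction = NA_real_, depth_um = NA_real_,
                    mean_gfp_raw = agg(gv), mean_rfp_raw = agg(rv),
                    volume_vox = as.integer(tabulate(factor(lab))))
  out$depth_um <- (out$z_slice - 1) * z_step_um
  if (!is.null(registration)) {
    rel <- cbind(out$x_px - registration$anterior_xy[1],
                 out$y_px - registration$anterior_xy[2])
    out$ap_fraction <- pmin(pmax(
      as.vector(rel %*% registration$axis) / registration$L, 0), 1)
  }
  if (drop_boundary) {
    idx_f <- which(labels_full > 0)
    lab_f <- labels_full[idx_f]
    yy_f <- (idx_f - 1) %% d[1] + 1
    xx_f <- ((idx_f - 1) %/% d[1]) %% d[2] + 1
    at_edge <- tapply(yy_f, lab_f, min) <= 1 |
      tapply(yy_f, lab_f, max) >= d[1] |
      tapply(xx_f, lab_f, min) <= 1 |
      tapply(xx_f, lab_f, max) >= d[2]
    out <- out[!at_edge[match(out$label, as.integer(names(at_edge)))], ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("nucleus_records", "data.frame"))
}

#' Correct depth attenuation using the uniform reference channel
#'
#' All nuclei carry nominally the same histone-RFP concentration, so any
#' systematic decrease of mean RFP with depth reflects optical attenuation
#' common to both channels. A smooth curve (loess) is fitted to mean RFP vs
#' depth; if it is not monotone decreasing within tolerance, an exponential
#' fit is used instead (with a warning). Each nucleus's GFP is multiplied by
#' `curve(ref_depth) / curve(depth)`, with the reference depth taken as the
#' mean depth of the shallowest decile, so near-surface nuclei are left
#' essentially unchanged.
#'
#' @param records a `nucleus_records` data frame.
#' @param span loess span.
#' @param monotone_tol allowed relative non-monotonicity of the fitted
#'   curve before falling back to the exponential model.
#' @return The records with `mean_gfp_corrected` and `attenuation_factor`
#'   columns.
#' @export
attenuation_correct <- function(records, span = 0.75, monotone_tol = 0.02) {
  if (nrow(records) < 10)
    stop("need >= 10 nuclei spanning a depth range", call. = FALSE)
  d <- records$depth_um
  r <- records$mean_rfp_raw
  if (diff(range(d)) < 1e-9) {
    records$attenuation_factor <- 1
    records$mean_gfp_corrected <- records$mean_gfp_raw
    return(records)
  }
  fit <- loess(r ~ d, span = span, degree = 1)
  ds <- sort(unique(d))
  pred <- predict(fit, data.frame(d = ds))
  rises <- diff(pred) > monotone_tol * max(abs(pred))
  curve_at <- function(x) predict(fit, data.frame(d = x))
  if (any(rises)) {
    warning("RFP-depth relation not monotone; falling back to exponential fit",
            call. = FALSE)
    ef <- lm(log(pmax(r, 1e-9)) ~ d)
    curve_at <- function(x) exp(predict(ef, data.frame(d = x)))
  }
  ref_depth <- mean(d[d <= quantile(d, 0.1)])
  fac <- as.numeric(curve_at(ref_depth)) / as.numeric(curve_at(d))
  records$attenuation_factor <- fac
  records$mean_gfp_corrected <- records$mean_gfp_raw * fac
  records
}

#' Subtract autofluorescence background estimated from posterior nuclei
#'
#' Nuclei at 85--95% EL carry no appreciable gradient signal, so their mean
#' (corrected) GFP estimates the autofluorescent background, which is
#' subtracted from all nuclei. Negative results are clipped to zero.
#'
#' @param records records with `mean_gfp_corrected` (or raw means if
#'   correction was skipped).
#' @param window posterior window on x/L used for the estimate.
#' @param background explicit background value overriding the estimate.
#' @return Records with `mean_gfp_corrected` background-subtracted; the
#'   estimate and clip count are attached as attributes `"background"` and
#'   `"n_clipped"`.
#' @export
subtract_background <- function(records, window = c(0.85, 0.95),
                                background = NULL) {
  if (is.null(records$mean_gfp_corrected))
    records$mean_gfp_corrected <- records$mean_gfp_raw
  if (is.null(background)) {
    post <- records$ap_fraction >= window[1] & records$ap_fraction <= window[2]
    if (!any(post, na.rm = TRUE))
      stop("no nuclei in the posterior window ", window[1], "-", window[2],
           " EL; supply an explicit background value", call. = FALSE)
    background <- mean(records$mean_gfp_corrected[which(post)])
  }
  shifted <- records$mean_gfp_corrected - background
  n_clip <- sum(shifted < 0)
  records$mean_gfp_corrected <- pmax(shifted, 0)
  attr(records, "background") <- background
  attr(records, "n_clipped") <- n_clip
  records
}

# Weighted log-linear exponential fit over an x/L window; shared by the
# nuclear profiles and the simulation snapshots. Returns amplitude (value
# extrapolated to x/L = 0), decay length in EL, and the number of bins used.
fit_exponential_profile <- function(x_l, value, weights = NULL,
                                    window = c(0.1, 0.7), min_bins = 5) {
  use <- x_l >= window[1] & x_l <= window[2] & is.finite(value) & value > 0
  if (sum(use) < min_bins)
    return(list(amplitude = NA_real_, decay_length_el = NA_real_,
                n_bins = sum(use), valid = FALSE))
  w <- if (is.null(weights)) rep(1, sum(use)) else weights[use]
  fit <- lm(log(value[use]) ~ x_l[use], weights = w)
  slope <- unname(coef(fit)[2])
  list(amplitude = exp(unname(coef(fit)[1])),
       decay_length_el = if (slope < 0) -1 / slope else NA_real_,
       n_bins = sum(use), valid = slope < 0)
}

#' Extract a binned AP gradient profile with an exponential fit
#'
#' Bins corrected nuclear GFP means into `n_bins` equal x/L intervals and
#' fits `log(intensity) ~ x/L` by weighted least squares (weights = bin
#' counts) over bins with positive means inside `fit_window`, avoiding
#' anterior saturation and the posterior background region. The amplitude is
#' the fitted value at x/L = 0 and the decay length the negative inverse
#' slope.
#'
#' @param records nucleus records with `ap_fraction` and
#'   `mean_gfp_corrected`.
#' @param n_bins number of equal x/L bins.
#' @param fit_window x/L window for the exponential fit.
#' @param cycle optional nuclear-cycle label stored with the profile.
#' @return An object of class `gradient_profile`: list with `cycle`, `bins`
#'   (data frame `x_l`, `mean`, `sd`, `n`), `amplitude`, `decay_length_el`,
#'   `fit_valid`.
#' @export
extract_profile <- function(records, n_bins = 50, fit_window = c(0.1, 0.7),
                            cycle = NA_integer_) {
  if (nrow(records) < 20)
    stop("need >= 20 nuclei to extract a profile", call. = FALSE)
  v <- records$mean_gfp_corrected %||% records$mean_gfp_raw
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(records$ap_fraction, edges,
                           rightmost.closed = TRUE), n_bins)
  bins <- data.frame(
    x_l = (edges[-1] + edges[-length(edges)]) / 2,
    mean = vapply(seq_len(n_bins), function(b)
      if (any(bin == b)) mean(v[bin == b]) else NA_real_, numeric(1)),
    sd = vapply(seq_len(n_bins), function(b)
      if (sum(bin == b) > 1) sd(v[bin == b]) else NA_real_, numeric(1)),
    n = tabulate(bin, n_bins))
  fit <- fit_exponential_profile(bins$x_l, bins$mean, weights = bins$n,
                                 window = fit_window)
  structure(list(cycle = cycle, bins = bins, amplitude = fit$amplitude,
                 decay_length_el = fit$decay_length_el,
                 fit_valid = fit$valid, fit_window = fit_window),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("<gradient_profile>%s amplitude %.4g, decay length %.4g EL (%s)\n",
              if (is.na(x$cycle)) "" else sprintf(" n.c. %d:", x$cycle),
              x$amplitude, x$decay_length_el,
              if (isTRUE(x$fit_valid)) "valid fit" else "fit flagged"))
  invisible(x)
}

#' @export
coef.gradient_profile <- function(object, ...) {
  c(amplitude = object$amplitude,
    decay_length_el = object$decay_length_el)
}

#' @export
predict.gradient_profile <- function(object, x_l = object$bins$x_l, ...) {
  object$amplitude * exp(-x_l / object$decay_length_el)
}

#' @export
plot.gradient_profile <- function(x, log = "", ...) {
  ok <- is.finite(x$bins$mean)
  plot(x$bins$x_l[ok], x$bins$mean[ok], xlab = "x/L",
       ylab = "mean nuclear intensity", log = log, ...)
  xs <- seq(0, 1, length.out = 200)
  lines(xs, predict(x, xs), col = 2)
  invisible(x)
}

#' Per-bin normalized amplitude trajectory across nuclear cycles
#'
#' Collects binned mean profiles for several cycles and normalizes each x/L
#' bin by the maximum it attains during development, exposing when each
#' position peaks and how far it declines afterwards.
#'
#' @param profiles list of `gradient_profile` objects (>= 2 cycles).
#' @return List with `cycles`, `x_l`, `normalized` (bins x cycles matrix of
#'   per-bin normalized means) and `amplitude` (fitted amplitude per cycle,
#'   normalized to its maximum).
#' @export
amplitude_timeseries <- function(profiles) {
  if (length(profiles) < 2)
    stop("need profiles from >= 2 cycles", call. = FALSE)
  cycles <- vapply(profiles, function(p) as.integer(p$cycle), integer(1))
  x_l <- profiles[[1]]$bins$x_l
  m <- vapply(profiles, function(p) p$bins$mean, numeric(length(x_l)))
  mx <- apply(m, 1, function(r) if (all(!is.finite(r))) NA else
    max(r, na.rm = TRUE))
  normalized <- sweep(m, 1, mx, "/")
  amp <- vapply(profiles, function(p) p$amplitude, numeric(1))
  list(cycles = cycles, x_l = x_l, normalized = normalized,
       amplitude = amp / max(amp, na.rm = TRUE))
}
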