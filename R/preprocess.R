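#' Realign z-slices by maximizing cross-correlation
#'
#' Corrects lateral stage drift: starting from the first slice (the
#' midsagittal reference, z = 0), each successive slice is shifted by the
#' integer offset that maximizes the pixel-wise correlation with its already
#' aligned predecessor, searching an exhaustive `(+/-max_shift)^2` window.
#' Cumulative shifts are applied outward from the reference; pixels exposed
#' at the borders are padded with the slice median.
#'
#' @param stack an [image_stack()] with at least 2 slices.
#' @param max_shift half-width of the integer search window in pixels.
#' @return The realigned `image_stack`, with the applied `(dy, dx)` shifts in
#'   `per_slice_offsets`. A warning is raised if any best shift lies on the
#'   search-window boundary (possible unbounded drift).
#' @export
realign_stack <- function(stack, max_shift = 5L) {
  v <- stack$voxels
  nz <- dim(v)[3]
  if (nz < 2) stop("need at least 2 slices to realign", call. = FALSE)
  offsets <- matrix(0L, nz, 2, dimnames = list(NULL, c("dy", "dx")))
  shifts <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  out <- v
  for (k in 2:nz) {
    # relative shift between consecutive raw slices, then cumulated
    best <- best_shift(v[, , k - 1], v[, , k], shifts)
    cum <- offsets[k - 1, ] + best
    if (any(abs(best) >= max_shift))
      warning(sprintf("slice %d: best shift on search boundary (%d, %d)",
                      k, best[1], best[2]), call. = FALSE)
    offsets[k, ] <- cum
    out[, , k] <- shift_slice(v[, , k], cum[1], cum[2])
  }
  stack$voxels <- out
  stack$per_slice_offsets <- offsets
  stack
}

# Correlation of ref with cur shifted by each candidate; returns the (dy,dx)
# maximizing it, ties broken toward the smallest |shift|.
best_shift <- function(ref, cur, shifts) {
  ny <- nrow(ref); nx <- ncol(ref)
  score <- vapply(seq_len(nrow(shifts)), function(i) {
    dy <- shifts$dy[i]; dx <- shifts$dx[i]
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    a <- ref[ys, xs]
    b <- cur[ys - dy, xs - dx]
    if (sd(a) == 0 || sd(b) == 0) return(-Inf)
    cor(as.vector(a), as.vector(b))
  }, numeric(1))
  ord <- order(-score, abs(shifts$dy) + abs(shifts$dx), shifts$dy, shifts$dx)
  c(shifts$dy[ord[1]], shifts$dx[ord[1]])
}

# Shift a slice by (dy, dx), padding exposed pixels with the slice median.
shift_slice <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(median(m), ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Estimate the raw-to-photon conversion factor of one slice
#'
#' Samples small image patches, computes the mean and variance of raw
#' intensity in each, and fits a straight line variance ~ mean. For
#' uncorrelated Poisson shot noise scaled by a gain g (raw = g x photons),
#' patch variance equals g x patch mean, so the slope is the conversion
#' factor between raw units and photon counts.
#'
#' @param slice numeric matrix (one z-slice) or an [image_stack()] (see
#'   [estimate_gains()] for the per-slice convenience wrapper).
#' @param n_patches maximum number of patches; if more than the number of
#'   available non-overlapping patches, all non-overlapping patches are used.
#' @param patch_size patch edge length in pixels (>= 3).
#' @param seed seed for patch sampling.
#' @param trim_iter robust refits dropping patches whose variance residual
#'   exceeds `trim_k` MADs -- patches containing particles have structured
#'   variance far above the shot-noise line and would otherwise bias the
#'   slope.
#' @param trim_k trimming threshold in MAD units.
#' @return An object of class `gain_fit` with `slope`, `intercept`,
#'   `n_patches` and `r_squared`.
#' @export
estimate_gain <- function(slice, n_patches = 1e5, patch_size = 5L,
                          seed = NULL, trim_iter = 3L, trim_k = 4) {
  if (inherits(slice, "image_stack")) slice <- slice$voxels[, , 1]
  if (patch_size < 3) stop("patch_size must be >= 3", call. = FALSE)
  ny <- nrow(slice); nx <- ncol(slice)
  py <- ny %/% patch_size; px <- nx %/% patch_size
  if (py < 1 || px < 1) stop("patch does not fit in slice", call. = FALSE)
  n_avail <- py * px
  idx <- if (n_avail <= n_patches) seq_len(n_avail) else
    with_seed(seed, sample.int(n_avail, n_patches))
  iy <- ((idx - 1) %% py) * patch_size
  ix <- ((idx - 1) %/% py) * patch_size
  mu <- numeric(length(idx)); v <- numeric(length(idx))
  for (i in seq_along(idx)) {
    p <- slice[(iy[i] + 1):(iy[i] + patch_size),
               (ix[i] + 1):(ix[i] + patch_size)]
    mu[i] <- mean(p); v[i] <- var(as.vector(p))
  }
  if (all(v == 0))
    stop("degenerate gain fit: image has zero variance everywhere",
         call. = FALSE)
  # particle-bearing patches sit far above the shot-noise line; drop the
  # extreme variance tail before the first fit, then trim by residual
  keep <- v <= quantile(v, 0.98)
  fit <- lm(v ~ mu, subset = keep)
  for (it in seq_len(trim_iter)) {
    res <- v - (coef(fit)[1] + coef(fit)[2] * mu)
    s <- stats::mad(res[keep])
    if (s == 0) break
    keep_new <- abs(res) <= trim_k * s
    if (sum(keep_new) < 10) break
    keep <- keep_new
    fit <- lm(v ~ mu, subset = keep)
  }
  r2 <- summary(fit)$r.squared
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_patches = sum(keep), r_squared = r2),
            class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("<gain_fit> slope = %.4g raw/photon (intercept %.4g, R2 %.3f, %d patches)\n",
              x$slope, x$intercept, x$r_squared, x$n_patches))
  invisible(x)
}

#' Estimate per-slice gains for a whole stack
#'
#' Applies [estimate_gain()] to every slice and optionally smooths the gain
#' profile with a running median, reflecting that the conversion factor
#' changes slowly and systematically with depth.
#'
#' @param stack an [image_stack()].
#' @param smooth logical; running-median smoothing (window 3) of the profile.
#' @param posterior_frac fraction of the x-extent, taken from the posterior
#'   end, used for the patches. Posterior regions are nearly particle-free,
#'   so their patch statistics reflect shot noise rather than mRNA signal;
#'   set to 1 to use whole slices.
#' @inheritParams estimate_gain
#' @return Numeric vector of per-slice gains.
#' @export
estimate_gains <- function(stack, n_patches = 1e5, patch_size = 5L,
                           seed = NULL, smooth = TRUE,
                           posterior_frac = 0.4) {
  nz <- dim(stack$voxels)[3]
  nx <- dim(stack$voxels)[2]
  x0 <- max(1L, floor(nx * (1 - posterior_frac)))
  g <- vapply(seq_len(nz), function(k)
    estimate_gain(stack$voxels[, x0:nx, k], n_patches, patch_size,
                  seed = if (is.null(seed)) NULL else seed + k)$slope,
    numeric(1))
  if (smooth && nz >= 3) {
    gs <- g
    for (k in 2:(nz - 1)) gs[k] <- median(g[(k - 1):(k + 1)])
    g <- gs
  }
  g
}

#' Normalize slices to photon-equivalent units
#'
#' Divides every z-slice by its gain so that intensities are expressed in
#' photon counts and a single detection threshold applies to all stacks
#' regardless of acquisition gain.
#'
#' @param stack an [image_stack()].
#' @param gains one positive gain per slice; defaults to the stack's
#'   recorded `per_slice_gain`.
#' @return The normalized `image_stack` (recorded gains reset to 1).
#' @export
normalize_slices <- function(stack, gains = NULL) {
  gains <- gains %||% stack$per_slice_gain
  nz <- dim(stack$voxels)[3]
  if (length(gains) == 1L) gains <- rep(gains, nz)
  if (length(gains) != nz) stop("need one gain per slice", call. = FALSE)
  if (any(!is.finite(gains)) || any(gains <= 0))
    stop("gains must be positive and finite", call. = FALSE)
  stack$voxels <- stack$voxels / rep(gains, each = prod(dim(stack$voxels)[1:2]))
  stack$per_slice_gain <- rep(1, nz)
  stack
}
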