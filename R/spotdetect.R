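#' Difference-of-Gaussians detection parameters
#'
#' The band-pass filter is the difference of two unit-sum circular Gaussian
#' kernels roughly matched to the particle size; being balanced it gives
#' exactly zero response to constant images. The detection threshold is
#' applied to the filtered image in photon-normalized units; 150 is the
#' value above which noise-only stacks produce essentially no candidates.
#'
#' @param center_radius_px sigma of the center Gaussian (default 1.5 px).
#' @param surround_radius_px sigma of the surround Gaussian (default 2.5 px).
#' @param threshold detection threshold on the filter value (default 150).
#' @return An object of class `dog_params`.
#' @export
dog_params <- function(center_radius_px = 1.5, surround_radius_px = 2.5,
                       threshold = 150) {
  if (!(center_radius_px > 0 && surround_radius_px > center_radius_px))
    stop("need 0 < center_radius_px < surround_radius_px", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  structure(list(center_radius_px = center_radius_px,
                 surround_radius_px = surround_radius_px,
                 threshold = threshold), class = "dog_params")
}

# Unit-sum 1D Gaussian kernel, radius 4 sigma.
gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# Separable 2D convolution with replicate border padding. Because the
# kernel has unit sum, constant images are mapped to themselves exactly.
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  ny <- nrow(m); nx <- ncol(m)
  # pad columns (x), convolve along x
  xp <- c(rep(1L, r), seq_len(nx), rep(nx, r))
  mp <- m[, xp, drop = FALSE]
  out <- matrix(0, ny, nx)
  for (j in seq_along(k))
    out <- out + k[j] * mp[, j:(j + nx - 1L), drop = FALSE]
  # pad rows (y), convolve along y
  yp <- c(rep(1L, r), seq_len(ny), rep(ny, r))
  mp <- out[yp, , drop = FALSE]
  out <- matrix(0, ny, nx)
  for (j in seq_along(k))
    out <- out + k[j] * mp[j:(j + ny - 1L), , drop = FALSE]
  out
}

#' Balanced difference-of-Gaussians filter
#'
#' @param slice 2D numeric matrix.
#' @param params a [dog_params()].
#' @return Filtered matrix of the same size.
#' @examples
#' f <- dog_filter(matrix(5, 32, 32), dog_params())
#' max(abs(f))  # balanced: zero response to a constant
#' @export
dog_filter <- function(slice, params = dog_params()) {
  if (!is.matrix(slice)) stop("slice must be a 2D matrix", call. = FALSE)
  conv_sep(slice, gauss_kernel1d(params$center_radius_px)) -
    conv_sep(slice, gauss_kernel1d(params$surround_radius_px))
}

# Local maxima of a matrix: strictly greater than lexicographically earlier
# 8-neighbours and >= later ones, so exactly one pixel survives per small
# plateau (the lexicographically smallest coordinate).
local_maxima <- function(m, threshold) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  nb <- function(dy, dx) pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
  ok <- m >= threshold &
    m > nb(-1, -1) & m > nb(-1, 0) & m > nb(-1, 1) & m > nb(0, -1) &
    m >= nb(0, 1) & m >= nb(1, -1) & m >= nb(1, 0) & m >= nb(1, 1)
  which(ok, arr.ind = TRUE)
}

#' Find candidate particles in a DoG-filtered stack
#'
#' Per-slice local maxima of the filtered image exceeding the detection
#' threshold, sorted by descending filter value.
#'
#' @param filtered 3D array of DoG-filtered slices, or an [image_stack()]
#'   already filtered.
#' @param params a [dog_params()] (supplies the threshold).
#' @return Data frame with `x_px`, `y_px`, `z_slice`, `dog_value`.
#' @export
find_candidates <- function(filtered, params = dog_params()) {
  if (inherits(filtered, "image_stack")) filtered <- filtered$voxels
  out <- vector("list", dim(filtered)[3])
  for (k in seq_len(dim(filtered)[3])) {
    ij <- local_maxima(filtered[, , k], params$threshold)
    out[[k]] <- data.frame(x_px = as.numeric(ij[, 2]),
                           y_px = as.numeric(ij[, 1]),
                           z_slice = rep(k, nrow(ij)),
                           dog_value = filtered[, , k][ij])
  }
  cand <- do.call(rbind, out)
  cand[order(-cand$dog_value, cand$z_slice, cand$y_px, cand$x_px), ,
       drop = FALSE]
}

#' Link axial shadows of candidate particles
#'
#' A sub-diffraction particle is detected on several consecutive z-slices
#' because of the axially extended PSF; the repeats ("shadows") must not be
#' counted as independent particles. Starting from the brightest unprocessed
#' candidate, candidates at the same x-y location (within `xy_radius_px`) on
#' other slices within `z_window` are marked as its shadows and removed from
#' further consideration.
#'
#' @param candidates data frame from [find_candidates()].
#' @param xy_radius_px lateral matching radius in pixels.
#' @param z_window maximum slice distance searched for shadows.
#' @return The surviving central candidates with an `n_shadows` column.
#' @export
link_shadows <- function(candidates, xy_radius_px = 2, z_window = 2) {
  n <- nrow(candidates)
  if (n == 0) return(cbind(candidates, n_shadows = integer(0)))
  ord <- order(-candidates$dog_value, candidates$z_slice,
               candidates$y_px, candidates$x_px)
  cand <- candidates[ord, ]
  state <- integer(n)            # 0 free, 1 center, -1 shadow
  n_shadows <- integer(n)
  r2 <- xy_radius_px^2
  for (i in seq_len(n)) {
    if (state[i] != 0L) next
    state[i] <- 1L
    free <- which(state == 0L)
    if (!length(free)) next
    dz <- abs(cand$z_slice[free] - cand$z_slice[i])
    d2 <- (cand$x_px[free] - cand$x_px[i])^2 +
      (cand$y_px[free] - cand$y_px[i])^2
    sh <- free[dz >= 1 & dz <= z_window & d2 <= r2]
    state[sh] <- -1L
    n_shadows[i] <- length(sh)
  }
  keep <- state == 1L
  out <- cand[keep, ]
  out$n_shadows <- n_shadows[keep]
  rownames(out) <- NULL
  out
}

# Clip a (2r+1)^2 patch centred on integer (yc, xc), reflecting at borders.
clip_patch <- function(slice, yc, xc, r = 4L) {
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 2L - i, i)
    ifelse(i > n, 2L * n - i, i)
  }
  ys <- refl((yc - r):(yc + r), nrow(slice))
  xs <- refl((xc - r):(xc + r), ncol(slice))
  slice[ys, xs, drop = FALSE]
}

# Elliptical Gaussian model on a coordinate grid. p = (xc, yc, rx, ry,
# theta, offset, A); radii are Gaussian sigmas.
egauss_model <- function(p, xg, yg) {
  ct <- cos(p[5]); st <- sin(p[5])
  u <- (xg - p[1]) * ct + (yg - p[2]) * st
  v <- -(xg - p[1]) * st + (yg - p[2]) * ct
  p[6] + p[7] * exp(-0.5 * (u^2 / p[3]^2 + v^2 / p[4]^2))
}

# Canonicalize fitted radii: r_x is the major axis; theta in (-pi/2, pi/2].
canon_axes <- function(p) {
  if (p[3] < p[4]) {
    p[c(3, 4)] <- p[c(4, 3)]
    p[5] <- p[5] + pi / 2
  }
  p[5] <- atan2(sin(p[5]), cos(p[5]))
  if (p[5] <= -pi / 2) p[5] <- p[5] + pi
  if (p[5] > pi / 2) p[5] <- p[5] - pi
  p
}

particle_row <- function(p, z_slice, n_shadows, dog_value, converged) {
  data.frame(x_c = p[1], y_c = p[2], z_slice = z_slice,
             r_x = p[3], r_y = p[4], theta = p[5],
             offset = p[6], amplitude = p[7], n_shadows = n_shadows,
             intensity = p[7] * p[3] * p[4],
             eccentricity = (p[3] - p[4]) / (p[3] + p[4]),
             diameter = 2 * sqrt(2 * log(2)) * (p[3] + p[4]) / 2,
             dog_value = dog_value, converged = converged)
}

#' Fit a single elliptical Gaussian to a candidate patch
#'
#' Least-squares fit of `I(x, y) = offset + amplitude * G(x - x_c, y - y_c;
#' r_x, r_y, theta)` to a 9x9 pixel patch centred on the candidate, by
#' Levenberg-Marquardt. Initialization: candidate position, radii 1.3 px,
#' offset = patch median, amplitude = centre minus median; radii bounded to
#' \[0.3, 5\] px. The fitted intensity is `amplitude * r_x * r_y`, the
#' eccentricity `(r_x - r_y)/(r_x + r_y)` with `r_x` the major axis, and the
#' reported diameter the mean FWHM of the two axes.
#'
#' @param slice 2D matrix (normalized units) containing the candidate.
#' @param candidate one-row data frame with `x_px`, `y_px`, `z_slice`,
#'   `dog_value` and optionally `n_shadows`.
#' @param patch_radius half-width of the square patch (default 4, a 9x9
#'   patch).
#' @return One-row data frame of fitted particle parameters (see
#'   [detect_particles()] for the full column list).
#' @export
fit_particle <- function(slice, candidate, patch_radius = 4L) {
  yc <- as.integer(round(candidate$y_px)); xc <- as.integer(round(candidate$x_px))
  patch <- clip_patch(slice, yc, xc, patch_radius)
  g <- expand.grid(y = (yc - patch_radius):(yc + patch_radius),
                   x = (xc - patch_radius):(xc + patch_radius))
  med <- median(patch)
  p0 <- c(xc, yc, 1.3, 1.3, 0, med,
          max(patch[patch_radius + 1, patch_radius + 1] - med, 1e-3))
  lower <- c(xc - 3, yc - 3, 0.3, 0.3, -pi, 0, 0)
  upper <- c(xc + 3, yc + 3, 5, 5, pi, Inf, Inf)
  fit <- try(minpack.lm::nls.lm(
    par = p0,
    fn = function(p) as.vector(patch) - egauss_model(p, g$x, g$y),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(particle_row(c(p0[1:5], med, 0), candidate$z_slice,
                        candidate$n_shadows %||% 0L, candidate$dog_value,
                        FALSE))
  p <- canon_axes(fit$par)
  particle_row(p, candidate$z_slice, candidate$n_shadows %||% 0L,
               candidate$dog_value, fit$info %in% 1:4)
}

#' Jointly fit overlapping candidates as a sum of Gaussians
#'
#' When several candidates fall within each other's 9x9 patches, their radii
#' and amplitudes are biased if fitted independently. A larger patch (the
#' candidates' bounding box plus a margin) is clipped and all components are
#' fitted simultaneously as a sum of elliptical Gaussians over one shared
#' offset. At most `max_components` candidates enter one joint fit; beyond
#' that the candidates farthest from the group centre fall back to single
#' fits. Components converging onto the same position (< 0.75 px apart) are
#' merged, keeping the brighter one.
#'
#' @param slice 2D matrix containing the candidates.
#' @param candidates data frame of candidates on this slice.
#' @param margin_px patch margin around the bounding box.
#' @param max_components cap on simultaneously fitted components.
#' @return Data frame with one row per fitted component.
#' @export
joint_fit <- function(slice, candidates, margin_px = 4L,
                      max_components = 6L) {
  # degenerate duplicates (same location) collapse before fitting
  if (nrow(candidates) > 1L) {
    ord <- order(-candidates$dog_value)
    keep <- rep(TRUE, nrow(candidates))
    for (a in seq_along(ord)) for (b in seq_along(ord)) {
      if (b <= a || !keep[ord[a]] || !keep[ord[b]]) next
      if ((candidates$x_px[ord[a]] - candidates$x_px[ord[b]])^2 +
          (candidates$y_px[ord[a]] - candidates$y_px[ord[b]])^2 < 1)
        keep[ord[b]] <- FALSE
    }
    candidates <- candidates[keep, , drop = FALSE]
  }
  if (nrow(candidates) == 1L) return(fit_particle(slice, candidates))
  if (nrow(candidates) > max_components) {
    cx <- mean(candidates$x_px); cy <- mean(candidates$y_px)
    d <- (candidates$x_px - cx)^2 + (candidates$y_px - cy)^2
    far <- order(d, decreasing = TRUE)[seq_len(nrow(candidates) - max_components)]
    singles <- do.call(rbind, lapply(far, function(i)
      fit_particle(slice, candidates[i, ])))
    rest <- joint_fit(slice, candidates[-far, ], margin_px, max_components)
    return(rbind(rest, singles))
  }
  y0 <- max(1L, min(round(candidates$y_px)) - margin_px)
  y1 <- min(nrow(slice), max(round(candidates$y_px)) + margin_px)
  x0 <- max(1L, min(round(candidates$x_px)) - margin_px)
  x1 <- min(ncol(slice), max(round(candidates$x_px)) + margin_px)
  patch <- slice[y0:y1, x0:x1, drop = FALSE]
  g <- expand.grid(y = y0:y1, x = x0:x1)
  med <- median(patch)
  nc <- nrow(candidates)
  # parameters: offset, then (xc, yc, rx, ry, theta, A) per component
  p0 <- c(med, unlist(lapply(seq_len(nc), function(i)
    c(candidates$x_px[i], candidates$y_px[i], 1.3, 1.3, 0,
      max(slice[round(candidates$y_px[i]), round(candidates$x_px[i])] - med,
          1e-3)))))
  lower <- c(0, rep(c(-Inf, -Inf, 0.3, 0.3, -pi, 0), nc))
  upper <- c(Inf, rep(c(Inf, Inf, 5, 5, pi, Inf), nc))
  model_sum <- function(p) {
    out <- rep(p[1], nrow(g))
    for (i in seq_len(nc)) {
      q <- p[2:7 + (i - 1) * 6]
      out <- out + egauss_model(c(q[1:5], 0, q[6]), g$x, g$y)
    }
    out
  }
  fit <- try(minpack.lm::nls.lm(
    par = p0, fn = function(p) as.vector(patch) - model_sum(p),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 150)), silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4)) {
    out <- do.call(rbind, lapply(seq_len(nc), function(i)
      fit_particle(slice, candidates[i, ])))
    out$converged <- FALSE
    return(out)
  }
  p <- fit$par
  rows <- do.call(rbind, lapply(seq_len(nc), function(i) {
    q <- canon_axes(c(p[2:7 + (i - 1) * 6][1:5], p[1],
                      p[2:7 + (i - 1) * 6][6]))
    particle_row(q, candidates$z_slice[i], candidates$n_shadows[i] %||% 0L,
                 candidates$dog_value[i], TRUE)
  }))
  # merge degenerate components that collapsed onto the same centre
  keep <- rep(TRUE, nrow(rows))
  for (i in seq_len(nrow(rows) - 1)) for (j in (i + 1):nrow(rows)) {
    if (keep[i] && keep[j] &&
        (rows$x_c[i] - rows$x_c[j])^2 + (rows$y_c[i] - rows$y_c[j])^2 < 0.75^2) {
      drop <- if (rows$amplitude[i] >= rows$amplitude[j]) j else i
      keep[drop] <- FALSE
    }
  }
  rows[keep, , drop = FALSE]
}

#' Acceptance criteria for fitted particles
#'
#' A fitted candidate is accepted as a true mRNA particle only if (i) both
#' Gaussian radii lie in (`r_min`, `r_max`), (ii) the amplitude exceeds the
#' background offset, and (iii) it has at least `min_shadows` shadows, i.e.
#' it was detected on at least `min_shadows + 1` z-slices.
#'
#' @param r_min,r_max radius bounds in pixels (defaults 0.7 and 2.5).
#' @param require_amplitude_gt_offset logical, criterion (ii).
#' @param min_shadows minimum number of shadows (default 1).
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(r_min = 0.7, r_max = 2.5,
                            require_amplitude_gt_offset = TRUE,
                            min_shadows = 1L) {
  if (!(r_min > 0 && r_max > r_min))
    stop("need 0 < r_min < r_max", call. = FALSE)
  structure(list(r_min = r_min, r_max = r_max,
                 require_amplitude_gt_offset = require_amplitude_gt_offset,
                 min_shadows = as.integer(min_shadows)),
            class = "filter_criteria")
}

#' Apply acceptance filters to fitted particles
#'
#' @param particles data frame of fitted particles.
#' @param criteria a [filter_criteria()].
#' @param keep_rejected if `TRUE`, return all rows with an `accepted` flag
#'   and `reject_reason`; otherwise only accepted rows.
#' @return Filtered data frame; per-criterion rejection counts are attached
#'   as attribute `"rejections"`.
#' @export
apply_filters <- function(particles, criteria = filter_criteria(),
                          keep_rejected = FALSE) {
  if (nrow(particles) == 0) {
    attr(particles, "rejections") <- c(radius = 0L, amplitude = 0L,
                                       shadows = 0L, fit = 0L)
    return(particles)
  }
  bad_fit <- !particles$converged
  bad_r <- particles$r_x <= criteria$r_min | particles$r_x >= criteria$r_max |
    particles$r_y <= criteria$r_min | particles$r_y >= criteria$r_max
  bad_a <- criteria$require_amplitude_gt_offset &
    particles$amplitude <= particles$offset
  bad_s <- particles$n_shadows < criteria$min_shadows
  reason <- rep(NA_character_, nrow(particles))
  reason[bad_s] <- "shadows"
  reason[bad_a] <- "amplitude"
  reason[bad_r] <- "radius"
  reason[bad_fit] <- "fit"
  accepted <- !(bad_fit | bad_r | bad_a | bad_s)
  rej <- c(radius = sum(bad_r), amplitude = sum(bad_a),
           shadows = sum(bad_s), fit = sum(bad_fit))
  particles$accepted <- accepted
  particles$reject_reason <- reason
  out <- if (keep_rejected) particles else particles[accepted, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rej
  out
}

# Union-find grouping of candidates whose 9x9 patches overlap each other's
# centres (Chebyshev distance <= patch width - 1 on the same slice).
group_candidates <- function(cand, reach = 8L) {
  n <- nrow(cand)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    if (i == n) break
    j <- (i + 1):n
    same <- cand$z_slice[j] == cand$z_slice[i] &
      abs(cand$x_px[j] - cand$x_px[i]) <= reach &
      abs(cand$y_px[j] - cand$y_px[i]) <= reach
    for (jj in j[same]) {
      ri <- find(i); rj <- find(jj)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Detect mRNA particles in a normalized image stack
#'
#' The full particle-calling chain: per-slice balanced DoG filtering,
#' thresholded local maxima (candidates), shadow linking across z, single or
#' joint elliptical Gaussian fitting, and acceptance filtering. The input is
#' expected in photon-normalized units (see [normalize_slices()]) so that
#' the default threshold applies.
#'
#' @param stack an [image_stack()] (realigned, normalized).
#' @param params a [dog_params()].
#' @param criteria a [filter_criteria()].
#' @param xy_radius_px,z_window shadow-linking parameters.
#' @param keep_rejected include rejected candidates with reasons.
#' @return Data frame of particles with columns `x_c`, `y_c`, `z_slice`,
#'   `r_x`, `r_y`, `theta`, `offset`, `amplitude`, `n_shadows`, `intensity`,
#'   `eccentricity`, `diameter`, `dog_value`, `converged` (and `accepted`,
#'   `reject_reason` if requested). Attribute `"counts"` logs per-stage
#'   tallies.
#' @export
detect_particles <- function(stack, params = dog_params(),
                             criteria = filter_criteria(),
                             xy_radius_px = 2, z_window = 2,
                             keep_rejected = FALSE) {
  v <- stack$voxels
  nz <- dim(v)[3]
  filtered <- array(0, dim(v))
  for (k in seq_len(nz)) filtered[, , k] <- dog_filter(v[, , k], params)
  cand <- find_candidates(filtered, params)
  centers <- link_shadows(cand, xy_radius_px, z_window)
  if (nrow(centers) == 0) {
    out <- particle_row(c(0, 0, 1, 1, 0, 0, 0), 1L, 0L, 0, TRUE)[0, ]
    out <- apply_filters(out, criteria, keep_rejected)
    attr(out, "counts") <- c(candidates = nrow(cand), centers = 0L,
                             fitted = 0L, accepted = 0L)
    return(out)
  }
  grp <- group_candidates(centers)
  fitted <- do.call(rbind, lapply(split(seq_len(nrow(centers)), grp),
                                  function(idx) {
    z <- centers$z_slice[idx[1]]
    joint_fit(v[, , z], centers[idx, , drop = FALSE])
  }))
  out <- apply_filters(fitted, criteria, keep_rejected)
  attr(out, "counts") <- c(candidates = nrow(cand), centers = nrow(centers),
                           fitted = nrow(fitted),
                           accepted = sum(out$accepted %||% rep(TRUE, nrow(out))))
  attr(out, "rejections") <- attr(out, "rejections", exact = TRUE)
  out
}
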