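# Lazily computed, memoised fixtures shared across test files. Everything
# is generated in code at test time; no stored data.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A compact embryo model whose full AP axis fits a small test stack
# (1 px = 1 um as in reduced_embryo_model, but a 300 um egg).
test_embryo <- function(stage = 12, geometry_mode = NULL) {
  if (is.null(geometry_mode))
    geometry_mode <- if (stage < 7) "wedge" else "cup"
  embryo_model(length_um = 300, width_um = 120, pixel_size_nm = 1000,
               z_step_nm = 1000, stage = stage, geometry_mode = geometry_mode)
}

test_dims <- c(140, 320, 12)

# Rendered cup-stage stack + detection, used by several files.
fixture_cup_run <- function() fixture("cup_run", function() {
  model <- test_embryo(12)
  particles <- sample_particles(model, 800, seed = 11)
  rendered <- render_stack(particles, model,
                           render_spec(gain = seq(2.2, 2.8,
                                                  length.out = test_dims[3]),
                                       read_noise_sd = 3, seed = 12),
                           dims = test_dims)
  stack <- normalize_slices(rendered$stack,
                            estimate_gains(rendered$stack, n_patches = 2000,
                                           seed = 13))
  detected <- detect_particles(stack)
  reg <- known_registration(model, test_dims)
  projected <- project_particles(detected, reg)
  list(model = model, truth = rendered$truth, raw = rendered$stack,
       stack = stack, detected = detected, registration = reg,
       projected = projected)
})

# Well-separated bright spots on a jittered grid: the high-SNR regime for
# precision/recall and calibration checks (minimum separation 8 px).
fixture_sparse_run <- function() fixture("sparse_run", function() {
  set.seed(21)
  gx <- seq(12, 116, by = 8); gy <- seq(12, 116, by = 8)
  centers <- expand.grid(x = gx, y = gy)
  keep <- sample.int(nrow(centers), 120)
  truth <- data.frame(
    x_px = centers$x[keep] + runif(120, -1, 1),
    y_px = centers$y[keep] + runif(120, -1, 1),
    z_slice = runif(120, 3.5, 8.5),
    photon_amplitude = exp(runif(120, log(2000), log(15000))))
  model <- embryo_model(length_um = 500, width_um = 180, stage = 12,
                        geometry_mode = "cup")
  rendered <- render_stack(truth, model,
                           render_spec(background_gradient = 0, gain = 2.5,
                                       read_noise_sd = 3, seed = 22),
                           dims = c(128, 128, 11))
  stack <- normalize_slices(rendered$stack, rep(2.5, 11))
  detected <- detect_particles(stack)
  list(truth = truth, raw = rendered$stack, stack = stack,
       detected = detected)
})

# Greedy matching of detections to ground truth within a radius.
match_particles <- function(detected, truth, radius_px = 2) {
  if (!nrow(detected) || !nrow(truth))
    return(list(recall = 0, precision = 0, matched = integer()))
  d2 <- outer(detected$x_c, truth$x_px, "-")^2 +
    outer(detected$y_c, truth$y_px, "-")^2
  used_t <- logical(nrow(truth)); used_d <- logical(nrow(detected))
  pairs <- 0L
  ord <- order(d2)
  for (k in ord) {
    if (d2[k] > radius_px^2) break
    i <- (k - 1) %% nrow(detected) + 1
    j <- (k - 1) %/% nrow(detected) + 1
    if (used_d[i] || used_t[j]) next
    used_d[i] <- used_t[j] <- TRUE
    pairs <- pairs + 1L
  }
  list(recall = pairs / nrow(truth), precision = pairs / nrow(detected),
       matched = which(used_t))
}

# Minimal hand-built 1D geometry (a single row of voxels) for closed-form
# solver checks.
line_geometry <- function(n = 60, spacing_um = 10) {
  nbr <- matrix(seq_len(n), n, 6)
  nbr[2:n, 1] <- 1:(n - 1)
  nbr[1:(n - 1), 2] <- 2:n
  structure(list(length_um = n * spacing_um, width_um = spacing_um,
                 spacing_um = spacing_um, dims = c(n, 1, 1),
                 vox = data.frame(ix = seq_len(n), iy = 1, iz = 1),
                 n = n, nbr = nbr, ap_index = seq_len(n),
                 x_l = (seq_len(n) - 0.5) / n),
            class = "sdd_geometry")
}
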