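render_spot <- function(ny, nx, xc, yc, sx, sy, A, offset = 0, theta = 0) {
  g <- expand.grid(y = 1:ny, x = 1:nx)
  u <- (g$x - xc) * cos(theta) + (g$y - yc) * sin(theta)
  v <- -(g$x - xc) * sin(theta) + (g$y - yc) * cos(theta)
  matrix(offset + A * exp(-0.5 * (u^2 / sx^2 + v^2 / sy^2)), ny, nx)
}

test_that("balanced DoG filter: zero on constants, closed-form impulse peak", {
  p <- dog_params()
  expect_lt(max(abs(dog_filter(matrix(37.5, 40, 40), p))), 1e-9)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  f <- dog_filter(imp, p)
  k_c <- dnorm(-6:6, sd = 1.5); k_c <- k_c / sum(k_c)
  k_s <- dnorm(-10:10, sd = 2.5); k_s <- k_s / sum(k_s)
  expect_equal(f[21, 21], max(k_c)^2 - max(k_s)^2, tolerance = 1e-12)
  # response linear in amplitude, peak ratio matches brute-force convolution
  s1 <- render_spot(41, 41, 21, 21, 1.1, 1.1, 100)
  s2 <- render_spot(41, 41, 21, 21, 1.1, 1.1, 700)
  expect_equal(max(dog_filter(s2, p)) / max(dog_filter(s1, p)), 7,
               tolerance = 1e-9)
  # brute-force check of the peak value via direct kernel sums
  kc2 <- outer(k_c, k_c); ks2 <- outer(k_s, k_s)
  resp_c <- sum(kc2 * s1[21 + (-6:6), 21 + (-6:6)])
  resp_s <- sum(ks2 * s1[21 + (-10:10), 21 + (-10:10)])
  expect_equal(dog_filter(s1, p)[21, 21], resp_c - resp_s, tolerance = 1e-9)
})

test_that("candidate finding: empty stacks, axial repeats, threshold knee", {
  p <- dog_params()
  expect_equal(nrow(find_candidates(array(0, c(30, 30, 3)), p)), 0L)
  # a bright particle is seen on several consecutive slices at the same x-y
  model <- test_embryo(12)
  r <- render_stack(data.frame(x_px = 30, y_px = 25, z_slice = 5,
                               photon_amplitude = 12000),
                    model, render_spec(background_photons = 0,
                                       background_gradient = 0, gain = 1,
                                       poisson = FALSE),
                    dims = c(50, 60, 9))
  filt <- r$stack$voxels
  for (k in 1:9) filt[, , k] <- dog_filter(r$stack$voxels[, , k], p)
  cand <- find_candidates(filt, p)
  expect_gte(nrow(cand), 3L)
  expect_true(all(abs(cand$x_px - 30) <= 1 & abs(cand$y_px - 25) <= 1))
  # noise-only stack: counts explode below the knee, none at threshold 150
  set.seed(41)
  noise <- array(rpois(60 * 60 * 3, 100), c(60, 60, 3))
  nf <- noise
  for (k in 1:3) nf[, , k] <- dog_filter(noise[, , k], p)
  n_low <- nrow(find_candidates(nf, dog_params(threshold = 1)))
  n_high <- nrow(find_candidates(nf, dog_params(threshold = 150)))
  expect_equal(n_high, 0L)
  expect_gt(n_low, 100)
})

test_that("shadow linking groups axial repeats, keeps distinct particles", {
  cand <- data.frame(x_px = c(10, 10, 10), y_px = c(20, 20, 20),
                     z_slice = c(4, 5, 6), dog_value = c(200, 400, 250))
  out <- link_shadows(cand)
  expect_equal(nrow(out), 1L)
  expect_equal(out$z_slice, 5)
  expect_equal(out$n_shadows, 2L)
  # two particles 10 px apart are not cross-linked
  cand2 <- rbind(cand, data.frame(x_px = 20, y_px = 20,
                                  z_slice = c(4, 5), dog_value = c(180, 300)))
  out2 <- link_shadows(cand2)
  expect_equal(nrow(out2), 2L)
  expect_equal(sort(out2$x_px), c(10, 20))
  # a single-slice candidate keeps zero shadows and is later rejected
  solo <- link_shadows(data.frame(x_px = 5, y_px = 5, z_slice = 2,
                                  dog_value = 200))
  expect_equal(solo$n_shadows, 0L)
  fitted <- particle <- data.frame(x_c = 5, y_c = 5, z_slice = 2, r_x = 1.2,
                                   r_y = 1.1, theta = 0, offset = 5,
                                   amplitude = 50, n_shadows = 0L,
                                   intensity = 66, eccentricity = 0.04,
                                   diameter = 2.7, dog_value = 200,
                                   converged = TRUE)
  expect_equal(nrow(apply_filters(fitted)), 0L)
})

test_that("elliptical Gaussian fit round-trips noise-free spots to 1e-3", {
  sl <- render_spot(15, 15, 8.3, 7.6, 1.2, 1.0, 100, offset = 10)
  cand <- data.frame(x_px = 8, y_px = 8, z_slice = 1, dog_value = 50,
                     n_shadows = 1L)
  fit <- fit_particle(sl, cand)
  expect_equal(fit$x_c, 8.3, tolerance = 1e-3)
  expect_equal(fit$y_c, 7.6, tolerance = 1e-3)
  expect_equal(fit$r_x, 1.2, tolerance = 1e-3)
  expect_equal(fit$r_y, 1.0, tolerance = 1e-3)
  expect_equal(fit$amplitude, 100, tolerance = 1e-3)
  expect_equal(fit$offset, 10, tolerance = 1e-3)
  expect_equal(fit$intensity, fit$amplitude * fit$r_x * fit$r_y)
  # circular spot: eccentricity ~ 0
  slc <- render_spot(15, 15, 8, 8, 1.1, 1.1, 80, offset = 5)
  fitc <- fit_particle(slc, cand)
  expect_lt(fitc$eccentricity, 1e-6)
  # flat patch: amplitude ~ 0, rejected by the amplitude criterion
  flat <- fit_particle(matrix(10, 15, 15), cand)
  expect_lt(flat$amplitude, 1e-6)
  expect_equal(nrow(apply_filters(flat)), 0L)
})

test_that("joint fitting resolves overlapping spots that bias single fits", {
  sl <- render_spot(21, 25, 10, 11, 1.1, 1.1, 100) +
    render_spot(21, 25, 13, 11, 1.1, 1.1, 60) + 8
  cand <- data.frame(x_px = c(10, 13), y_px = c(11, 11), z_slice = 1,
                     dog_value = c(30, 20), n_shadows = 1L)
  joint <- joint_fit(sl, cand)
  joint <- joint[order(joint$x_c), ]
  expect_equal(nrow(joint), 2L)
  expect_equal(joint$amplitude, c(100, 60), tolerance = 0.10)
  single <- rbind(fit_particle(sl, cand[1, ]), fit_particle(sl, cand[2, ]))
  err_joint <- abs(joint$amplitude - c(100, 60)) / c(100, 60)
  err_single <- abs(single$amplitude - c(100, 60)) / c(100, 60)
  expect_gt(max(err_single), max(err_joint))
  # far-apart spots: joint fit agrees with single fits
  sl2 <- render_spot(21, 41, 8, 11, 1.2, 1.0, 90) +
    render_spot(21, 41, 32, 11, 1.0, 1.2, 50) + 5
  cand2 <- data.frame(x_px = c(8, 32), y_px = c(11, 11), z_slice = 1,
                      dog_value = c(30, 20), n_shadows = 1L)
  j2 <- joint_fit(sl2, cand2)
  s2 <- rbind(fit_particle(sl2, cand2[1, ]), fit_particle(sl2, cand2[2, ]))
  expect_equal(sort(j2$amplitude), sort(s2$amplitude), tolerance = 1e-2)
  # duplicated candidates collapse to one merged component
  cand3 <- data.frame(x_px = c(10, 10), y_px = c(11, 11), z_slice = 1,
                      dog_value = c(30, 29), n_shadows = 1L)
  sl3 <- render_spot(21, 25, 10, 11, 1.1, 1.1, 100) + 8
  j3 <- joint_fit(sl3, cand3)
  expect_equal(nrow(j3), 1L)
})

test_that("acceptance filters enforce the published criteria", {
  base <- data.frame(x_c = 5, y_c = 5, z_slice = 2, r_x = 1.4, r_y = 1.2,
                     theta = 0, offset = 10, amplitude = 50, n_shadows = 1L,
                     intensity = 84, eccentricity = 0.08, diameter = 3.1,
                     dog_value = 200, converged = TRUE)
  ok <- apply_filters(base)
  expect_equal(nrow(ok), 1L)
  narrow <- base; narrow$r_y <- 0.5
  expect_equal(nrow(apply_filters(narrow)), 0L)
  dim_p <- base; dim_p$amplitude <- 5
  expect_equal(nrow(apply_filters(dim_p)), 0L)
  wide <- base; wide$r_x <- 3.0
  expect_equal(nrow(apply_filters(wide)), 0L)
  all4 <- apply_filters(rbind(base, narrow, dim_p, wide),
                        keep_rejected = TRUE)
  expect_equal(sum(all4$accepted), 1L)
  expect_setequal(all4$reject_reason[!all4$accepted],
                  c("radius", "amplitude", "radius"))
})

test_that("end-to-end detection is precise and gain-invariant", {
  run <- fixture_sparse_run()
  expect_gt(nrow(run$detected), 0)
  m <- match_particles(run$detected, run$truth)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  # global rescale of the raw stack changes nothing after normalization
  scaled <- run$raw
  scaled$voxels <- scaled$voxels * 2
  redet <- detect_particles(normalize_slices(scaled, rep(5, 11)))
  expect_equal(nrow(redet), nrow(run$detected))
  # noise-only stack yields no particles at the standard threshold
  set.seed(43)
  noise <- image_stack(array(rpois(80 * 80 * 6, 120), c(80, 80, 6)))
  expect_equal(nrow(detect_particles(noise)), 0L)
})

test_that("detected intensities are consistent and track the DoG value", {
  run <- fixture_sparse_run()
  det <- run$detected
  m <- match_particles(det, run$truth)
  # intensity strictly equals amplitude * r_x * r_y
  expect_equal(det$intensity, det$amplitude * det$r_x * det$r_y)
  # linear correspondence between intensity and DoG filter value
  expect_gt(cor(det$intensity, det$dog_value), 0.95)
  # summed detected intensity ~ summed truth amplitude x sigma^2 product
  expect_equal(sum(det$intensity),
               sum(run$truth$photon_amplitude) * 1.1 * 1.1,
               tolerance = 0.15)
  # circular PSF: eccentricity concentrates near zero
  expect_lt(median(det$eccentricity), 0.15)
  # bright particles carry more shadows than dim ones
  top <- det$amplitude >= quantile(det$amplitude, 0.9)
  expect_gte(min(det$n_shadows[top]), 2)
  expect_gte(mean(det$n_shadows >= 1), 1)  # all accepted have >= 1
})
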