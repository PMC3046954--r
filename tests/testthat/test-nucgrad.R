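# Analytic nucleus records: exponential gradient with known attenuation.
make_records <- function(n = 60, amplitude = 1000, decay = 0.15,
                         background = 0, att_um = Inf, rfp = 500,
                         seed = 71) {
  set.seed(seed)
  ap <- runif(n)
  depth <- runif(n, 0, 30)
  att <- exp(-depth / att_um)
  data.frame(label = seq_len(n), x_px = ap * 300, y_px = 50,
             z_slice = depth / 3.5 + 1, ap_fraction = ap,
             depth_um = depth,
             mean_gfp_raw = (amplitude * exp(-ap / decay) + background) * att,
             mean_rfp_raw = rfp * att, volume_vox = 60L)
}

test_that("segmentation labels isolated and touching nuclei correctly", {
  v <- array(10, c(40, 60, 8))
  sphere <- function(v, cx, cy, cz, r, val) {
    for (z in 1:8) for (y in 1:40) for (x in 1:60)
      if ((x - cx)^2 + (y - cy)^2 + ((z - cz) * 2)^2 <= r^2)
        v[y, x, z] <- val
    v
  }
  v <- sphere(v, 15, 12, 4, 4, 500)
  v <- sphere(v, 45, 28, 5, 4, 480)
  lab <- segment_nuclei(image_stack(v), stage = 6)
  expect_equal(attr(lab, "n_nuclei"), 2L)
  ids <- sort(unique(lab[lab > 0]))
  cents <- t(vapply(ids, function(i) {
    w <- which(lab == i, arr.ind = FALSE)
    d <- dim(lab)
    c(mean(((w - 1) %/% d[1]) %% d[2] + 1), mean((w - 1) %% d[1] + 1))
  }, numeric(2)))
  cents <- cents[order(cents[, 1]), ]
  expect_equal(cents[, 1], c(15, 45), tolerance = 0.08)
  expect_equal(cents[, 2], c(12, 28), tolerance = 0.08)
  # touching pair at blastoderm spacing: watershed separates them
  v2 <- array(10, c(40, 60, 8))
  v2 <- sphere(v2, 28, 20, 4, 4, 500)
  v2 <- sphere(v2, 36, 20, 4, 4, 500)
  lab2 <- segment_nuclei(image_stack(v2), stage = 12)
  expect_equal(attr(lab2, "n_nuclei"), 2L)
  # empty stack
  lab0 <- segment_nuclei(image_stack(array(10, c(20, 20, 4))), stage = 6)
  expect_equal(attr(lab0, "n_nuclei"), 0L)
})

test_that("nucleus measurement recovers exact channel means", {
  lab <- array(0L, c(20, 20, 4))
  lab[5:8, 5:8, 2] <- 1L
  lab[12:15, 12:15, 3] <- 2L
  gfp <- array(1, dim(lab)); gfp[lab == 1] <- 42; gfp[lab == 2] <- 17
  rfp <- array(1, dim(lab)); rfp[lab > 0] <- 300
  rec <- measure_nuclei(lab, image_stack(gfp, z_step_nm = 3500),
                        image_stack(rfp, z_step_nm = 3500))
  expect_equal(sort(rec$mean_gfp_raw), c(17, 42))
  expect_equal(rec$mean_rfp_raw, c(300, 300))
  expect_equal(sort(rec$depth_um), c(1, 2) * 3.5)
  expect_error(measure_nuclei(lab, image_stack(gfp[, , 1:3, drop = FALSE]),
                              image_stack(rfp)), "dimensions")
})

test_that("attenuation correction undoes depth-dependent signal loss", {
  flat <- attenuation_correct(make_records(att_um = Inf))
  expect_equal(flat$attenuation_factor, rep(1, nrow(flat)), tolerance = 0.02)
  rec <- make_records(att_um = 50)
  out <- attenuation_correct(rec)
  truth <- 1000 * exp(-out$ap_fraction / 0.15)
  # corrected GFP matches the unattenuated truth within 5% at all depths
  expect_lt(max(abs(out$mean_gfp_corrected - truth) / truth), 0.05)
  # two nuclei with equal true GFP at depths 0 and 30 um end up equal
  pair <- which.min(abs(out$depth_um - 0))
  deep <- which.max(out$depth_um)
  ratio <- (out$mean_gfp_corrected[pair] / truth[pair]) /
    (out$mean_gfp_corrected[deep] / truth[deep])
  expect_equal(ratio, 1, tolerance = 0.03)
  expect_error(attenuation_correct(rec[1:5, ]), ">= 10")
})

test_that("posterior nuclei estimate and remove the background", {
  rec <- make_records(n = 200, background = 80, seed = 72)
  rec$mean_gfp_corrected <- rec$mean_gfp_raw
  out <- subtract_background(rec)
  expect_equal(attr(out, "background"), 80, tolerance = 0.05)
  anterior <- out$ap_fraction < 0.3
  expect_equal(out$mean_gfp_corrected[anterior],
               1000 * exp(-out$ap_fraction[anterior] / 0.15),
               tolerance = 0.01)
  # zero-background generator: subtraction changes almost nothing
  rec0 <- make_records(n = 200, background = 0, seed = 73)
  rec0$mean_gfp_corrected <- rec0$mean_gfp_raw
  out0 <- subtract_background(rec0)
  expect_lt(attr(out0, "background") / 1000, 0.01)
  # no posterior nuclei: instructive error
  expect_error(subtract_background(rec[rec$ap_fraction < 0.5, ]),
               "background")
})

test_that("profile extraction is exact on noiseless exponentials and scale-equivariant", {
  rec <- make_records(n = 500, amplitude = 100, decay = 0.15, seed = 74)
  rec$mean_gfp_corrected <- 100 * exp(-rec$ap_fraction / 0.15)
  prof <- extract_profile(rec, n_bins = 200)
  expect_equal(unname(coef(prof)["decay_length_el"]), 0.15, tolerance = 1e-3)
  expect_equal(unname(coef(prof)["amplitude"]), 100, tolerance = 1e-2)
  # exact identity when bin means are exactly exponential (one nucleus/bin)
  rec2 <- rec[1:60, ]
  rec2$ap_fraction <- (seq(105, 695, by = 10) - 0.5) / 1000
  rec2$mean_gfp_corrected <- 100 * exp(-rec2$ap_fraction / 0.15)
  prof2 <- extract_profile(rec2, n_bins = 1000)
  expect_equal(unname(coef(prof2)), c(100, 0.15), tolerance = 1e-6)
  # scale equivariance
  rec3 <- rec2
  rec3$mean_gfp_corrected <- rec3$mean_gfp_corrected * 7
  prof3 <- extract_profile(rec3, n_bins = 1000)
  expect_equal(unname(coef(prof3)["amplitude"]), 700, tolerance = 1e-6)
  expect_equal(unname(coef(prof3)["decay_length_el"]), 0.15,
               tolerance = 1e-9)
  expect_error(extract_profile(rec[1:10, ]), ">= 20")
})

test_that("imaging pipeline recovers generator gradients end to end", {
  model <- test_embryo(12)
  est <- c()
  for (decay in c(0.15, 0.20)) {
    nuc <- render_nuclear_stack(model, gradient_amplitude = 1000,
                                decay_length_el = decay,
                                attenuation_length_um = 50,
                                background = 50, n_nuclei = 240,
                                noise_fraction = 0.05,
                                dims = c(130, 310, 10), seed = 81)
    lab <- segment_nuclei(nuc$rfp, stage = 12)
    expect_gt(attr(lab, "n_nuclei"), 150)
    reg <- known_registration(model, c(130, 310))
    rec <- measure_nuclei(lab, nuc$gfp, nuc$rfp, registration = reg,
                          z_step_um = 3.5)
    rec <- attenuation_correct(rec)
    rec <- subtract_background(rec)
    prof <- extract_profile(rec, n_bins = 50)
    expect_true(prof$fit_valid)
    est <- c(est, unname(coef(prof)["decay_length_el"]))
  }
  # fixed-tissue emulation: 0.15 EL recovered within 0.02
  expect_lt(abs(est[1] - 0.15), 0.02)
  # live-embryo emulation (0.20 EL) recovered and clearly distinguishable
  # (posterior-window background subtraction removes a little true signal,
  # biasing both estimates slightly low)
  expect_lt(abs(est[2] - 0.20), 0.03)
  expect_gt(est[2] - est[1], 0.02)
})

test_that("per-bin normalization exposes the amplitude trajectory", {
  mk <- function(cycle, scale) {
    rec <- make_records(n = 300, seed = 90 + cycle)
    rec$mean_gfp_corrected <- scale * exp(-rec$ap_fraction / 0.15)
    extract_profile(rec, n_bins = 20, cycle = cycle)
  }
  # constant profiles: every normalized value is 1
  const <- amplitude_timeseries(list(mk(7, 100), mk(8, 100)))
  ok <- is.finite(const$normalized)
  expect_equal(unname(const$normalized[ok]), rep(1, sum(ok)),
               tolerance = 0.05)
  # monotone rising series: the final cycle attains every bin maximum
  rising <- amplitude_timeseries(list(mk(7, 50), mk(8, 80), mk(9, 120)))
  last <- rising$normalized[, 3]
  expect_equal(unname(last[is.finite(last)]),
               rep(1, sum(is.finite(last))), tolerance = 1e-9)
  expect_equal(rising$amplitude[3], 1, tolerance = 1e-9)
})

test_that("model-driven nuclear series peaks late and declines modestly", {
  geo <- sdd_geometry(300, 120, 20)
  series <- simulate_gradient_series(noise_fraction = 0, geometry = geo,
                                     sources = default_sources(geo, seed = 1,
                                                               n_particles = 5000))
  anterior <- vapply(7:14, function(cc) {
    s <- series[series$cycle == cc, ]
    s$value[which.min(abs(s$x_l - 0.1))]
  }, numeric(1))
  peak <- (7:14)[which.max(anterior)]
  expect_true(peak %in% 11:13)
  expect_gt(anterior[8], 0.55 * max(anterior))  # late values 70-85% of peak
  expect_lt(anterior[8], max(anterior))
})
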