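test_that("ellipsoid geometry has the right extent and volume", {
  geo <- sdd_geometry(500, 180, 10)
  expect_equal(geo$dims[1], 50)
  analytic <- 4 / 3 * pi * 250 * 90 * 90 / 10^3
  expect_equal(geo$n, analytic, tolerance = 0.05)
  expect_error(sdd_geometry(500, 180, 200), "spacing|coarse|>")
  expect_error(sdd_geometry(40, 180, 10), "length_um")
})

test_that("source discretization conserves strength and geometry", {
  geo <- sdd_geometry(300, 120, 20)
  pt <- build_source(NULL, geo, "point", S_tot = 5)
  expect_equal(sum(pt > 0), 1L)
  expect_equal(sum(pt), 5)
  expect_equal(geo$vox$ix[which(pt > 0)], min(geo$vox$ix))
  wedge <- sample_particles(embryo_model(stage = 4), 20000, seed = 101)
  cup <- sample_particles(embryo_model(stage = 12, geometry_mode = "cup"),
                          20000, seed = 102)
  s1 <- build_source(wedge, geo, "realistic", S_tot = 3)
  s2 <- build_source(cup, geo, "realistic", S_tot = 3)
  expect_equal(sum(s1), 3, tolerance = 1e-9)
  expect_equal(sum(s2), 3, tolerance = 1e-9)
  # >90% of synthesis anterior of 20% EL
  xl <- geo$x_l[geo$ap_index]
  expect_gt(sum(s1[xl <= 0.2]) / sum(s1), 0.9)
  expect_gt(sum(s2[xl <= 0.2]) / sum(s2), 0.9)
})

test_that("solver conserves mass exactly under no-flux boundaries", {
  geo <- sdd_geometry(300, 120, 20)
  src <- build_source(NULL, geo, "point", S_tot = 2)
  # zero source, zero initial condition: identically zero
  sol0 <- sdd_solve(geo, src,
                    sdd_params(T_src_on = 15, T_src_off = 15))
  expect_true(all(sol0$snapshots$value == 0))
  # no degradation: total mass = S_tot x active time, to rounding
  sol <- sdd_solve(geo, src, sdd_params(D = 3.1, tau = 1e12, T_src_on = 1,
                                        T_src_off = 14, T_diff_off = Inf))
  sched <- cycle_schedule()
  expect_equal(sol$totals$total, 2 * sched$t_end_min, tolerance = 1e-9)
  # linearity: doubling the source doubles every concentration exactly
  sol2 <- sdd_solve(geo, src * 2, sdd_params(D = 3.1, tau = 1e12,
                                             T_src_on = 1, T_src_off = 14,
                                             T_diff_off = Inf))
  expect_equal(sol2$snapshots$value, 2 * sol$snapshots$value,
               tolerance = 1e-12)
  # D = 0: protein stays on the source support
  solD0 <- sdd_solve(geo, src, sdd_params(D = 0, T_src_on = 1,
                                          T_src_off = 14, T_diff_off = Inf))
  last <- solD0$snapshots[solD0$snapshots$cycle == 14, ]
  src_slabs <- unique(geo$ap_index[src > 0])
  expect_true(all(last$value[-src_slabs] == 0))
  expect_gt(last$value[src_slabs[1]], 0)
})

test_that("1D steady state reproduces the closed-form decay length", {
  geo <- line_geometry(n = 60, spacing_um = 10)
  src <- structure(c(1, numeric(59)), class = "source_field")
  # D = 4 um^2/s, tau = 2500 s: lambda = sqrt(D tau) = 100 um
  tau_min <- 2500 / 60
  params <- sdd_params(D = 4, tau = tau_min, T_src_on = 1, T_src_off = 14,
                       T_diff_off = Inf)
  sol <- sdd_solve(geo, src, params, cycles = 1:14)
  prof <- sol$snapshots[sol$snapshots$cycle == 14, "value"]
  # independent reference integration to steady state (600 min ~ 14 tau)
  c_now <- numeric(60)
  dt <- 0.05
  alpha <- 4 * 60 / 100
  for (s in seq_len(round(600 / dt))) {
    lap <- c(c_now[-1], c_now[60]) + c(c_now[1], c_now[-60]) - 2 * c_now
    c_now <- c_now + dt * (alpha * lap - c_now / tau_min + src)
  }
  x <- (5:40) * 10
  fit <- lm(log(c_now[5:40]) ~ x)
  expect_equal(-1 / unname(coef(fit)[2]), 100, tolerance = 0.02)
  # and the packaged solver agrees with the reference integration
  expect_gt(cor(prof, c_now), 0.99)
})

test_that("grid refinement and maturation limits behave consistently", {
  # halving the spacing changes profiles by < 5% (L2)
  p <- sdd_params()
  g1 <- sdd_geometry(300, 120, 20)
  g2 <- sdd_geometry(300, 120, 10)
  src1 <- build_source(data.frame(ap_fraction = rep(seq(0.02, 0.3, 0.02), 5),
                                  intensity = rep(exp(-seq(0.02, 0.3, 0.02) / 0.1), 5)),
                       g1, "realistic")
  src2 <- build_source(data.frame(ap_fraction = rep(seq(0.02, 0.3, 0.02), 5),
                                  intensity = rep(exp(-seq(0.02, 0.3, 0.02) / 0.1), 5)),
                       g2, "realistic")
  s1 <- sdd_solve(g1, src1, p)$snapshots
  s2 <- sdd_solve(g2, src2, p)$snapshots
  # compared while diffusion is active; once D drops to zero the source
  # accumulates in isolated voxels and slab means are discretisation-bound
  for (cc in 9:11) {
    v1 <- s1$value[s1$cycle == cc]
    v2 <- s2$value[s2$cycle == cc]
    v2c <- (v2[seq(1, 30, 2)] + v2[seq(2, 30, 2)]) / 2
    expect_lt(sqrt(sum((v1 - v2c)^2) / sum(v1^2)), 0.05)
  }
  # fast maturation reproduces the single-species solution
  geo <- sdd_geometry(300, 120, 20)
  src <- build_source(NULL, geo, "point")
  single <- sdd_solve(geo, src, sdd_params())
  fast <- sdd_solve(geo, src, sdd_params(k_maturation = 60), dt = 0.008)
  v_single <- single$snapshots$value[single$snapshots$cycle == 12]
  v_fast <- fast$snapshots$value_mature[fast$snapshots$cycle == 12]
  expect_equal(v_fast, v_single, tolerance = 0.01)
  # slow maturation delays visible fluorescence
  slow <- sdd_solve(geo, src, sdd_params(k_maturation = 1 / 20))
  sm <- slow$snapshots
  expect_lt(sum(sm$value_mature[sm$cycle == 8]),
            sum(sm$value[sm$cycle == 8]))
})

test_that("instability and invalid configurations raise errors", {
  geo <- sdd_geometry(300, 120, 20)
  src <- build_source(NULL, geo, "point")
  expect_error(sdd_solve(geo, src, sdd_params(D = 10), dt = 5),
               "stability")
  expect_error(sdd_params(tau = -5), "tau")
  expect_error(sdd_params(T_src_on = 10, T_src_off = 5), "T_src_on")
})

test_that("best-fit scenario peaks at nuclear cycle 12 and then declines", {
  geo <- sdd_geometry(300, 120, 20)
  sol <- run_paper_scenario(params = sdd_params(), geometry = geo, seed = 1)
  sn <- sol$snapshots
  anterior <- vapply(1:14, function(cc) {
    s <- sn[sn$cycle == cc, ]
    s$value[which.min(abs(s$x_l - 0.1))]
  }, numeric(1))
  expect_equal(which.max(anterior), 12)
  expect_lt(anterior[14], anterior[12])
  expect_true(all(anterior[1:5] == 0))
  # classic-SDD control: fixed source geometry always on, constant D,
  # short tau -> amplitude saturates monotonically, no late decline
  wedge <- sample_particles(embryo_model(stage = 4), 5000, seed = 1)
  classic <- sdd_solve(geo, build_source(wedge, geo, "realistic"),
                       sdd_params(D = 3.1, tau = 30, T_src_on = 1,
                                  T_src_off = 14, T_diff_off = Inf))
  a2 <- vapply(1:14, function(cc) {
    s <- classic$snapshots[classic$snapshots$cycle == cc, ]
    s$value[which.min(abs(s$x_l - 0.1))]
  }, numeric(1))
  expect_true(all(diff(a2) > -1e-9))
  expect_gt(a2[14], 0.95 * max(a2))
})
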