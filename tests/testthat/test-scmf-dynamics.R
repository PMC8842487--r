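test_that("frozen-field Metropolis dynamics reproduces Boltzmann occupancy", {
  lat <- shell_lattice(6, 1.0)
  set.seed(3)
  chains <- list(matrix(c(1.5, 0, 0, 2.5, 0, 0, 3.5, 0, 0), 3, 3,
                        byrow = TRUE))
  piField <- c(1.2, 0.6, 0.2, 0.0, -0.3, 0.1)
  res <- micellex:::cpp_mc_run(
    chains, c(0L, 1L, 0L), c(0L, 1L, 2L), lat$edges, lat$volumes,
    0, 0, 0, 1.0, 1.62, monomer_volume(), monomer_volume(),
    0.9, 150000L, 1000L, FALSE, 100.0, 1.0,
    TRUE, rep(0, 6), piField, rep(0, 6), rep(0, 6), 0L, 0.5, 60L, TRUE)
  occ <- res$occupancy / sum(res$occupancy)
  # independent oracle: direct conformational sampling with Boltzmann
  # reweighting (same frozen field, no Markov chain)
  set.seed(99)
  v_p <- monomer_volume()
  sh <- function(p) min(6L, 1L + floor(sqrt(sum(p^2))))
  hist_or <- rep(0, 6)
  for (i in 1:200000) {
    r <- 6 * runif(1)^(1 / 3)
    cth <- runif(1, -1, 1); ph <- runif(1, 0, 2 * pi)
    x2 <- r * c(sqrt(1 - cth^2) * cos(ph), sqrt(1 - cth^2) * sin(ph), cth)
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    b1 <- x2 + u1; b3 <- x2 + u2
    if (sum((b1 - b3)^2) < 1) next
    if (max(sum(b1^2), sum(b3^2), sum(x2^2)) > 36) next
    H <- v_p * (piField[sh(b1)] + piField[sh(x2)] + piField[sh(b3)])
    hist_or[sh(x2)] <- hist_or[sh(x2)] + exp(-H)
  }
  hist_or <- hist_or / sum(hist_or)
  expect_lt(max(abs(occ - hist_or)), 0.02)   # within Monte-Carlo error
})

test_that("exchange runs are seed-reproducible and conserve tags", {
  spec <- l44_spec("semiflexible")
  lat <- shell_lattice(20)
  r1 <- run_exchange(spec, n_micelle = 30, n_bulk = 4, n_cycles = 2000,
                     burn_in = 500, lattice = lat, stride = 100, seed = 8,
                     membership_radius = 10)
  r2 <- run_exchange(spec, n_micelle = 30, n_bulk = 4, n_cycles = 2000,
                     burn_in = 500, lattice = lat, stride = 100, seed = 8,
                     membership_radius = 10)
  expect_identical(r1$series$f, r2$series$f)
  expect_identical(r1$series$F, r2$series$F)
  # normalization and bounds
  expect_equal(r1$series$F[1], 1)
  expect_true(all(r1$series$f <= r1$f0))
  expect_true(all(diff(r1$series$time_cycles) > 0))
  expect_gt(r1$f0, 0)
  expect_lt(r1$f_eq, r1$f0)
})

test_that("a single free bead diffuses with the closed-form step variance", {
  # translation-only move set: step = amplitude * U(0,1) along an isotropic
  # direction, always accepted, so D = E[step^2]/6 = amplitude^2/18
  set.seed(21)
  amp <- 0.5
  res <- micellex:::cpp_msd_run(
    lapply(1:200, function(i) matrix(rnorm(3), 1, 3)),
    0L, 0L, 0.0, 1.62, amp, 2000L, 10L)
  fit <- lm(msd ~ cycle, data = data.frame(cycle = res$cycle, msd = res$msd))
  D <- unname(coef(fit)[2]) / 6
  expect_equal(D, amp^2 / 18, tolerance = 0.05)
})

test_that("small-amplitude diffusion scales quadratically with amplitude", {
  spec <- l44_spec("semiflexible")
  d1 <- measure_diffusion(spec, n_chains = 40, n_cycles = 1500,
                          amplitude = 0.1, seed = 5)
  d2 <- measure_diffusion(spec, n_chains = 40, n_cycles = 1500,
                          amplitude = 0.2, seed = 5)
  expect_gt(d2$D_scmf / d1$D_scmf, 3.0)
  expect_lt(d2$D_scmf / d1$D_scmf, 5.0)
})

test_that("the time calibration follows Stokes-Einstein", {
  cal <- calibrate_time(D_scmf = 0.5e-3, a_hydro = 1e-9,
                        temperature = 310, eta = 6.91e-4)
  expect_equal(cal$D_phys, 3.3e-10, tolerance = 0.02)
  # inversion consistent with a (D_SCMF, D_phys) pair in the reference range
  cal2 <- calibrate_time(D_scmf = 0.5e-3, a_hydro = 1e-9)
  cal2 <- calibrate_time(0.5e-3, a_hydro = 4.28e-9)  # gives D_phys 7.7e-11
  expect_equal(cal2$D_phys, 7.7e-11, tolerance = 0.02)
  expect_equal(cal2$t_cycle_s, 0.5e-3 * (0.2e-9)^2 / cal2$D_phys,
               tolerance = 1e-12)
  expect_equal(cal2$t_cycle_s, 2.6e-13, tolerance = 0.02)
  # viscosity proportionality
  a <- calibrate_time(1e-3, 1e-9, eta = 6.91e-4)
  b <- calibrate_time(1e-3, 1e-9, eta = 2 * 6.91e-4)
  expect_equal(b$D_phys, a$D_phys / 2, tolerance = 1e-12)
  expect_equal(b$t_cycle_s, 2 * a$t_cycle_s, tolerance = 1e-12)
  expect_error(calibrate_time(1e-3, -1), "radius")
  expect_error(calibrate_time(1e-3, 1e-9, eta = 0), "viscosity")
})

test_that("exchange curves convert cycles to seconds", {
  spec <- l44_spec("semiflexible")
  run <- run_exchange(spec, n_micelle = 25, n_bulk = 3, n_cycles = 1000,
                      burn_in = 300, lattice = shell_lattice(18),
                      stride = 100, seed = 12, membership_radius = 9)
  cv <- exchange_curve(run, t_cycle_s = 7.0e-13)
  expect_equal(cv$time_s, run$series$time_cycles * 7.0e-13)
  expect_identical(cv$F, run$series$F)
})
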