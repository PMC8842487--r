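test_that("closed-form solution agrees with independent ODE integration", {
  set.seed(101)
  for (i in 1:10) {
    eps <- runif(1, 0.01, 0.1)
    k2 <- 10^runif(1, -2, 6)
    gam <- 10^runif(1, -14, 3)
    p <- eyring_params(eps, gam * k2, k2)
    t <- eyring_time_grid(p)
    expect_lt(max(abs(eyring_solution(t, p) - eyring_ode_oracle(t, p))),
              1e-8)
  }
})

test_that("solution starts at one and decays monotonically to its floor", {
  p <- eyring_params(2.6e-2, 1.0e-8, 6.8e5)   # Table-like type-b values
  expect_identical(eyring_solution(0, p), 1)  # exact by construction
  t <- eyring_time_grid(p, 200)
  F <- eyring_solution(t, p)
  expect_true(all(diff(F) <= 1e-12))
  r <- micellex:::eyring_roots(p)
  floor_F <- -p$eps * log(r$wp)
  expect_true(all(F >= floor_F - 1e-10))
})

test_that("right-hand side is consistent with the solution and its limits", {
  p <- eyring_params(0.03, 5e-2, 1e2)
  t <- 10^seq(log10(p$tau1), log10(5 * p$tau2), length.out = 40)
  F <- eyring_solution(t, p)
  h <- t * 1e-6
  dF_num <- (eyring_solution(t + h, p) - eyring_solution(t - h, p)) / (2 * h)
  dF <- eyring_rhs(F, p)
  expect_lt(max(abs(dF_num - dF) / pmax(abs(dF), 1e-300)), 1e-5)
  # decay everywhere above the stationary value
  expect_true(all(dF < 0))
  # k2 -> 0: initial rate is the bare activated term -k1 exp(1/eps)
  p0 <- eyring_params(0.05, 1e-3, 1e-300)
  expect_equal(eyring_rhs(1, p0), -1e-3 * exp(1 / 0.05) + 1e-3 * exp(-1 / 0.05),
               tolerance = 1e-12)
})

test_that("derived time scales match the printed identities", {
  # gamma = k1/k2 for the flexible simulation fit is negligibly small
  p <- eyring_params(2.6e-2, 1.0e-8, 6.8e5)
  expect_equal(p$gamma, 1.0e-8 / 6.8e5, tolerance = 1e-12)
  expect_lt(p$gamma, 1e-13)
  expect_equal(p$class, "b")
  # tau1 = (eps/k1) exp(-1/eps) ~ 5e-11 s, consistent with a logarithmic
  # onset near 1e-10 s
  expect_equal(p$tau1, (2.6e-2 / 1.0e-8) * exp(-1 / 2.6e-2), tolerance = 1e-12)
  expect_gt(p$tau1, 2e-11)
  expect_lt(p$tau1, 1e-10)
})

test_that("master transform round-trips and produces the -1 slope", {
  p <- eyring_params(0.02, 4e-5, 4e5)
  t <- 10^seq(-12, -4, length.out = 80)
  curve <- eyring_curve(t, p)
  sc <- scale_transform(curve, p)
  back <- unscale_transform(sc, p)
  expect_equal(back$F, curve$F, tolerance = 1e-12)
  expect_equal(back$time_s, curve$time_s, tolerance = 1e-12)
  # slope of log y* vs log t* in the logarithmic window
  tstar <- 10^seq(-3, log10(2e-2), length.out = 40)
  sc2 <- scale_transform(eyring_curve(tstar * p$a, p), p)
  slope <- unname(coef(lm(sc2$log_y_star ~ log(sc2$t_star)))[2])
  expect_lt(abs(slope + 1), 0.02)
})

test_that("any two type-b parameter sets with a logarithmic regime collapse", {
  sets <- list(
    eyring_params(0.02, 4e-5, 4e5),
    eyring_params(2.6e-2, 1.0e-8, 6.8e5),
    eyring_params(0.03, 5e-6, 50),
    eyring_params(0.025, 1e-3, 1e4)
  )
  u <- vapply(sets, function(p) exp(-1 / p$eps) / p$gamma, 0.0)
  for (i in 2:length(sets)) {
    # compare beyond the (non-universal) initial fast regime of both curves
    t_lo <- max(1e-2, 100 * max(u[1], u[i]))
    tstar <- 10^seq(log10(t_lo), 0, length.out = 50)
    l1 <- scale_transform(eyring_curve(tstar * sets[[1]]$a, sets[[1]]),
                          sets[[1]])$log_y_star
    li <- scale_transform(eyring_curve(tstar * sets[[i]]$a, sets[[i]]),
                          sets[[i]])$log_y_star
    expect_lt(max(abs(exp(li - l1) - 1)), 0.02)
  }
})

test_that("asymptotic approximants are accurate in their stated windows", {
  p <- eyring_params(0.02, 1e-6 * 4e5, 4e5)   # gamma = 1e-6, type b
  exact <- function(t) eyring_solution(t, p)
  # logarithmic: 10 tau1 up to a tenth of the crossover
  f_log <- eyring_asymptotic(p, "logarithmic")
  tw <- 10^seq(log10(10 * p$tau1), log10(p$a / 10), length.out = 100)
  expect_lt(max(abs(f_log(tw) - exact(tw))), 0.01)
  # matched global form: full range
  f_m <- eyring_asymptotic(p, "matched")
  tt <- 10^seq(log10(p$tau1 / 10), log10(5 * p$a), length.out = 200)
  expect_lt(max(abs(f_m(tt) - exact(tt))), 0.01)
  expect_equal(f_m(0), 1, tolerance = 1e-12)
  # second intermediate exponential beyond t* ~ 1
  f_2 <- eyring_asymptotic(p, "second_intermediate")
  t2 <- p$a * seq(2, 4, length.out = 10)
  expect_lt(max(abs(f_2(t2) - exact(t2))), 0.02)
  # type-a terminal approach
  pa <- eyring_params(0.05, 2e3, 1e2)
  f_t <- eyring_asymptotic(pa, "terminal")
  t3 <- pa$tau2 * 10^seq(0.5, 1.5, length.out = 20)
  expect_lt(max(abs(f_t(t3) - eyring_solution(t3, pa))), 0.01)
  # regime errors
  expect_error(eyring_asymptotic(p, "terminal"), "type-a")
  expect_error(eyring_asymptotic(pa, "matched"), "type-b")
})

test_that("fits recover known parameters from synthetic curves", {
  p_true <- eyring_params(0.02, 1e-13, 4e5)
  s <- synth_curves(list(p_true), noise = 0, seed = 7, n_points = 200)
  fit <- eyring_fit(s$curves[[1]])
  expect_lt(abs(fit$params$eps / p_true$eps - 1), 0.01)
  expect_lt(abs(fit$params$k1 / p_true$k1 - 1), 0.01)
  expect_lt(abs(fit$params$k2 / p_true$k2 - 1), 0.01)
  expect_gt(fit$r2, 0.9999)

  p2 <- eyring_params(0.08, 1, 100)
  s2 <- synth_curves(list(p2), noise = 0.01, seed = 11, n_points = 400)
  fit2 <- eyring_fit(s2$curves[[1]])
  expect_lt(abs(fit2$params$eps / p2$eps - 1), 0.10)
  expect_lt(abs(fit2$params$k1 / p2$k1 - 1), 0.10)
  expect_lt(abs(fit2$params$k2 / p2$k2 - 1), 0.10)
  expect_gt(fit2$r2, 0.98)
})

test_that("degenerate fit inputs are rejected", {
  t <- 10^seq(-10, -4, length.out = 50)
  expect_error(eyring_fit(tibble::tibble(time_s = t, F = rep(1, 50))),
               "flat")
  expect_error(eyring_fit(tibble::tibble(time_s = t[1:5], F = runif(5))),
               "at least 10")
})

test_that("tidy and glance summarize a fit", {
  p <- eyring_params(0.03, 1e-4, 1e3)
  s <- synth_curves(list(p), noise = 0, seed = 3, n_points = 120)
  fit <- eyring_fit(s$curves[[1]])
  td <- tidy(fit)
  expect_setequal(td$term, c("eps", "k1", "k2", "gamma", "tau1", "tau2"))
  gl <- glance(fit)
  expect_equal(gl$class, "b")
  expect_true(gl$r.squared > 0.999)
})

test_that("classification labels dynamic classes and flags unreliable k2", {
  # experimental-style constants: k1 = 4.1e-10, k2 = 2.4e-9 at 47 C
  p_exp <- eyring_params(7.2e-2, 4.1e-10, 2.4e-9)
  expect_equal(p_exp$gamma, 4.1e-10 / 2.4e-9, tolerance = 1e-12)
  expect_equal(round(log10(p_exp$gamma)), -1)   # gamma ~ 1e-1
  expect_equal(p_exp$class, "b")

  p_sim <- eyring_params(2.0e-2, 1.0e-13, 4.1e5)
  full <- eyring_curve(10^seq(log10(p_exp$tau1 / 10), log10(5 * p_exp$a),
                              length.out = 60), p_exp)
  # curve truncated inside the logarithmic window: t*max < 0.1
  trunc <- eyring_curve(10^seq(-11, -9, length.out = 30), p_sim)
  cc <- classify_and_collapse(list(
    list(curve = full, params = p_exp),
    list(curve = trunc, params = p_sim)
  ), ids = c("experimental", "truncated"))
  expect_equal(cc$classification$class, c("b", "b"))
  expect_true(cc$classification$k2_reliable[1])
  expect_false(cc$classification$k2_reliable[2])
  expect_setequal(unique(cc$scaled$id), c("experimental", "truncated"))
  # boundary case warns
  expect_warning(eyring_params(0.05, 1, 1), "boundary")
})
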