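toy_lattice <- function() shell_lattice(3, 2.0)

toy_chains <- function() {
  mk <- function(r) cbind(c(r - 1, r, r + 1), 0, 0)
  lapply(c(1.2, 1.8, 2.6, 3.4, 4.1, 4.8), mk)
}

toy_ensemble <- function(pot = pair_potential()) {
  manual_ensemble(toy_chains(), chain_spec(1, 1, 1, 1, 1), toy_lattice(),
                  pot = pot)
}

test_that("projections conserve bead and well volumes", {
  spec <- l44_spec("semiflexible")
  lat <- shell_lattice(30)
  pot <- pair_potential()
  set.seed(23)
  conf <- sample_conformation(spec, center = TRUE)
  pr <- project_conformation(conf, lat, center = c(6, 0, 0),
                             screen_intra = FALSE)
  v_p <- monomer_volume()
  # all bead volume lands somewhere; EO/PO split is exact
  expect_equal(sum(pr$phi_EO * lat$volumes), 20 * v_p, tolerance = 1e-9)
  expect_equal(sum(pr$phi_PO * lat$volumes), 23 * v_p, tolerance = 1e-9)
  # unscreened interaction volumes: n_beads x the analytic well-shell volume
  vwell <- 4 / 3 * pi * (pot$well_outer^3 - 1)
  expect_equal(sum(pr$Phi_EO * lat$volumes), 20 * vwell, tolerance = 1e-9)
  expect_equal(sum(pr$Phi_PO * lat$volumes), 23 * vwell, tolerance = 1e-9)
  # screening strictly reduces the accessible interaction volume
  pr_s <- project_conformation(conf, lat, center = c(6, 0, 0),
                               screen_intra = TRUE)
  expect_lt(sum(pr_s$Phi_PO * lat$volumes), 23 * vwell)
  expect_gt(sum(pr_s$Phi_PO * lat$volumes), 0.3 * 23 * vwell)
})

test_that("a single bead lands entirely in the shell containing it", {
  spec <- chain_spec(1, 1, 1, 1, 1)
  lat <- shell_lattice(5, 1.0)
  conf <- make_conformation(rbind(c(2.4, 0, 0), c(3.4, 0, 0), c(4.4, 0, 0)),
                            c(0L, 1L, 0L))
  pr <- project_conformation(conf, lat)
  expect_equal(pr$phi_PO[4] * lat$volumes[4], monomer_volume(),
               tolerance = 1e-12)
  expect_equal(sum(pr$phi_PO[-4]), 0)
  # radial translation by one shell width shifts the bin by one
  conf2 <- make_conformation(unclass(conf) - rep(c(1, 0, 0), each = 3),
                             c(0L, 1L, 0L))
  pr2 <- project_conformation(conf2, lat)
  expect_equal(pr2$phi_PO[3] * lat$volumes[3], monomer_volume(),
               tolerance = 1e-12)
})

test_that("the Hamiltonian reduces to the intramolecular energy when decoupled", {
  pot0 <- pair_potential(eps_EO_PO = 0, eps_EO_s = 0, eps_PO_s = 0)
  ens <- toy_ensemble(pot0)
  R <- 3
  fields <- list(CEO = rep(0.3, R), CPO = rep(0.2, R), WEO = rep(5, R),
                 WPO = rep(4, R), cs = rep(1, R), pi = rep(0, R))
  expect_equal(scmf_hamiltonian(ens, fields, N = 4), ens$U, tolerance = 1e-12)
})

test_that("solvent coupling is linear in the solvent concentration", {
  ens <- toy_ensemble()
  R <- 3
  base <- list(CEO = rep(0, R), CPO = rep(0, R), WEO = rep(0, R),
               WPO = rep(0, R), cs = rep(0.5, R), pi = rep(0, R))
  h1 <- scmf_hamiltonian(ens, base, N = 4) - ens$U
  base$cs <- base$cs * 2
  h2 <- scmf_hamiltonian(ens, base, N = 4) - ens$U
  expect_equal(h2, 2 * h1, tolerance = 1e-12)
})

test_that("the Hamiltonian matches a hand-computed term-by-term sum", {
  pot <- pair_potential()
  lat <- shell_lattice(2, 2.0)
  chains <- list(cbind(c(0.5, 1.5, 2.5), 0, 0))
  ens <- manual_ensemble(chains, chain_spec(1, 1, 1, 1, 1), lat, pot = pot)
  R <- 2
  fields <- list(CEO = c(0.1, 0.2), CPO = c(0.3, 0.05), WEO = c(2, 1),
                 WPO = c(1.5, 0.5), cs = c(0.8, 1.2), pi = c(0.4, -0.1))
  N <- 3
  q <- (N - 1) / N
  Vr <- lat$volumes
  hand <- ens$U[1] +
    q * pot$contact_EO_PO / 2 *
      (sum(ens$wEO[1, ] * fields$CPO) + sum(ens$nPO[1, ] * fields$WEO / Vr) +
       sum(ens$wPO[1, ] * fields$CEO) + sum(ens$nEO[1, ] * fields$WPO / Vr)) +
    pot$contact_EO_s * sum(ens$wEO[1, ] * fields$cs) +
    pot$contact_PO_s * sum(ens$wPO[1, ] * fields$cs) +
    monomer_volume() * sum((ens$nEO[1, ] + ens$nPO[1, ]) * fields$pi)
  expect_equal(scmf_hamiltonian(ens, fields, N), hand, tolerance = 1e-12)
})

test_that("the self-consistent fixed point minimizes the free energy", {
  ens <- toy_ensemble()
  N <- 4
  st <- solve_scmf(ens, N, tol = 1e-12, max_iter = 20000, mix = 0.2)
  expect_true(st$converged)
  expect_equal(sum(st$p), 1, tolerance = 1e-12)
  expect_lte(st$incomp_residual, 1e-6)
  direct <- scmf_direct_minimum(ens, N)
  expect_lt(abs(direct$F - st$F), 1e-6)
  # local minimality: perturbing the weights can only raise the functional
  set.seed(31)
  for (i in 1:10) {
    theta <- log(st$p) + rnorm(ens$M, 0, 0.05)
    p2 <- exp(theta - max(theta)); p2 <- p2 / sum(p2)
    Vr <- ens$lattice$volumes
    f2 <- list(CEO = N * as.numeric(crossprod(p2, ens$nEO)) / Vr,
               CPO = N * as.numeric(crossprod(p2, ens$nPO)) / Vr,
               WEO = N * as.numeric(crossprod(p2, ens$wEO)),
               WPO = N * as.numeric(crossprod(p2, ens$wPO)))
    phis <- pmax(1e-12, 1 - (f2$CEO + f2$CPO) * ens$v_p)
    f2$cs <- phis / monomer_volume()
    f2$pi <- rep(0, 3)
    expect_gte(scmf_free_energy(ens, N, p2, f2) - st$F, -1e-9)
  }
})

test_that("an ideal ensemble converges to uniform weights and uniform fields", {
  pot0 <- pair_potential(eps_EO_PO = 0, eps_EO_s = 0, eps_PO_s = 0)
  # equal intramolecular energy (straight rods) at different radii; bead
  # volume taken negligible so the steric field vanishes too
  ens <- manual_ensemble(toy_chains(), chain_spec(1, 1, 1, 1, 1),
                         toy_lattice(), pot = pot0, v_p = 1e-9)
  st <- solve_scmf(ens, N = 2, tol = 1e-12, max_iter = 5000, mix = 0.3)
  expect_true(st$converged)
  expect_equal(st$p, rep(1 / ens$M, ens$M), tolerance = 1e-6)
  expect_lt(diff(range(st$fields$cs)), 1e-6)
})

test_that("weights must be normalized to evaluate the free energy", {
  ens <- toy_ensemble()
  st <- solve_scmf(ens, 2, max_iter = 200)
  expect_error(scmf_free_energy(ens, 2, st$p * 2, st$fields),
               "not normalized")
})

test_that("hydrophobic driving strength deepens the micelle free energy", {
  # fixed toy ensemble, growing PO-solvent penalty
  lat <- shell_lattice(6, 1.5)
  set.seed(37)
  spec <- chain_spec(2, 4, 2, 2, 4)
  mk <- function() {
    conf <- sample_conformation(spec, center = TRUE)
    unclass(conf)
  }
  chains <- replicate(40, mk(), simplify = FALSE)
  vals <- vapply(c(0.5, 1.2, 2.1), function(e) {
    pot <- pair_potential(eps_PO_s = e)
    ens <- manual_ensemble(chains, spec, lat, pot = pot)
    st <- solve_scmf(ens, N = 8, tol = 1e-10, max_iter = 8000, mix = 0.2)
    st$F
  }, 0.0)
  expect_true(all(diff(vals) > 0))  # larger penalty, higher absolute F of the
                                    # solvated cluster (less favourable)
})

test_that("no hydrophobic penalty means no micellization", {
  pot0 <- pair_potential(eps_PO_s = 0, eps_EO_s = 0)
  scan <- micellization_scan(l44_spec("semiflexible"), pot = pot0,
                             N_range = c(10L, 20L, 40L),
                             lattice = shell_lattice(16), M = 300L,
                             M_single = 200L, seed = 3, max_iter = 300L,
                             n_macro = 1L)
  expect_false(scan$micellized)
  expect_true(is.na(scan$N_star))
})
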