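#' Dynamic SCMF exchange simulation
#'
#' Metropolis dynamics of N explicit chains inside self-consistently updated
#' spherical mean fields: in every cycle each chain receives one symmetric
#' local move (joint pivot or rigid translation), accepted with
#' min(1, exp(-dH/kBT)) where H is the single-chain SCMF Hamiltonian in the
#' cycle-start fields (own contribution excluded), after which the
#' concentration fields, solvent profile and incompressibility multiplier
#' are re-solved from the new ensemble.  Chains inside the micelle at the
#' end of the burn-in are tagged, and the tagged-in-micelle count f(t) gives
#' the exchange correlation function
#' \deqn{F(t) = \frac{f(t) - f_{eq}}{f(0) - f_{eq}},}
#' with f_eq = f(0) x (tagged chains / total chains) the mixing-equilibrium
#' expectation (the tagged equilibrium is not zero; runs are far shorter
#' than full remixing, so f_eq is computed, not measured).
#'
#' Membership uses the PO-block centre of mass: a chain is inside while its
#' PO centre lies within the corona/bulk interface radius, with a 1 sigma
#' hysteresis band to suppress boundary flicker.
#'
#' @param spec A [chain_spec()].
#' @param n_micelle Chains initially placed in the micelle.
#' @param n_bulk Additional untagged chains placed in the bulk region.
#' @param n_cycles Production Monte Carlo cycles.
#' @param burn_in Equilibration cycles before tagging.
#' @param lattice A [shell_lattice()].
#' @param pot A [pair_potential()].
#' @param amplitude Move amplitude (radians for pivots, sigma for
#'   translations).  Acceptance for L44-type chains plateaus near 60-75
#'   percent over a wide amplitude range (short-sub-chain pivots stay
#'   cheap); the default sits at the onset of that plateau.
#' @param stride Record f(t) every `stride` cycles.
#' @param seed Integer seed (R RNG; runs are bit-reproducible).
#' @param v_s Solvent molecular volume (sigma^3).
#' @param membership_radius Corona/bulk interface radius (sigma); `NULL`
#'   detects it from the burn-in averaged fields via [region_boundaries()].
#' @param profile_every Accumulate radial shape profiles every this many
#'   cycles (0 disables).
#' @param prof_bin,n_prof_bins Radial profile binning (sigma).
#' @return An object of class `exchange_run`: `series` (tibble:
#'   `time_cycles`, `f`, `F`), `f0`, `f_eq`, `n_chains`,
#'   `membership_radius`, `accept_rate`, `boundaries`, averaged
#'   concentration fields, profile accumulators and the final chain
#'   positions.
#' @export
run_exchange <- function(spec, n_micelle = 91L, n_bulk = 10L,
                         n_cycles = 20000L, burn_in = 5000L,
                         lattice = shell_lattice(28L),
                         pot = pair_potential(), amplitude = 1.2,
                         stride = 10L, seed = 1L, v_s = monomer_volume(),
                         membership_radius = NULL, profile_every = 10L,
                         prof_bin = 0.5, n_prof_bins = 60L) {
  set.seed(seed)
  v_p <- monomer_volume()
  chains <- init_micelle_chains(spec, n_micelle, n_bulk, lattice, pot)
  nc <- length(chains)
  block <- block_labels(spec)
  seg_end <- segment_ends(spec)
  r_guess <- micelle_radius_guess(spec, n_micelle, v_p) + 4
  burn <- cpp_mc_run(chains, block, seg_end, lattice$edges, lattice$volumes,
                     pot$contact_EO_PO, pot$contact_EO_s, pot$contact_PO_s,
                     pot$hard_core, pot$well_outer, v_p, v_s,
                     amplitude, as.integer(burn_in), as.integer(stride),
                     rep(FALSE, nc), r_guess, 1.0,
                     FALSE, numeric(0), numeric(0), numeric(0), numeric(0),
                     0L, prof_bin, as.integer(n_prof_bins), TRUE)
  fields_burn <- tibble::tibble(r_mid = lattice$r_mid,
                                c_EO = burn$avg_cEO, c_PO = burn$avg_cPO)
  bounds <- tryCatch(region_boundaries(fields_burn),
                     error = function(e) NULL)
  r_memb <- if (!is.null(membership_radius)) membership_radius
            else if (!is.null(bounds)) bounds$r_corona_bulk else r_guess
  # tag the chains currently inside the micelle
  po_r <- vapply(burn$chains, function(p) {
    po <- p[block == 1L, , drop = FALSE]
    sqrt(sum(colMeans(po)^2))
  }, 0.0)
  tagged <- po_r < r_memb
  if (!any(tagged)) stop("zero chains inside the micelle after burn-in")
  run <- cpp_mc_run(burn$chains, block, seg_end, lattice$edges,
                    lattice$volumes,
                    pot$contact_EO_PO, pot$contact_EO_s, pot$contact_PO_s,
                    pot$hard_core, pot$well_outer, v_p, v_s,
                    amplitude, as.integer(n_cycles), as.integer(stride),
                    tagged, r_memb, 1.0,
                    FALSE, numeric(0), numeric(0), numeric(0), numeric(0),
                    as.integer(profile_every), prof_bin,
                    as.integer(n_prof_bins), TRUE)
  f0 <- sum(tagged)
  f_eq <- f0 * f0 / nc
  f_all <- c(f0, run$f)
  if (f0 - f_eq > sqrt(.Machine$double.eps)) {
    Fv <- (f_all - f_eq) / (f0 - f_eq)
  } else {
    # every chain tagged: the relaxation normalization is undefined
    warning("all chains are tagged (f_eq = f0): F(t) undefined, returning NA")
    Fv <- rep(NA_real_, length(f_all))
  }
  series <- tibble::tibble(
    time_cycles = c(0L, run$cycle),
    f = f_all,
    F = Fv
  )
  structure(
    list(series = series, f0 = f0, f_eq = f_eq, n_chains = nc,
         membership_radius = r_memb, boundaries = bounds,
         accept_rate = run$accept_rate,
         fields = tibble::tibble(r_mid = lattice$r_mid,
                                 c_EO = run$avg_cEO, c_PO = run$avg_cPO),
         profiles_raw = run[c("prof_rg_sum", "prof_angle_sum", "prof_n",
                              "prof_n_angle")],
         prof_bin = prof_bin,
         chains = run$chains, member = run$member, tagged = tagged,
         spec = spec, lattice = lattice, seed = seed),
    class = "exchange_run"
  )
}

#' @export
print.exchange_run <- function(x, ...) {
  cat(sprintf(
    "dynamic SCMF exchange run: %d chains (f0 = %d tagged), %d records\n",
    x$n_chains, x$f0, nrow(x$series)))
  cat(sprintf("  membership radius %.2f sigma, acceptance %.1f%%\n",
              x$membership_radius, 100 * x$accept_rate))
  invisible(x)
}

init_micelle_chains <- function(spec, n_micelle, n_bulk, lattice, pot) {
  seg_len <- segment_lengths(spec)
  block <- block_labels(spec)
  Rcell <- max(lattice$edges)
  r_core <- micelle_radius_guess(spec, n_micelle, monomer_volume())
  chains <- vector("list", n_micelle + n_bulk)
  for (i in seq_len(n_micelle + n_bulk)) {
    repeat {
      pos <- cpp_sample_chain(seg_len, 10000L)
      po <- pos[block == 1L, , drop = FALSE]
      pos <- sweep(pos, 2, colMeans(po))     # PO centre at origin
      pos <- pos %*% random_rotation()
      ext <- sqrt(max(rowSums(pos^2)))
      if (i <= n_micelle) {
        r <- r_core * stats::runif(1)^(1 / 3)
      } else {
        lo <- min(r_core + 5, Rcell - ext - 1)
        hi <- Rcell - ext - 0.5
        if (hi <= lo) next
        r <- stats::runif(1, lo, hi)
      }
      if (ext + r < Rcell) {
        chains[[i]] <- sweep(pos, 2, -r * random_unit())
        break
      }
    }
  }
  chains
}

micelle_radius_guess <- function(spec, N, v_p) {
  (3 * N * spec$n_PO * v_p / (4 * pi * 0.85))^(1 / 3)
}

#' Centre-of-mass diffusion constant of free chains
#'
#' Runs free-space Monte Carlo dynamics of independent chains (exact
#' intramolecular energetics, no fields) and extracts D_SCMF from the slope
#' of the mean-square centre-of-mass displacement versus cycles, divided
#' by 6.
#'
#' @param spec A [chain_spec()].
#' @param n_chains Independent chains.
#' @param n_cycles Cycles.
#' @param amplitude Move amplitude.
#' @param stride Recording stride.
#' @param seed Integer seed.
#' @param pot A [pair_potential()].
#' @return A list with `D_scmf` (sigma^2/cycle), `series` (tibble: cycle,
#'   msd), `accept_rate` and the regression `slope`.
#' @export
measure_diffusion <- function(spec, n_chains = 50L, n_cycles = 5000L,
                              amplitude = 1.2, stride = 10L, seed = 1L,
                              pot = pair_potential()) {
  set.seed(seed)
  seg_len <- segment_lengths(spec)
  chains <- lapply(seq_len(n_chains), function(i) cpp_sample_chain(seg_len, 10000L))
  res <- cpp_msd_run(chains, block_labels(spec), segment_ends(spec),
                     pot$contact_EO_PO, pot$well_outer, amplitude,
                     as.integer(n_cycles), as.integer(stride))
  series <- tibble::tibble(cycle = res$cycle, msd = res$msd)
  if (nrow(series) < 5L) stop("insufficient cycles for the linear MSD regime")
  # slope over the second half (linear regime, past initial transients)
  half <- series[series$cycle > max(series$cycle) / 2, ]
  slope <- stats::coef(stats::lm(msd ~ cycle, data = half))[["cycle"]]
  list(D_scmf = slope / 6, series = series, accept_rate = res$accept_rate,
       slope = slope)
}

#' Convert Monte Carlo cycles to physical time
#'
#' Matches the simulated free-chain diffusion constant D_SCMF
#' (sigma^2/cycle) to the physical Stokes-Einstein diffusion constant
#' D = kB T / (6 pi eta a), giving the duration of one cycle
#' t_cycle = D_SCMF l^2 / D with l the physical bead size.
#'
#' @param D_scmf Simulated diffusion constant (sigma^2/cycle).
#' @param a_hydro Hydrodynamic radius (m).  The model supplies no closed
#'   expression for it; supply a measured free-chain radius of gyration (in
#'   metres) or another estimate.
#' @param l Physical bead size (m), ~0.2 nm.
#' @param temperature Temperature (K).
#' @param eta Solvent viscosity (kg/m/s); water at 37 C by default.
#' @return A list with `D_phys` (m^2/s) and `t_cycle_s` (seconds per cycle).
#' @examples
#' calibrate_time(D_scmf = 0.5e-3, a_hydro = 1e-9)
#' @export
calibrate_time <- function(D_scmf, a_hydro, l = 0.2e-9,
                           temperature = 310.15, eta = 6.91e-4) {
  if (!is.finite(a_hydro) || a_hydro <= 0) stop("hydrodynamic radius must be > 0")
  if (!is.finite(eta) || eta <= 0) stop("viscosity must be > 0")
  kB <- 1.380649e-23
  D_phys <- kB * temperature / (6 * pi * eta * a_hydro)
  list(D_phys = D_phys, t_cycle_s = D_scmf * l^2 / D_phys)
}

#' Exchange correlation series in seconds
#'
#' Applies a cycle-time calibration to an [run_exchange()] result.
#'
#' @param run An `exchange_run`.
#' @param t_cycle_s Seconds per cycle (see [calibrate_time()]).
#' @return A tibble with `time_s`, `time_cycles`, `F`.
#' @export
exchange_curve <- function(run, t_cycle_s) {
  stopifnot(inherits(run, "exchange_run"), t_cycle_s > 0)
  tibble::tibble(time_s = run$series$time_cycles * t_cycle_s,
                 time_cycles = run$series$time_cycles,
                 F = run$series$F)
}
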