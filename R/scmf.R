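#' Spherical-shell lattice for the mean fields
#'
#' Concentric shells of equal width starting from the cell centre; all mean
#' fields (concentrations, solvent, incompressibility multiplier) live on
#' this one-dimensional radial grid.
#'
#' @param n_shells Number of shells.
#' @param width Shell width (sigma).
#' @return An object of class `shell_lattice` with `edges` (length
#'   n_shells + 1), `r_mid`, `volumes` and total cell volume `V`.
#' @export
shell_lattice <- function(n_shells = 28L, width = 1.0) {
  stopifnot(n_shells >= 2L, width > 0)
  edges <- seq(0, n_shells * width, by = width)
  vol <- 4 / 3 * pi * diff(edges^3)
  structure(
    list(n_shells = as.integer(n_shells), width = width, edges = edges,
         r_mid = (edges[-1] + edges[-length(edges)]) / 2,
         volumes = vol, V = sum(vol)),
    class = "shell_lattice"
  )
}

#' Default monomer volume (sigma^3)
#'
#' One bead of diameter sigma; the solvent molecular volume defaults to the
#' same value (one solvent molecule per bead volume).
#' @return (pi/6) sigma^3.
#' @export
monomer_volume <- function() pi / 6

#' Project a conformation onto the shell lattice
#'
#' Bins bead volumes by bead-centre shell (volume fractions phi) and
#' apportions each bead's square-well shell (inner radius 1 sigma, outer
#' 1.62 sigma) among the lattice shells analytically (available interaction
#' volumes Phi, expressed as volume fractions of each shell).
#'
#' @param conf A conformation.
#' @param lattice A [shell_lattice()].
#' @param center Optional 3-vector added to the conformation before
#'   projection (placement relative to the cell centre).
#' @param pot A [pair_potential()] (for the well radii).
#' @param v_p Monomer volume (sigma^3).
#' @param screen_intra Exclude the volume blocked by the chain's own beads
#'   from the interaction wells (pairwise overlap correction)?  The default
#'   reflects that solvent and neighbouring molecules cannot occupy space
#'   already filled by the chain itself; disable to obtain the bare
#'   geometric well volumes.
#' @return A tibble with one row per shell: `shell`, `r_mid`, `phi_EO`,
#'   `phi_PO`, `Phi_EO`, `Phi_PO`, plus attribute `outside` (TRUE when any
#'   bead fell outside the lattice: the cell is too small).
#' @export
project_conformation <- function(conf, lattice, center = c(0, 0, 0),
                                 pot = pair_potential(),
                                 v_p = monomer_volume(),
                                 screen_intra = TRUE) {
  stopifnot(inherits(lattice, "shell_lattice"))
  pos <- sweep(unclass(conf)[, , drop = FALSE], 2, -center)
  pr <- cpp_project(pos, attr(conf, "block"), lattice$edges,
                    pot$hard_core, pot$well_outer, screen_intra)
  if (pr$outside) warning("beads outside the lattice: cell too small")
  out <- tibble::tibble(
    shell = seq_len(lattice$n_shells),
    r_mid = lattice$r_mid,
    phi_EO = pr$count_EO * v_p / lattice$volumes,
    phi_PO = pr$count_PO * v_p / lattice$volumes,
    Phi_EO = pr$well_EO / lattice$volumes,
    Phi_PO = pr$well_PO / lattice$volumes
  )
  attr(out, "outside") <- pr$outside
  out
}

#' Sample a conformation ensemble for an SCMF solve
#'
#' Samples `M` self-avoiding conformations, applies a random rotation, and
#' places the centre of mass in the cell: `"biased"` places it at a radius
#' uniform in r (importance bias toward the micelle centre, corrected by the
#' recorded sampling density so results are placement-unbiased),
#' `"uniform"` places it uniformly in the cell volume, `"pinned"` keeps the
#' centre of mass at the origin (used for the single-chain reference solve,
#' where the translational entropy is excluded by construction).
#'
#' Conformations are placed by the centre of mass of the PO block (the
#' natural coordinate of the micelle problem); the importance correction
#' uses the exact conditional placement density of each sampled chain, so
#' the free energy is unbiased for any placement rule.  Passing a
#' `radial_density` (from a previous solve, see [radial_density()])
#' importance-resamples the placements toward the current micelle profile,
#' which keeps the effective sample size usable in the strongly localized
#' micelle states.
#'
#' @param spec A [chain_spec()].
#' @param lattice A [shell_lattice()].
#' @param M Ensemble size.
#' @param placement `"biased"` (uniform in radius, centre-weighted in
#'   volume), `"uniform"` (uniform in the cell volume) or `"pinned"`
#'   (PO centre at the origin).
#' @param pot A [pair_potential()].
#' @param seed Integer seed.
#' @param v_p Monomer volume (sigma^3).
#' @param radial_density Optional target radial density for the placements
#'   (a list with `breaks` and `dens`, normalized over radius); mixed with
#'   30 percent of the flat proposal for exploration.
#' @param orient_bias Importance-bias the chain orientation so the EO blocks
#'   point outward (density-corrected); raises the effective sample size of
#'   micelle solves.
#' @return An object of class `scmf_ensemble` carrying per-sample bead-count
#'   and well-volume projections (M x n_shells matrices), exact
#'   intramolecular energies, log sampling densities (relative to one
#'   solvent site) and shape observables.
#' @export
scmf_ensemble <- function(spec, lattice, M = 5000L,
                          placement = c("biased", "uniform", "pinned"),
                          pot = pair_potential(), seed = NULL,
                          v_p = monomer_volume(), radial_density = NULL,
                          orient_bias = FALSE) {
  placement <- match.arg(placement)
  if (!is.null(seed)) set.seed(seed)
  v_s <- v_p
  block <- block_labels(spec)
  seg_len <- segment_lengths(spec)
  Rcell <- max(lattice$edges)
  w_unif <- 0.3
  chains <- vector("list", M)
  logg <- numeric(M)
  U <- numeric(M)
  r_po <- rg_po <- angle <- numeric(M)
  for (m in seq_len(M)) {
    repeat {
      pos <- cpp_sample_chain(seg_len, 10000L)
      po_rows <- block == 1L
      pos <- sweep(pos, 2, colMeans(pos[po_rows, , drop = FALSE]))
      pos <- pos %*% random_rotation()
      ext <- sqrt(max(rowSums(pos^2)))
      rmax <- Rcell - ext - 1e-9
      if (placement == "pinned" || rmax > 0) break
    }
    if (placement == "pinned") {
      r <- 0
      logg[m] <- 0
    } else if (placement == "uniform") {
      r <- rmax * stats::runif(1)^(1 / 3)
      logg[m] <- log(v_s) - log(4 / 3 * pi * rmax^3)
    } else if (is.null(radial_density)) {
      r <- stats::runif(1, 0, rmax)
      logg[m] <- log(v_s) - log(4 * pi * max(r, 1e-6)^2 * rmax)
    } else {
      # mixture of flat-in-r and the supplied radial density (truncated to
      # this conformation's admissible radius)
      br <- radial_density$breaks
      dr <- diff(br)
      mass <- radial_density$dens * dr
      # truncation to [0, rmax]
      frac_in <- pmin(pmax((rmax - br[-length(br)]) / dr, 0), 1)
      mass_tr <- mass * frac_in
      Htr <- sum(mass_tr)
      if (stats::runif(1) < w_unif || Htr <= 0) {
        r <- stats::runif(1, 0, rmax)
      } else {
        b <- sample.int(length(mass_tr), 1L, prob = mass_tr)
        r <- stats::runif(1, br[b], min(br[b + 1], rmax))
      }
      dens_here <- function(rr) {
        b <- findInterval(rr, br, all.inside = TRUE)
        h <- if (Htr > 0) radial_density$dens[b] / Htr else 0
        w_unif / rmax + (1 - w_unif) * h
      }
      logg[m] <- log(v_s) + log(dens_here(r)) - log(4 * pi * max(r, 1e-6)^2)
    }
    if (r > 0) {
      u <- random_unit()
      if (orient_bias && placement == "biased") {
        # align the PO->EO internal axis with the outward radial direction,
        # importance-corrected (uniform rotations give cos(theta) ~ U[-1,1])
        eo <- pos[!po_rows, , drop = FALSE]
        ax <- colMeans(eo)
        nax <- sqrt(sum(ax^2))
        if (nax > 1e-9) {
          ax <- ax / nax
          cb <- sample_cos_bias()
          pos <- pos %*% rotation_between(ax, c(0, 0, 1))
          pos <- pos %*% rotation_about_z(stats::runif(1, 0, 2 * pi))
          st <- sqrt(max(0, 1 - cb$c^2))
          tilt <- rotation_between(c(0, 0, 1), c(st, 0, cb$c))
          pos <- pos %*% tilt
          frame <- rotation_between(c(0, 0, 1), u)
          pos <- pos %*% frame
          logg[m] <- logg[m] + cb$logq
        }
      }
      pos <- sweep(pos, 2, -r * u)
    }
    chains[[m]] <- pos
    U[m] <- cpp_intra_energy(pos, block, pot$contact_EO_PO, pot$well_outer)
    sm <- shape_metrics(as_conformation(pos, spec))
    po <- pos[block == 1L, , drop = FALSE]
    r_po[m] <- sqrt(sum(colMeans(po)^2))
    rg_po[m] <- sm$rg_PO
    angle[m] <- sm$angle
  }
  pr <- cpp_project_ensemble(chains, block, lattice$edges, pot$hard_core,
                             pot$well_outer, TRUE)
  structure(
    list(spec = spec, lattice = lattice, M = M, placement = placement,
         pot = pot, v_p = v_p,
         U = U, logg = logg,
         nEO = pr$count_EO, nPO = pr$count_PO,
         wEO = pr$well_EO, wPO = pr$well_PO,
         outside = pr$outside,
         r_PO = r_po, rg_PO = rg_po, angle = angle),
    class = "scmf_ensemble"
  )
}

# orientation proposal for cos(theta) between the PO->EO axis and the
# outward radial direction: mixture of uniform and (1+c)^4; returns the
# draw and log(q(c)/q_uniform)
sample_cos_bias <- function(w = 0.3, n = 4) {
  c <- if (stats::runif(1) < w) stats::runif(1, -1, 1) else
    2 * stats::rbeta(1, n + 1, 1) - 1
  q <- w / 2 + (1 - w) * (n + 1) / 2^(n + 1) * (1 + c)^n
  list(c = c, logq = log(2 * q))
}

# rotation matrix carrying unit vector a onto unit vector b
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) return(diag(c(1, -1, -1)))  # antipodal: any 180-deg
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

rotation_about_z <- function(th) {
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

#' Weighted radial density of the PO-block centres of a solved state
#'
#' @param state A [solve_scmf()] result.
#' @param bin Radial bin width (sigma).
#' @return A list with `breaks` and `dens` (density in radius, integrates
#'   to 1), used to importance-resample ensemble placements.
#' @export
radial_density <- function(state, bin = 1.0) {
  r <- state$ens$r_PO
  p <- state$p
  Rcell <- max(state$ens$lattice$edges)
  br <- seq(0, Rcell, by = bin)
  if (br[length(br)] < Rcell) br <- c(br, Rcell)
  b <- findInterval(r, br, all.inside = TRUE)
  mass <- tapply(p, factor(b, levels = seq_len(length(br) - 1L)), sum)
  mass[is.na(mass)] <- 0
  dens <- as.numeric(mass) / diff(br)
  dens <- dens / sum(dens * diff(br))
  list(breaks = br, dens = dens)
}

#' Self-consistent solve with placement resampling
#'
#' Runs [solve_scmf()] in macro-iterations: after each solve the ensemble
#' placements are importance-resampled toward the current radial density of
#' the micelle (fresh conformation shapes each round), and the fields are
#' warm-started.  This keeps the effective sample size of the weighted
#' ensemble high in strongly localized micelle states.
#'
#' @inheritParams scmf_ensemble
#' @param N Number of chains in the cell.
#' @param n_macro Macro-iterations (ensemble regenerations).
#' @param init Optional initial fields; defaults to [micelle_seed_fields()].
#' @param v_s Solvent molecular volume.
#' @param tol,max_iter,mix See [solve_scmf()].
#' @return The final [solve_scmf()] state (with the last ensemble).
#' @export
solve_scmf_macro <- function(spec, lattice, N, M = 5000L,
                             pot = pair_potential(), seed = 1L,
                             n_macro = 3L, init = NULL,
                             v_s = monomer_volume(), tol = 1e-5,
                             max_iter = 1500L, mix = 0.1) {
  ens <- scmf_ensemble(spec, lattice, M = M, placement = "biased", pot = pot,
                       seed = seed, orient_bias = TRUE)
  fi <- if (is.null(init)) micelle_seed_fields(ens, N, v_s) else init
  # concentrate the placements where the seeded fields put the chains BEFORE
  # any field update: a thinly sampled core cannot sustain the micelle
  # branch through the self-consistent iteration
  H0 <- scmf_hamiltonian(ens, fi, N, v_s)
  logw <- -H0 - ens$logg
  logw <- logw - max(logw)
  p0 <- exp(logw); p0 <- p0 / sum(p0)
  dens0 <- radial_density(list(ens = ens, p = p0))
  ens <- scmf_ensemble(spec, lattice, M = M, placement = "biased", pot = pot,
                       seed = seed + 500L, radial_density = dens0,
                       orient_bias = TRUE)
  st <- solve_scmf(ens, N, v_s = v_s, tol = tol, max_iter = max_iter,
                   mix = mix, init = fi)
  for (k in seq_len(max(0L, n_macro - 1L))) {
    dens <- radial_density(st)
    ens <- scmf_ensemble(spec, lattice, M = M, placement = "biased",
                         pot = pot, seed = seed + 1000L * k,
                         radial_density = dens, orient_bias = TRUE)
    st <- solve_scmf(ens, N, v_s = v_s, tol = tol, max_iter = max_iter,
                     mix = mix, init = st$fields)
  }
  st
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

random_rotation <- function() {
  # uniform rotation from a random quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Build an SCMF ensemble from explicitly given conformations
#'
#' Used for small enumerable systems (solver validation) and for replaying
#' stored conformations; all conformations are taken at their given
#' positions with equal sampling density.
#'
#' @param chains List of n x 3 position matrices (sigma units, cell centre
#'   at the origin).
#' @param spec A [chain_spec()] (or `NULL` with explicit `block`).
#' @param lattice A [shell_lattice()].
#' @param pot A [pair_potential()].
#' @param block Optional integer bead labels (0 = EO, 1 = PO) overriding
#'   `spec`.
#' @param v_p Monomer volume (sigma^3).
#' @param screen_intra Apply the intra-chain well screening correction?
#' @return An `scmf_ensemble`.
#' @export
manual_ensemble <- function(chains, spec, lattice, pot = pair_potential(),
                            block = NULL, v_p = monomer_volume(),
                            screen_intra = TRUE) {
  if (is.null(block)) block <- block_labels(spec)
  M <- length(chains)
  U <- vapply(chains, function(p)
    cpp_intra_energy(p, block, pot$contact_EO_PO, pot$well_outer), 0.0)
  pr <- cpp_project_ensemble(chains, block, lattice$edges, pot$hard_core,
                             pot$well_outer, screen_intra)
  r_po <- vapply(chains, function(p) {
    po <- p[block == 1L, , drop = FALSE]
    sqrt(sum(colMeans(po)^2))
  }, 0.0)
  structure(
    list(spec = spec, lattice = lattice, M = M, placement = "manual",
         pot = pot, v_p = v_p, U = U, logg = rep(0, M),
         nEO = pr$count_EO, nPO = pr$count_PO,
         wEO = pr$well_EO, wPO = pr$well_PO, outside = pr$outside,
         r_PO = r_po, rg_PO = rep(NA_real_, M), angle = rep(NA_real_, M)),
    class = "scmf_ensemble"
  )
}

#' Single-chain SCMF Hamiltonian for every ensemble member
#'
#' H(alpha) = U_intra(alpha) + interchain EO-PO mean-field coupling +
#' EO-solvent and PO-solvent couplings + incompressibility term
#' pi(r) phi(alpha, r).  The interchain term is the exact functional
#' derivative of the mean-field interaction energy, so the self-consistent
#' weights P(alpha) = exp(-H)/Z are the stationary point of the free-energy
#' functional evaluated by [scmf_free_energy()].
#'
#' @param ens An [scmf_ensemble()].
#' @param fields A field list with `CEO`, `CPO` (monomer concentrations per
#'   shell), `WEO`, `WPO` (total well volumes per shell), `cs` (solvent
#'   concentration), `pi` (incompressibility multiplier).
#' @param N Number of chains in the cell.
#' @param v_s Solvent molecular volume (sigma^3).
#' @return Numeric vector H (kBT), one entry per ensemble member.
#' @export
scmf_hamiltonian <- function(ens, fields, N, v_s = monomer_volume()) {
  pot <- ens$pot
  Vr <- ens$lattice$volumes
  q <- if (N > 0) (N - 1) / N else 0
  hcc <- q * pot$contact_EO_PO / 2 *
    (ens$wEO %*% fields$CPO + ens$nPO %*% (fields$WEO / Vr) +
     ens$wPO %*% fields$CEO + ens$nEO %*% (fields$WPO / Vr))
  hcs <- pot$contact_EO_s * (ens$wEO %*% fields$cs) +
    pot$contact_PO_s * (ens$wPO %*% fields$cs)
  hpi <- ens$v_p * ((ens$nEO + ens$nPO) %*% fields$pi)
  as.numeric(ens$U + hcc + hcs + hpi)
}

#' Self-consistent solution of the SCMF equations
#'
#' Damped Picard iteration of the fixed point: chain weights
#' P(alpha) proportional to exp(-H(alpha)) (importance-corrected for the
#' placement bias), mean concentration and interaction-volume fields from
#' the weights, solvent concentration from the incompressibility constraint
#' (the cell volume is completely filled by chains and solvent in every
#' shell), and the Lagrange multiplier field pi(r) from the solvent
#' stationarity condition (gauge: pi = 0 in the outermost shell).
#'
#' @param ens An [scmf_ensemble()].
#' @param N Number of chains in the cell (>= 1).
#' @param v_s Solvent molecular volume (sigma^3; default one bead volume).
#' @param tol Convergence tolerance on the relative field update.
#' @param max_iter Iteration budget.
#' @param mix Picard mixing parameter (0 < mix <= 1).
#' @param init Optional initial fields (e.g. a previous solve's `fields`, or
#'   [micelle_seed_fields()]).
#' @return An object of class `scmf_state`: `p` (weights, sum 1), `fields`,
#'   `F` (free energy, kBT, from [scmf_free_energy()]), `converged`,
#'   `iterations`, `residual` (final field update), `incomp_residual`
#'   (max deviation of the packing fraction from 1, nonzero only where the
#'   solvent floor clips), `N`, and the ensemble.
#' @export
solve_scmf <- function(ens, N, v_s = monomer_volume(), tol = 1e-8,
                       max_iter = 3000L, mix = 0.1, init = NULL) {
  Vr <- ens$lattice$volumes
  R <- ens$lattice$n_shells
  fields <- if (is.null(init)) {
    list(CEO = rep(0, R), CPO = rep(0, R), WEO = rep(0, R), WPO = rep(0, R),
         cs = rep(1 / v_s, R), pi = rep(0, R))
  } else init
  resid <- Inf
  p <- rep(1 / ens$M, ens$M)
  mix_eff <- mix
  d_hist <- rep(NA_real_, max_iter)
  for (it in seq_len(max_iter)) {
    H <- scmf_hamiltonian(ens, fields, N, v_s)
    logw <- -H - ens$logg
    logw <- logw - max(logw)
    p <- exp(logw)
    p <- p / sum(p)
    CEO_new <- N * as.numeric(crossprod(p, ens$nEO)) / Vr
    CPO_new <- N * as.numeric(crossprod(p, ens$nPO)) / Vr
    WEO_new <- N * as.numeric(crossprod(p, ens$wEO))
    WPO_new <- N * as.numeric(crossprod(p, ens$wPO))
    dmax <- max(abs(c(CEO_new - fields$CEO, CPO_new - fields$CPO)) /
                  max(1e-8, max(abs(c(CEO_new, CPO_new)))))
    d_hist[it] <- dmax
    # back off the mixing when the damped map limit-cycles
    if (it %% 150L == 0L && it >= 300L) {
      recent <- mean(d_hist[(it - 149L):it])
      before <- mean(d_hist[(it - 299L):(it - 150L)])
      if (recent > 0.9 * before && recent > tol) {
        mix_eff <- max(mix_eff / 2, 0.005)
      }
    }
    fields$CEO <- (1 - mix_eff) * fields$CEO + mix_eff * CEO_new
    fields$CPO <- (1 - mix_eff) * fields$CPO + mix_eff * CPO_new
    fields$WEO <- (1 - mix_eff) * fields$WEO + mix_eff * WEO_new
    fields$WPO <- (1 - mix_eff) * fields$WPO + mix_eff * WPO_new
    # projection onto the physically packable set: concentrations cannot
    # exceed close packing in any shell, otherwise the incompressibility
    # field diverges and annihilates the very states that built the overshoot
    phi_ch <- (fields$CEO + fields$CPO) * ens$v_p
    over <- phi_ch > 0.95
    if (any(over)) {
      f <- 0.95 / phi_ch[over]
      fields$CEO[over] <- fields$CEO[over] * f
      fields$CPO[over] <- fields$CPO[over] * f
      fields$WEO[over] <- fields$WEO[over] * f
      fields$WPO[over] <- fields$WPO[over] * f
    }
    phis <- pmax(1e-12, 1 - (fields$CEO + fields$CPO) * ens$v_p)
    fields$cs <- phis / v_s
    hs <- (ens$pot$contact_EO_s * fields$WEO +
             ens$pot$contact_PO_s * fields$WPO) / Vr
    fields$pi <- -(log(phis) + hs) / v_s
    fields$pi <- fields$pi - fields$pi[R]
    resid <- dmax
    if (dmax < tol) break
  }
  phi_tot <- (fields$CEO + fields$CPO) * ens$v_p + fields$cs * v_s
  structure(
    list(p = p, fields = fields,
         F = scmf_free_energy(ens, N, p, fields, v_s),
         converged = resid < tol,
         iterations = it, residual = resid,
         incomp_residual = max(abs(phi_tot - 1)),
         N = N, v_s = v_s, ens = ens),
    class = "scmf_state"
  )
}

#' Free energy of an SCMF state
#'
#' Evaluates the mean-field free-energy functional (kBT): exact
#' intramolecular energy, mean-field interchain and chain-solvent energies,
#' chain configurational entropy N sum P log P (with the importance-sampling
#' measure referenced to one solvent site), and the solvent translational
#' entropy.
#'
#' @param ens An [scmf_ensemble()].
#' @param N Number of chains.
#' @param p Normalized chain weights.
#' @param fields Field list (see [scmf_hamiltonian()]).
#' @param v_s Solvent molecular volume.
#' @return Free energy (kBT).
#' @export
scmf_free_energy <- function(ens, N, p, fields, v_s = monomer_volume()) {
  if (abs(sum(p) - 1) > 1e-8) stop("weights are not normalized")
  pot <- ens$pot
  Vr <- ens$lattice$volumes
  q <- if (N > 0) (N - 1) / N else 0
  e_intra <- N * sum(p * ens$U)
  e_cc <- q * pot$contact_EO_PO / 2 *
    sum(fields$WEO * fields$CPO + fields$WPO * fields$CEO)
  e_cs <- sum((pot$contact_EO_s * fields$WEO +
                 pot$contact_PO_s * fields$WPO) * fields$cs)
  pos <- p > 0
  # per-chain configurational/translational entropy plus the chain
  # indistinguishability term (the solvent term below carries its own
  # Stirling factor through c_s (log(c_s v_s) - 1))
  s_chain <- N * (sum(p[pos] * (log(p[pos]) + ens$logg[pos])) + log(ens$M)) +
    lgamma(N + 1)
  s_solv <- sum(Vr * fields$cs * (log(fields$cs * v_s) - 1))
  e_intra + e_cc + e_cs + s_chain + s_solv
}

#' Radial field profile of a converged state
#'
#' @param state An [solve_scmf()] result.
#' @return A tibble: `shell`, `r_mid`, `c_EO`, `c_PO`, `c_s`, `pi`,
#'   `phi_total` (packing fraction, 1 at convergence).
#' @export
field_profile <- function(state) {
  f <- state$fields
  lat <- state$ens$lattice
  tibble::tibble(
    shell = seq_len(lat$n_shells), r_mid = lat$r_mid,
    c_EO = f$CEO, c_PO = f$CPO, c_s = f$cs, pi = f$pi,
    phi_total = (f$CEO + f$CPO) * state$ens$v_p + f$cs * state$v_s
  )
}

#' Micelle-seeded initial fields
#'
#' A dense PO core of radius set by the aggregation number plus an EO corona
#' ring; used to start the Picard iteration on the micelle branch.
#'
#' @param ens An [scmf_ensemble()].
#' @param N Aggregation number.
#' @param v_s Solvent molecular volume.
#' @return A field list suitable for `solve_scmf(init = )`.
#' @export
micelle_seed_fields <- function(ens, N, v_s = monomer_volume()) {
  spec <- ens$spec
  lat <- ens$lattice
  v_p <- ens$v_p
  r_core <- (3 * N * spec$n_PO * v_p / (4 * pi * 0.85))^(1 / 3)
  vwell <- 4 / 3 * pi * (ens$pot$well_outer^3 - 1)
  CPO <- ifelse(lat$r_mid < r_core, 0.85 / v_p, 0)
  CEO <- ifelse(lat$r_mid >= r_core & lat$r_mid < r_core + 3, 0.3 / v_p, 0)
  fields <- list(CEO = CEO, CPO = CPO,
                 WEO = CEO * lat$volumes * vwell,
                 WPO = CPO * lat$volumes * vwell,
                 cs = rep(1 / v_s, lat$n_shells),
                 pi = rep(0, lat$n_shells))
  phis <- pmax(1e-12, 1 - (CEO + CPO) * v_p)
  fields$cs <- phis / v_s
  hs <- (ens$pot$contact_EO_s * fields$WEO +
           ens$pot$contact_PO_s * fields$WPO) / lat$volumes
  fields$pi <- -(log(phis) + hs) / v_s
  fields$pi <- fields$pi - fields$pi[lat$n_shells]
  fields
}

#' Micellization scan over aggregation numbers
#'
#' For each aggregation number N, solves the SCMF equations with the micelle
#' pinned at the cell centre and computes the standard chemical-potential
#' difference per chain,
#' \deqn{\Delta\mu_N^0 = [F_{cell}(N) - F_{cell}(0)]/N - \mu_1^0,}
#' with \eqn{\mu_1^0} from a single-chain solve (centre-of-mass pinned, no
#' translational entropy: mole-fraction standard state) and
#' \eqn{F_{cell}(0) = -V/v_s} the pure-solvent cell.  The preferred
#' aggregation number N* is the interior minimum (smallest N within 0.01 kBT
#' of the minimum) and the critical micelle concentration follows as
#' CMC = exp(min Delta mu) x 55.5 mol/L.
#'
#' @param spec A [chain_spec()].
#' @param pot A [pair_potential()].
#' @param N_range Integer vector of aggregation numbers to scan.
#' @param lattice A [shell_lattice()].
#' @param M Ensemble size per solve.
#' @param seed Integer seed for conformation sampling.
#' @param v_s Solvent molecular volume (sigma^3).
#' @param mix,max_iter,tol Solver controls (see [solve_scmf()]).
#' @param M_single Ensemble size of the single-chain reference solve.
#' @return An object of class `micellization_scan`: `scan` (tibble: N,
#'   delta_mu, converged), `N_star`, `min_delta_mu`, `cmc_mol_L`,
#'   `micellized` (FALSE when no interior minimum exists), `mu1`, `seed`.
#' @export
micellization_scan <- function(spec, pot = pair_potential(),
                               N_range = c(30L, 60L, 91L, 145L, 200L, 260L,
                                           320L, 400L),
                               lattice = shell_lattice(28L),
                               M = 5000L, seed = 1L,
                               v_s = monomer_volume(), mix = 0.1,
                               max_iter = 1500L, tol = 1e-5,
                               M_single = 2000L, n_macro = 3L) {
  N_range <- sort(unique(as.integer(N_range)))
  ens1 <- scmf_ensemble(spec, lattice, M = M_single, placement = "pinned",
                        pot = pot, seed = seed + 1L)
  st1 <- solve_scmf(ens1, N = 1L, v_s = v_s, tol = tol,
                    max_iter = max_iter, mix = mix)
  F0 <- -lattice$V / v_s
  mu1 <- st1$F - F0
  delta_mu <- rep(NA_real_, length(N_range))
  conv <- micelle <- logical(length(N_range))
  ess <- numeric(length(N_range))
  init <- NULL
  for (i in seq_along(N_range)) {
    N <- N_range[i]
    st <- solve_scmf_macro(spec, lattice, N = N, M = M, pot = pot,
                           seed = seed, n_macro = n_macro,
                           init = init, v_s = v_s, tol = tol,
                           max_iter = max_iter, mix = mix)
    delta_mu[i] <- (st$F - F0) / N - mu1
    conv[i] <- st$converged
    ess[i] <- 1 / sum(st$p^2)
    # micelle-branch detection: the solve holds a dense hydrophobic core
    # (small aggregation numbers melt back to the dispersed branch, whose
    # cell-size-dependent translational free energy is not a mu_N^0)
    micelle[i] <- max(st$fields$CPO) * ens_vp(st) > 0.3
    init <- if (micelle[i]) st$fields else NULL
  }
  on_branch <- which(micelle & is.finite(delta_mu))
  N_star <- min_dm <- cmc <- NA_real_
  interior <- FALSE
  micellized <- length(on_branch) > 0
  if (micellized) {
    imin <- on_branch[which.min(delta_mu[on_branch])]
    near <- on_branch[delta_mu[on_branch] <= delta_mu[imin] + 0.01]
    N_star <- N_range[min(near)]
    min_dm <- delta_mu[imin]
    cmc <- exp(min_dm) * 55.5
    interior <- imin > min(on_branch) && imin < max(on_branch)
  }
  structure(
    list(scan = tibble::tibble(N = N_range, delta_mu = delta_mu,
                               converged = conv, micelle = micelle,
                               ess = ess),
         N_star = N_star, min_delta_mu = min_dm, cmc_mol_L = cmc,
         micellized = micellized, interior_minimum = interior,
         mu1 = mu1, seed = seed, spec = spec),
    class = "micellization_scan"
  )
}

ens_vp <- function(st) st$ens$v_p

#' @export
print.micellization_scan <- function(x, ...) {
  cat("SCMF micellization scan\n")
  print(x$scan, n = Inf)
  if (x$micellized) {
    cat(sprintf("N* = %d, min delta-mu = %.3f kBT, CMC = %.3g mol/L%s\n",
                x$N_star, x$min_delta_mu, x$cmc_mol_L,
                if (!x$interior_minimum) " (minimum at the scanned-branch edge)"
                else ""))
  } else {
    cat("no micellization: no aggregation number holds a micelle\n")
  }
  invisible(x)
}

#' @rdname tidy.eyring_fit
#' @export
tidy.micellization_scan <- function(x, ...) x$scan

#' @rdname glance.eyring_fit
#' @export
glance.micellization_scan <- function(x, ...) {
  tibble::tibble(N_star = x$N_star, min_delta_mu = x$min_delta_mu,
                 cmc_mol_L = x$cmc_mol_L, micellized = x$micellized,
                 interior_minimum = x$interior_minimum)
}
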