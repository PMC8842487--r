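# Independent oracles used across the suite.

# High-accuracy numerical integration of the kinetic ODE in the bounded
# variable z = log w = -F/eps (dz/dt = (k1/eps)(e^-z - e^z) + k2/eps),
# independent of the closed-form evaluation path.
eyring_ode_oracle <- function(t, p, rtol = 1e-11, atol = 1e-12) {
  rhs <- function(tt, y, parms) {
    list((p$k1 / p$eps) * (exp(-y[1]) - exp(y[1])) + p$k2 / p$eps)
  }
  out <- deSolve::ode(c(z = -1 / p$eps), times = c(0, t), rhs, NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 200000)
  -p$eps * out[-1, "z"]
}

# log-spaced time grid covering both characteristic scales of a parameter set
eyring_time_grid <- function(p, n = 60) {
  lo <- min(p$tau1, p$tau2) / 100
  hi <- 20 * max(p$tau1, p$tau2)
  10^seq(log10(lo), log10(hi), length.out = n)
}

# brute-force intramolecular energy: plain double loop in R
intra_energy_bruteforce <- function(pos, block, contact, rc) {
  n <- nrow(pos)
  e <- 0
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d < 1 - 1e-9) return(Inf)
      if (d <= rc && block[i] != block[j]) e <- e + contact
    }
  }
  e
}

# conformation object from a bare coordinate matrix (test fixtures)
make_conformation <- function(pos, block) {
  structure(as.matrix(pos), block = as.integer(block),
            class = c("conformation", "matrix", "array"))
}

# direct minimization of the SCMF free-energy functional over softmax
# weights (independent route to the fixed point)
scmf_direct_minimum <- function(ens, N, v_s = monomer_volume(),
                                maxit = 4000) {
  Vr <- ens$lattice$volumes
  obj <- function(theta) {
    p <- exp(theta - max(theta))
    p <- p / sum(p)
    fields <- list(
      CEO = N * as.numeric(crossprod(p, ens$nEO)) / Vr,
      CPO = N * as.numeric(crossprod(p, ens$nPO)) / Vr,
      WEO = N * as.numeric(crossprod(p, ens$wEO)),
      WPO = N * as.numeric(crossprod(p, ens$wPO)))
    phis <- pmax(1e-12, 1 - (fields$CEO + fields$CPO) * ens$v_p)
    fields$cs <- phis / v_s
    fields$pi <- rep(0, ens$lattice$n_shells)
    scmf_free_energy(ens, N, p, fields, v_s)
  }
  o <- stats::optim(rep(0, ens$M), obj, method = "BFGS",
                    control = list(maxit = maxit, reltol = 1e-14))
  p <- exp(o$par - max(o$par))
  list(F = o$value, p = p / sum(p))
}
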