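#' Modified Eyring kinetic model for micelle chain-exchange relaxation
#'
#' Three-parameter kinetic model for the tagged-chain exchange correlation
#' function F(t) of copolymer micelles,
#' \deqn{\frac{dF}{dt} = -k_1 e^{F/\epsilon} + k_1 e^{-F/\epsilon} - k_2,}
#' with `eps` a dimensionless crossover value of the correlation function,
#' `k1` (1/s) the kinetic constant of the initial and logarithmic-intermediate
#' regimes and `k2` (1/s) the kinetic constant governing the crossover to the
#' final exponential regime.  Note the units convention: `k1` carries units of
#' 1/s although it always appears multiplied by the large factor
#' \eqn{e^{1/\epsilon}}; the physically relevant initial rate is
#' \eqn{k_1 e^{1/\epsilon}}.
#'
#' In the variable \eqn{y \equiv e^{F/\epsilon}} the model is a constant
#' coefficient Riccati equation \eqn{\epsilon \dot y = -k_1 y^2 - k_2 y + k_1},
#' which admits a closed-form solution (see [eyring_solution()]) and, after
#' the rescaling \eqn{t = a t^*}, \eqn{\tilde y = b y^*} with \eqn{a =
#' \epsilon/k_2} and \eqn{b = e^{-1/\epsilon}/\gamma}, collapses onto the
#' parameter-free master equation \eqn{dy^*/dt^* = -y^{*2} - y^*} (plus a
#' correction \eqn{\gamma^2} that only matters near the stationary state).
#'
#' @param eps Dimensionless crossover value (> 0, typically ~1e-2).
#' @param k1 Kinetic constant of the initial/intermediate regimes (1/s).
#' @param k2 Kinetic constant of the final exponential regime (1/s).
#'
#' @return An object of class `eyring_params`: a list with fields `eps`,
#'   `k1`, `k2` plus the derived quantities `gamma` (= k1/k2), `tau1`
#'   (= (eps/k1) exp(-1/eps), onset of the logarithmic regime, s), `tau2`
#'   (terminal relaxation time, s), the master-transform scale factors
#'   `a` (= eps/k2, s) and `b` (= exp(-1/eps)/gamma), and the dynamic
#'   `class` label: `"a"` for gamma > 1, `"b"` for gamma < 1, `"boundary"`
#'   at gamma == 1.
#'
#' @examples
#' p <- eyring_params(eps = 2.6e-2, k1 = 1.0e-8, k2 = 6.8e5)
#' p$gamma   # ~1.5e-14, type b
#' p$tau1    # ~5e-11 s
#' @export
eyring_params <- function(eps, k1, k2) {
  stopifnot(is.numeric(eps), is.numeric(k1), is.numeric(k2),
            length(eps) == 1L, length(k1) == 1L, length(k2) == 1L)
  if (!is.finite(eps) || eps <= 0) stop("`eps` must be a positive finite number")
  if (!is.finite(k1) || k1 <= 0) stop("`k1` must be a positive finite number")
  if (!is.finite(k2) || k2 <= 0) stop("`k2` must be a positive finite number")
  gamma <- k1 / k2
  cls <- if (gamma > 1) "a" else if (gamma < 1) "b" else "boundary"
  if (identical(cls, "boundary")) {
    warning("gamma = k1/k2 is exactly 1: boundary between type-a and type-b dynamics")
  }
  structure(
    list(
      eps = eps, k1 = k1, k2 = k2,
      gamma = gamma,
      tau1 = (eps / k1) * exp(-1 / eps),
      tau2 = eps / (k2 * sqrt(1 + 4 * gamma^2)),
      a = eps / k2,
      b = exp(-1 / eps) / gamma,
      class = cls
    ),
    class = "eyring_params"
  )
}

#' @export
print.eyring_params <- function(x, ...) {
  cat("Modified Eyring parameters\n")
  cat(sprintf("  eps   = %.4g\n  k1    = %.4g 1/s\n  k2    = %.4g 1/s\n",
              x$eps, x$k1, x$k2))
  cat(sprintf("  gamma = %.4g  (type %s)\n  tau1  = %.4g s\n  tau2  = %.4g s\n",
              x$gamma, x$class, x$tau1, x$tau2))
  invisible(x)
}

as_eyring_params <- function(p) {
  if (inherits(p, "eyring_params")) return(p)
  if (is.numeric(p) && length(p) == 3L) {
    return(eyring_params(p[[1]], p[[2]], p[[3]]))
  }
  if (is.list(p) && all(c("eps", "k1", "k2") %in% names(p))) {
    return(eyring_params(p$eps, p$k1, p$k2))
  }
  stop("cannot interpret `p` as Eyring parameters (need eps, k1, k2)")
}

# Roots of the Riccati equation in w = exp(-F/eps):
#   dw/dt = -(k1/eps) (w - wp)(w - wm),   wp > 0 > wm,
# computed without cancellation (wm via the conjugate form).
eyring_roots <- function(p) {
  delta <- sqrt(p$k2^2 + 4 * p$k1^2)
  list(
    wp = (p$k2 + delta) / (2 * p$k1),
    wm = -2 * p$k1 / (p$k2 + delta),
    lambda = delta / p$eps
  )
}

#' Right-hand side of the modified Eyring equation
#'
#' Evaluates dF/dt = -k1 exp(F/eps) + k1 exp(-F/eps) - k2 (units 1/s).
#'
#' @param F Dimensionless correlation-function value(s).
#' @param p An [eyring_params()] object (or coercible).
#' @return dF/dt, same length as `F`.
#' @export
eyring_rhs <- function(F, p) {
  p <- as_eyring_params(p)
  -p$k1 * exp(F / p$eps) + p$k1 * exp(-F / p$eps) - p$k2
}

#' Closed-form solution of the modified Eyring equation
#'
#' Exact solution of the model with initial condition F(0) = 1, evaluated in
#' the overflow-safe variable w = exp(-F/eps).  With wp, wm the positive and
#' negative roots of k1 w^2 - k2 w - k1 and lambda = sqrt(k2^2 + 4 k1^2)/eps,
#' \deqn{w(t) = \frac{w_p w_0 + |w_m| w_p (1 - e^{-\lambda t}) + |w_m| w_0
#'   e^{-\lambda t}}{(w_0 + |w_m|)(1 + \rho e^{-\lambda t})},\quad
#'   \rho = \frac{w_p - w_0}{w_0 + |w_m|},}
#' with w0 = exp(-1/eps); every term is positive so the expression is stable
#' across the full parameter range, and F(t) = -eps log w(t).
#'
#' @param t Time grid (s), non-negative.
#' @param p An [eyring_params()] object (or coercible).
#' @return Numeric vector F(t); F(0) = 1 exactly.
#' @export
eyring_solution <- function(t, p) {
  p <- as_eyring_params(p)
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0))
  r <- eyring_roots(p)
  w0 <- exp(-1 / p$eps)
  m <- -r$wm                       # |wm| > 0
  E <- exp(-r$lambda * t)
  one_minus_E <- -expm1(-r$lambda * t)
  rho <- (r$wp - w0) / (w0 + m)
  w <- (r$wp * w0 + m * r$wp * one_minus_E + m * w0 * E) /
    ((w0 + m) * (1 + rho * E))
  out <- -p$eps * log(w)
  out[t == 0] <- 1   # exact initial condition
  out
}

#' Correlation curve from the modified Eyring model
#'
#' Convenience wrapper returning a tidy two-column curve.
#'
#' @inheritParams eyring_solution
#' @return A tibble with columns `time_s` and `F`.
#' @export
eyring_curve <- function(t, p) {
  tibble::tibble(time_s = t, F = eyring_solution(t, p))
}

#' Asymptotic regime approximants of the modified Eyring model
#'
#' Returns a function F(t) approximating the exact solution in one of the
#' model's asymptotic regimes:
#' \describe{
#'   \item{`"logarithmic"`}{F(t) = -eps log(exp(-1/eps) + k1 t/eps); exact for
#'     k2 = 0, valid from the initial plateau through the logarithmic decay
#'     (tau1 << t << crossover).}
#'   \item{`"terminal"`}{type-a (gamma > 1) terminal exponential approach to
#'     the stationary state with time scale tau2 = eps/(2 k1).}
#'   \item{`"second_intermediate"`}{type-b (gamma < 1) pure exponential of the
#'     universal second intermediate regime, y* ~ C exp(-t*), valid t* >~ 1.}
#'   \item{`"matched"`}{type-b globally matched form
#'     F(t) = eps [ -t* - log(u + 1 - e^{-t*}) - log gamma ],
#'     u = exp(-1/eps)/gamma, t* = t k2/eps; reduces to the logarithmic
#'     approximant for t* << 1 and to the second intermediate exponential for
#'     t* >~ 1; global error O(gamma^2) for gamma << 1.}
#' }
#'
#' @param p An [eyring_params()] object (or coercible).
#' @param regime One of `"logarithmic"`, `"terminal"`,
#'   `"second_intermediate"`, `"matched"`.
#' @return A function of `t` (seconds) returning approximate F(t).
#' @export
eyring_asymptotic <- function(p, regime = c("logarithmic", "terminal",
                                            "second_intermediate", "matched")) {
  p <- as_eyring_params(p)
  regime <- match.arg(regime)
  eps <- p$eps; k1 <- p$k1; k2 <- p$k2; gamma <- p$gamma
  switch(regime,
    logarithmic = function(t) {
      -eps * log(exp(-1 / eps) + k1 * t / eps)
    },
    terminal = {
      if (gamma <= 1) {
        stop("terminal-exponential asymptotics require type-a dynamics (gamma > 1); ",
             sprintf("gamma = %.3g", gamma))
      }
      # reduced equation dy*/dt* = -(y*^2 - gamma^2), stationary y* = gamma,
      # relaxation time tau2a = eps/(2 k1)
      tau2a <- eps / (2 * k1)
      ystar0 <- gamma * exp(1 / eps)
      d <- 2 * gamma / (ystar0 + gamma)       # 1 - R_a
      function(t) {
        E <- exp(-t / tau2a)
        one_minus_E <- -expm1(-t / tau2a)
        # log(y*/gamma) = log(1 + (1-d) E) - log(d E + (1 - E))
        eps * (log1p((1 - d) * E) - log(d * E + one_minus_E))
      }
    },
    second_intermediate = {
      if (gamma >= 1) {
        stop("second-intermediate asymptotics require type-b dynamics (gamma < 1); ",
             sprintf("gamma = %.3g", gamma))
      }
      u <- exp(-1 / eps) / gamma
      logC <- -log1p(u)
      function(t) {
        tstar <- t * k2 / eps
        eps * (logC - tstar - log(gamma))
      }
    },
    matched = {
      if (gamma >= 1) {
        stop("the matched form applies to type-b dynamics (gamma < 1); ",
             sprintf("gamma = %.3g", gamma))
      }
      u <- exp(-1 / eps) / gamma
      function(t) {
        tstar <- t * k2 / eps
        eps * (-tstar - log(u - expm1(-tstar)) - log(gamma))
      }
    }
  )
}

#' Master-curve scaling transform
#'
#' Maps a correlation curve (t, F) onto the dimensionless master coordinates
#' \eqn{t^* = t/a} and \eqn{y^* = \gamma e^{F/\epsilon}} (equivalently
#' \eqn{y^* = \tilde y / b} with \eqn{\tilde y = e^{(F-1)/\epsilon}},
#' \eqn{a = \epsilon/k_2}, \eqn{b = e^{-1/\epsilon}/\gamma}).  In these
#' coordinates every type-b parameter set follows the same master curve up to
#' the crossover at \eqn{t^* \sim 1}, with log-log slope -1 in the
#' intermediate window.
#'
#' @param curve A data frame with columns `time_s` and `F`.
#' @param p An [eyring_params()] object (or coercible).
#' @return A tibble with columns `t_star`, `log_y_star` and `y_star`
#'   (`y_star = exp(log_y_star)`, may overflow to `Inf` for extreme
#'   parameters; the log column is always finite).
#' @export
scale_transform <- function(curve, p) {
  p <- as_eyring_params(p)
  stopifnot(is.data.frame(curve), all(c("time_s", "F") %in% names(curve)))
  log_y_star <- curve$F / p$eps + log(p$gamma)
  tibble::tibble(
    t_star = curve$time_s / p$a,
    log_y_star = log_y_star,
    y_star = exp(log_y_star)
  )
}

#' Inverse of the master-curve scaling transform
#'
#' @param scaled A data frame with columns `t_star` and `log_y_star`
#'   (as produced by [scale_transform()]).
#' @param p An [eyring_params()] object (or coercible).
#' @return A tibble with columns `time_s` and `F`; round-trips
#'   [scale_transform()] to machine precision.
#' @export
unscale_transform <- function(scaled, p) {
  p <- as_eyring_params(p)
  stopifnot(is.data.frame(scaled), all(c("t_star", "log_y_star") %in% names(scaled)))
  tibble::tibble(
    time_s = scaled$t_star * p$a,
    F = p$eps * (scaled$log_y_star - log(p$gamma))
  )
}
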