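#' Fit the modified Eyring model to a relaxation curve
#'
#' Nonlinear least squares of the closed-form solution [eyring_solution()] to
#' a correlation curve F(t).  Residuals are taken in F on points resampled
#' uniformly in log time (the information content of relaxation data is
#' spread per decade, and the y = exp(F/eps) variable would amplify noise by
#' exp(F/eps)).  Positivity of all three parameters is enforced by fitting in
#' log-parameter space, with a deterministic initialization heuristic plus
#' multi-start jitter.
#'
#' @param curve A data frame with columns `time_s` (strictly increasing, > 0)
#'   and `F`.  At least 10 points spanning at least 2 decades in time.
#' @param init Optional [eyring_params()] starting values; `NULL` uses the
#'   built-in heuristic (local lin-log slope for eps, plateau-departure time
#'   for k1, data span for k2).
#' @param n_resample Number of points of the uniform-in-log-time resampling
#'   grid used for fitting.
#' @param n_start Number of multi-starts (first start is the heuristic or
#'   `init`, the rest are jittered from it).
#' @param seed Integer seed for the multi-start jitter (deterministic fits).
#'
#' @return An object of class `eyring_fit`: list with `params`
#'   ([eyring_params()], including gamma/tau1/tau2), `r2`, `fitted`
#'   (tibble of the resampled points, fitted values, residuals), `data`
#'   (the original curve), `k2_reliable` (FALSE when the data never leave the
#'   logarithmic window, t*max < 0.1, so k2 is not constrained), `class`
#'   (dynamic class "a"/"b"), `vcov_log` (covariance of the log-parameters),
#'   `convergence` diagnostics.
#' @seealso [tidy.eyring_fit()], [glance.eyring_fit()], [autoplot.eyring_fit()]
#' @export
eyring_fit <- function(curve, init = NULL, n_resample = 200L, n_start = 8L,
                       seed = 1L) {
  stopifnot(is.data.frame(curve), all(c("time_s", "F") %in% names(curve)))
  t <- curve$time_s
  F <- curve$F
  ok <- is.finite(t) & is.finite(F) & t > 0
  t <- t[ok]; F <- F[ok]
  if (length(t) < 10L) stop("need at least 10 finite points with t > 0")
  if (is.unsorted(t, strictly = TRUE)) stop("`time_s` must be strictly increasing")
  if (log10(max(t) / min(t)) < 2) stop("data must span at least 2 decades in time")
  if (diff(range(F)) < 1e-3) stop("curve is flat/constant; nothing to fit")

  # uniform-in-log-time resampling
  lg <- seq(log(min(t)), log(max(t)), length.out = n_resample)
  tg <- exp(lg)
  Fg <- stats::approx(log(t), F, xout = lg, rule = 2)$y

  resid_fun <- function(logpar) {
    p <- eyring_params(exp(logpar[1]), exp(logpar[2]), exp(logpar[3]))
    eyring_solution(tg, p) - Fg
  }

  start0 <- if (is.null(init)) {
    eyring_init_heuristic(tg, Fg)
  } else {
    p0 <- as_eyring_params(init)
    c(log(p0$eps), log(p0$k1), log(p0$k2))
  }

  starts <- list(start0)
  jitter_rng <- local({
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    draws <- matrix(stats::rnorm(3L * max(0L, n_start - 1L), 0,
                                 rep(c(0.3, 1.5, 1.5), max(0L, n_start - 1L))),
                    ncol = 3L, byrow = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
    draws
  })
  for (i in seq_len(max(0L, n_start - 1L))) {
    starts[[i + 1L]] <- start0 + jitter_rng[i, ]
  }

  best <- NULL
  best_ss <- Inf
  convergence <- list()
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.finite(ss) && ss < best_ss) {
      best <- fit
      best_ss <- ss
    }
  }
  if (is.null(best)) stop("Eyring fit failed to converge from any start")

  logpar <- best$par
  params <- eyring_params(exp(logpar[1]), exp(logpar[2]), exp(logpar[3]))
  fitted_vals <- eyring_solution(tg, params)
  ss_res <- sum((Fg - fitted_vals)^2)
  ss_tot <- sum((Fg - mean(Fg))^2)
  r2 <- 1 - ss_res / ss_tot

  vcov_log <- tryCatch({
    h <- best$hessian
    s2 <- ss_res / max(1L, length(Fg) - 3L)
    s2 * solve(h)
  }, error = function(e) matrix(NA_real_, 3, 3))

  structure(
    list(
      params = params,
      r2 = r2,
      fitted = tibble::tibble(time_s = tg, F = Fg, F_fit = fitted_vals,
                              resid = Fg - fitted_vals),
      data = tibble::as_tibble(curve),
      k2_reliable = max(t) / params$a >= 0.1,
      class = params$class,
      vcov_log = vcov_log,
      convergence = list(info = best$info, message = best$message,
                         deviance = best_ss, n_starts = length(starts))
    ),
    class = "eyring_fit"
  )
}

# eps from the straightest lin-log window, k1 from the plateau-departure time
# via tau1 = (eps/k1) exp(-1/eps), k2 from assuming the crossover sits near the
# end of the data (t*max ~ 1).
eyring_init_heuristic <- function(tg, Fg) {
  lg <- log(tg)
  n <- length(tg)
  win <- max(10L, floor(n / 5))
  slopes <- rep(NA_real_, n - win)
  for (i in seq_len(n - win)) {
    idx <- i:(i + win)
    slopes[i] <- stats::coef(stats::lm.fit(cbind(1, lg[idx]), Fg[idx]))[2]
  }
  # straightest negative-slope window: slope most locally constant
  dd <- abs(diff(slopes))
  roll <- stats::filter(dd, rep(1, 5), sides = 2)
  cand <- which(slopes[-length(slopes)] < 0)
  pick <- if (length(cand)) cand[which.min(roll[cand])] else which.min(slopes)
  if (is.na(pick) || !length(pick)) pick <- which.min(slopes)
  eps0 <- min(0.5, max(1e-3, -slopes[pick], na.rm = TRUE))
  Ftop <- stats::quantile(Fg, 0.98, names = FALSE)
  dep <- which(Fg < Ftop - 2 * eps0)
  t_dep <- if (length(dep)) tg[dep[1]] else tg[ceiling(n / 4)]
  k10 <- eps0 / t_dep * exp(-1 / eps0)
  k20 <- eps0 / max(tg)
  c(log(eps0), log(k10), log(k20))
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat("Modified Eyring fit\n")
  print(x$params)
  cat(sprintf("  R^2 = %.5f  (class %s%s)\n", x$r2, x$class,
              if (!x$k2_reliable) ", k2 not reliable: data never leave the logarithmic window" else ""))
  invisible(x)
}

#' Tidy an Eyring fit
#'
#' @param x An [eyring_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per quantity (`eps`, `k1`, `k2`, `gamma`,
#'   `tau1`, `tau2`) and columns `term`, `estimate`.
#' @export
tidy.eyring_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("eps", "k1", "k2", "gamma", "tau1", "tau2"),
    estimate = c(p$eps, p$k1, p$k2, p$gamma, p$tau1, p$tau2)
  )
}

#' One-row summary of an Eyring fit
#'
#' @param x An [eyring_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `n`, `class`, `gamma`,
#'   `k2_reliable`, `deviance`.
#' @export
glance.eyring_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2,
    n = nrow(x$data),
    class = x$class,
    gamma = x$params$gamma,
    k2_reliable = x$k2_reliable,
    deviance = x$convergence$deviance
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Classify fitted curves and overlay them on the master curve
#'
#' Labels each fitted relaxation curve type a (gamma > 1) or type b
#' (gamma < 1), flags unreliable k2 estimates (curves that never leave the
#' logarithmic window, max t* < 0.1), and emits all curves in the master
#' coordinates (t*, y*) for joint plotting.
#'
#' @param fits A list of [eyring_fit()] objects, or a list of lists with
#'   elements `curve` (data frame `time_s`, `F`) and `params`.
#' @param ids Optional character vector of curve labels.
#' @return A list with `classification` (tibble: id, class, gamma, eps, k1,
#'   k2, k2_reliable) and `scaled` (tibble: id, t_star, log_y_star, y_star).
#' @export
classify_and_collapse <- function(fits, ids = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (is.null(ids)) ids <- paste0("curve", seq_along(fits))
  stopifnot(length(ids) == length(fits))
  rows <- vector("list", length(fits))
  scaled <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (inherits(f, "eyring_fit")) {
      curve <- f$data
      p <- f$params
      rel <- f$k2_reliable
    } else {
      curve <- f$curve
      p <- as_eyring_params(f$params)
      rel <- max(curve$time_s) / p$a >= 0.1
    }
    rows[[i]] <- tibble::tibble(
      id = ids[i], class = p$class, gamma = p$gamma,
      eps = p$eps, k1 = p$k1, k2 = p$k2, k2_reliable = rel
    )
    sc <- scale_transform(curve, p)
    sc$id <- ids[i]
    scaled[[i]] <- sc[, c("id", "t_star", "log_y_star", "y_star")]
  }
  list(
    classification = dplyr::bind_rows(rows),
    scaled = dplyr::bind_rows(scaled)
  )
}
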