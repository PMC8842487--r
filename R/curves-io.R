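#' Read a relaxation curve from a two-column TSV file
#'
#' Accepts the seconds-domain format (header `time_s<TAB>F`) or the
#' cycles-domain format (header `time_cycles<TAB>F`); for the latter a
#' calibration sidecar (JSON with field `t_cycle_s`, written by
#' [write_curve()]) converts cycles to seconds.
#'
#' @param path Path to the TSV file.
#' @param sidecar Optional path to the calibration sidecar JSON; defaults to
#'   `<path>.calibration.json` when the file is in the cycles domain.
#' @return A tibble with columns `time_s` and `F` (plus `time_cycles` when
#'   read from a cycles-domain file).
#' @export
read_curve <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty curve file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!(identical(header[1:2], c("time_s", "F")) ||
        identical(header[1:2], c("time_cycles", "F")))) {
    stop("unrecognized header in ", path,
         ": expected 'time_s\\tF' or 'time_cycles\\tF'")
  }
  cycles_domain <- identical(header[1], "time_cycles")
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad_ncol <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad_ncol)) {
    stop("malformed row (need 2 tab-separated columns) at line ",
         bad_ncol[1] + 1L, " of ", path)
  }
  tv <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  Fv <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad_num <- which(!is.finite(tv) | !is.finite(Fv))
  if (length(bad_num)) {
    stop("non-numeric cell at line ", bad_num[1] + 1L, " of ", path)
  }
  non_mono <- which(diff(tv) <= 0)
  if (length(non_mono)) {
    stop("times not strictly increasing at line ", non_mono[1] + 2L,
         " of ", path)
  }
  if (cycles_domain) {
    if (is.null(sidecar)) sidecar <- paste0(path, ".calibration.json")
    if (!file.exists(sidecar)) {
      stop("cycles-domain curve needs a calibration sidecar (t_cycle_s): ",
           sidecar, " not found")
    }
    cal <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(cal$t_cycle_s) || !is.finite(cal$t_cycle_s) || cal$t_cycle_s <= 0) {
      stop("invalid calibration sidecar (need positive t_cycle_s): ", sidecar)
    }
    tibble::tibble(time_cycles = tv, time_s = tv * cal$t_cycle_s, F = Fv)
  } else {
    tibble::tibble(time_s = tv, F = Fv)
  }
}

#' Write a relaxation curve to a two-column TSV file
#'
#' @param curve A data frame with columns `time_s` and `F`, or `time_cycles`
#'   and `F` for the cycles domain.
#' @param path Output path.
#' @param t_cycle_s Optional seconds-per-cycle calibration; when the curve is
#'   in the cycles domain this is written to the sidecar
#'   `<path>.calibration.json`.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, t_cycle_s = NULL) {
  stopifnot(is.data.frame(curve), "F" %in% names(curve))
  if ("time_s" %in% names(curve)) {
    df <- data.frame(time_s = curve$time_s, F = curve$F)
  } else if ("time_cycles" %in% names(curve)) {
    df <- data.frame(time_cycles = curve$time_cycles, F = curve$F)
    if (!is.null(t_cycle_s)) {
      jsonlite::write_json(list(t_cycle_s = t_cycle_s),
                           paste0(path, ".calibration.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  } else {
    stop("curve must have a `time_s` or `time_cycles` column")
  }
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate synthetic Eyring relaxation curves
#'
#' Samples the closed-form solution [eyring_solution()] on a log-uniform time
#' grid with optional additive Gaussian noise; used both as test fixtures and
#' for fitter validation.  The ground-truth parameters and seed are recorded
#' in the manifest.
#'
#' @param params_list A list of [eyring_params()] objects (or coercibles).
#' @param noise Relative amplitude of additive Gaussian noise (standard
#'   deviation in F units, since the signal scale is F(0) = 1).  Must be
#'   < 0.5 (noise of the order of the signal is rejected).
#' @param seed Integer seed.
#' @param n_points Points per curve.
#' @param t_range Either `NULL` (auto: from tau1/10 to 10 eps/k2 per curve)
#'   or a length-2 numeric range in seconds applied to all curves.
#' @param dir Optional directory; when given, curves are written as TSV files
#'   `curve-<i>.tsv` plus a `manifest.json` and file paths are returned in
#'   the manifest.
#' @return A list with `curves` (list of tibbles `time_s`, `F`) and
#'   `manifest` (tibble: id, eps, k1, k2, gamma, noise, seed, n_points, file).
#' @export
synth_curves <- function(params_list, noise = 0, seed = 1L, n_points = 200L,
                         t_range = NULL, dir = NULL) {
  stopifnot(is.list(params_list), length(params_list) >= 1L)
  if (!is.finite(noise) || noise < 0 || noise >= 0.5) {
    stop("`noise` must be in [0, 0.5): noise of the order of the signal scale is not allowed")
  }
  params_list <- lapply(params_list, as_eyring_params)
  set.seed(seed)
  curves <- vector("list", length(params_list))
  files <- rep(NA_character_, length(params_list))
  for (i in seq_along(params_list)) {
    p <- params_list[[i]]
    rng <- if (is.null(t_range)) c(p$tau1 / 10, 10 * p$a) else t_range
    t <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_points))
    F <- eyring_solution(t, p)
    if (noise > 0) F <- F + stats::rnorm(n_points, 0, noise)
    curves[[i]] <- tibble::tibble(time_s = t, F = F)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files[i] <- file.path(dir, sprintf("curve-%d.tsv", i))
      write_curve(curves[[i]], files[i])
    }
  }
  manifest <- tibble::tibble(
    id = seq_along(params_list),
    eps = vapply(params_list, `[[`, 0, "eps"),
    k1 = vapply(params_list, `[[`, 0, "k1"),
    k2 = vapply(params_list, `[[`, 0, "k2"),
    gamma = vapply(params_list, `[[`, 0, "gamma"),
    noise = noise, seed = seed, n_points = n_points,
    file = files
  )
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = FALSE, digits = NA, na = "null")
  }
  list(curves = curves, manifest = manifest)
}
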