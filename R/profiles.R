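#' Core/corona and corona/bulk interface radii from converged fields
#'
#' The core/corona interface is the radius where the PO and EO monomer
#' concentrations cross; the corona/bulk interface is where the EO
#' concentration has decayed to its bulk value plus 5 percent of its peak
#' excess.  Both are linearly interpolated between shells.
#'
#' @param fields A data frame with columns `r_mid`, `c_EO`, `c_PO`
#'   (e.g. [field_profile()] of a converged micelle solve, or the averaged
#'   fields of an [run_exchange()]).
#' @return A list with `r_core_corona` and `r_corona_bulk` (sigma).
#' @export
region_boundaries <- function(fields) {
  stopifnot(is.data.frame(fields),
            all(c("r_mid", "c_EO", "c_PO") %in% names(fields)))
  r <- fields$r_mid
  d <- fields$c_PO - fields$c_EO
  if (d[1] <= 0) stop("no micelle: PO does not dominate the centre")
  cross <- which(d[-1] <= 0 & d[-length(d)] > 0)
  if (!length(cross)) stop("no micelle: c_PO never crosses c_EO")
  i <- cross[1]
  r_cc <- r[i] + (r[i + 1] - r[i]) * d[i] / (d[i] - d[i + 1])
  n <- length(r)
  bulk <- mean(fields$c_EO[max(1, floor(0.9 * n)):n])
  peak <- max(fields$c_EO)
  if (peak <= bulk) stop("no corona: EO has no excess over bulk")
  thr <- bulk + 0.05 * (peak - bulk)
  ipk <- which.max(fields$c_EO)
  e <- fields$c_EO
  below <- which(e < thr & seq_len(n) > ipk)
  if (!length(below)) stop("corona extends to the cell edge: cell too small")
  j <- below[1] - 1L   # last shell above threshold going outward from the peak
  r_cb <- r[j] + (r[j + 1] - r[j]) * (e[j] - thr) / (e[j] - e[j + 1])
  if (!(r_cc < r_cb)) stop("degenerate boundaries (r_core_corona >= r_corona_bulk)")
  list(r_core_corona = r_cc, r_corona_bulk = r_cb)
}

#' Radial conformational profiles
#'
#' Bin-averaged PO-block radius of gyration (normalized by the bulk
#' free-chain value Rg*) and EO-PO-EO angle versus the radial distance of
#' the PO-block centre of mass from the micelle centre.
#'
#' @param samples A data frame with columns `r` (PO-centre radius, sigma),
#'   `rg_PO` (sigma), `angle` (degrees, may be NA) and optionally `weight`.
#' @param rg_star Bulk free-chain PO radius of gyration (normalizer; see
#'   [bulk_rg_po()]).
#' @param bin_width Radial bin width (sigma).
#' @param min_count Minimum (effective) samples per reported bin; sparser
#'   bins are dropped, never interpolated.
#' @return A tibble: `r_mid`, `rg_ratio` (mean Rg_PO/Rg*), `rg_se`,
#'   `angle` (mean, degrees), `angle_se`, `n` (effective count).
#' @export
radial_profiles <- function(samples, rg_star, bin_width = 0.5,
                            min_count = 50) {
  stopifnot(is.data.frame(samples),
            all(c("r", "rg_PO", "angle") %in% names(samples)),
            rg_star > 0)
  w <- if ("weight" %in% names(samples)) samples$weight else
    rep(1, nrow(samples))
  bin <- floor(samples$r / bin_width)
  df <- tibble::tibble(bin = bin, r = samples$r, rg = samples$rg_PO,
                       angle = samples$angle, w = w)
  out <- df |>
    dplyr::group_by(bin) |>
    dplyr::summarise(
      r_mid = (bin[1] + 0.5) * bin_width,
      n = sum(w)^2 / sum(w^2),   # Kish effective sample size
      rg_ratio = stats::weighted.mean(rg, w) / rg_star,
      rg_se = sqrt(max(0, stats::weighted.mean(rg^2, w) -
                         stats::weighted.mean(rg, w)^2) / max(1, n[1])) / rg_star,
      angle_mean = stats::weighted.mean(angle[!is.na(angle)],
                                        w[!is.na(angle)]),
      angle_se = sqrt(max(0, stats::weighted.mean(angle[!is.na(angle)]^2,
                                                  w[!is.na(angle)]) -
                            angle_mean^2) / max(1, sum(!is.na(angle)))),
      .groups = "drop"
    ) |>
    dplyr::filter(n >= min_count) |>
    dplyr::arrange(r_mid) |>
    dplyr::rename(angle = angle_mean)
  out[, c("r_mid", "rg_ratio", "rg_se", "angle", "angle_se", "n")]
}

#' Radial profiles from an equilibrium SCMF state
#'
#' Probability-weighted profiles over the solve's conformation ensemble.
#'
#' @param state A converged [solve_scmf()] state (from a micelle solve).
#' @param rg_star Bulk PO radius of gyration ([bulk_rg_po()]).
#' @inheritParams radial_profiles
#' @return See [radial_profiles()].
#' @export
equilibrium_profiles <- function(state, rg_star, bin_width = 0.5,
                                 min_count = 50) {
  ens <- state$ens
  samples <- tibble::tibble(r = ens$r_PO, rg_PO = ens$rg_PO,
                            angle = ens$angle,
                            weight = state$p * state$N)
  radial_profiles(samples, rg_star, bin_width, min_count)
}

#' Radial profiles accumulated during a dynamics run
#'
#' @param run An [run_exchange()] result (with `profile_every > 0`).
#' @param rg_star Bulk PO radius of gyration.
#' @param min_count Minimum samples per reported bin.
#' @return A tibble: `r_mid`, `rg_ratio`, `angle`, `n`.
#' @export
dynamics_profiles <- function(run, rg_star, min_count = 50) {
  pr <- run$profiles_raw
  keep <- pr$prof_n >= min_count
  tibble::tibble(
    r_mid = (seq_along(pr$prof_n) - 0.5) * run$prof_bin,
    rg_ratio = ifelse(pr$prof_n > 0, pr$prof_rg_sum / pr$prof_n, NA) / rg_star,
    angle = ifelse(pr$prof_n_angle > 0,
                   pr$prof_angle_sum / pmax(1L, pr$prof_n_angle), NA),
    n = pr$prof_n
  )[keep, ]
}

#' Bulk free-chain PO radius of gyration
#'
#' Conformational average of the PO-block radius of gyration of an isolated
#' chain (weights exp(-U_intra); uniform solvent contributions cancel in
#' the ratio profiles).
#'
#' @param spec A [chain_spec()].
#' @param M Samples.
#' @param pot A [pair_potential()].
#' @param seed Integer seed.
#' @return Rg* (sigma).
#' @export
bulk_rg_po <- function(spec, M = 2000L, pot = pair_potential(), seed = 1L) {
  set.seed(seed)
  seg_len <- segment_lengths(spec)
  block <- block_labels(spec)
  rg <- numeric(M)
  u <- numeric(M)
  for (m in seq_len(M)) {
    pos <- cpp_sample_chain(seg_len, 10000L)
    po <- pos[block == 1L, , drop = FALSE]
    com <- colMeans(po)
    rg[m] <- sqrt(mean(rowSums(sweep(po, 2, com)^2)))
    u[m] <- cpp_intra_energy(pos, block, pot$contact_EO_PO, pot$well_outer)
  }
  w <- exp(-(u - min(u)))
  sum(w * rg) / sum(w)
}
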