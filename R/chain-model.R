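#' Coarse-grained triblock copolymer chain specification
#'
#' Defines an EOx-POy-EOx triblock as a string of beads of diameter sigma
#' (one bead per monomer, bond length = sigma) whose stiffness is set by the
#' Kuhn segment lengths of the hydrophilic (EO) and hydrophobic (PO) blocks:
#' `kuhn_EO` / `kuhn_PO` consecutive monomers form a straight rigid rod, with
#' complete flexibility at the joints between consecutive rods and at every
#' chemical block boundary.  The default is the L44 poloxamer EO10-PO23-EO10.
#'
#' @param n_head_EO,n_PO,n_tail_EO Monomer counts of the three blocks.
#' @param kuhn_EO,kuhn_PO Monomers per rigid Kuhn segment in the EO and PO
#'   blocks (>= 1; a terminal segment may be shorter, ceil partition).
#' @param bead_diameter Physical bead size (m); ~0.2 nm for EO/PO monomers.
#'   All geometry is handled internally in sigma units; this value only
#'   enters the physical time calibration.
#' @return An object of class `chain_spec`.
#' @examples
#' chain_spec(kuhn_EO = 3, kuhn_PO = 4)   # semiflexible L44
#' @export
chain_spec <- function(n_head_EO = 10L, n_PO = 23L, n_tail_EO = 10L,
                       kuhn_EO = 3L, kuhn_PO = 4L, bead_diameter = 0.2e-9) {
  counts <- c(n_head_EO, n_PO, n_tail_EO)
  if (any(counts < 1L)) stop("all block monomer counts must be >= 1")
  if (kuhn_EO < 1L || kuhn_PO < 1L) stop("Kuhn lengths must be >= 1")
  structure(
    list(n_head_EO = as.integer(n_head_EO), n_PO = as.integer(n_PO),
         n_tail_EO = as.integer(n_tail_EO),
         kuhn_EO = as.integer(kuhn_EO), kuhn_PO = as.integer(kuhn_PO),
         bead_diameter = bead_diameter, bond_length = 1.0),
    class = "chain_spec"
  )
}

#' Flexibility presets of the L44 study
#'
#' Returns the L44 chain at one of the three stiffnesses used throughout:
#' flexible (Kuhn lengths 2/2), semiflexible (3/4, the experimental L44) or
#' rigid (10/20).
#'
#' @param case One of `"flexible"`, `"semiflexible"`, `"rigid"`.
#' @return A [chain_spec()].
#' @export
l44_spec <- function(case = c("semiflexible", "flexible", "rigid")) {
  case <- match.arg(case)
  k <- switch(case, flexible = c(2L, 2L), semiflexible = c(3L, 4L),
              rigid = c(10L, 20L))
  chain_spec(kuhn_EO = k[1], kuhn_PO = k[2])
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("EO%d-PO%d-EO%d triblock, Kuhn lengths EO=%d PO=%d (%d beads)\n",
              x$n_head_EO, x$n_PO, x$n_tail_EO, x$kuhn_EO, x$kuhn_PO,
              n_beads(x)))
  invisible(x)
}

n_beads <- function(spec) spec$n_head_EO + spec$n_PO + spec$n_tail_EO

#' Square-well pair potential of the coarse-grained model
#'
#' Hard core of one bead diameter, square well out to `well_outer` sigma.
#' Well depths are quoted in kBT per coordination contact: a neighbouring
#' bead (or solvent molecule) whose centre falls inside the well contributes
#' `eps_xy / z` kBT.  Defaults are the implicit-water parameter set for
#' EO/PO at 37 degrees C.
#'
#' @param eps_EO_PO,eps_EO_s,eps_PO_s Well depths (kBT/z) for EO-PO,
#'   EO-solvent and PO-solvent contacts.
#' @param z Coordination number (fixed constant in the energy convention).
#' @param well_outer Outer well radius (sigma).
#' @return An object of class `pair_potential` with the per-contact energies
#'   in `contact_EO_PO`, `contact_EO_s`, `contact_PO_s` (kBT).
#' @export
pair_potential <- function(eps_EO_PO = 0.006, eps_EO_s = 0.5, eps_PO_s = 2.1,
                           z = 26, well_outer = 1.62) {
  if (well_outer <= 1) stop("well_outer must exceed the hard core (1 sigma)")
  stopifnot(is.finite(eps_EO_PO), is.finite(eps_EO_s), is.finite(eps_PO_s))
  structure(
    list(eps_EO_PO = eps_EO_PO, eps_EO_s = eps_EO_s, eps_PO_s = eps_PO_s,
         z = z, hard_core = 1.0, well_outer = well_outer,
         contact_EO_PO = eps_EO_PO / z,
         contact_EO_s = eps_EO_s / z,
         contact_PO_s = eps_PO_s / z),
    class = "pair_potential"
  )
}

#' Kuhn-segment partition of a chain
#'
#' Tiles the chain into rigid segments: each block is split into
#' ceil(block length / Kuhn length) segments (the last segment of a block may
#' be shorter), and a free joint sits between every pair of consecutive
#' segments, including every EO/PO chemical boundary.
#'
#' @param spec A [chain_spec()].
#' @return A tibble with one row per segment: `segment` (index), `block`
#'   ("EO" or "PO"), `from`, `to` (1-based bead indices), `length`.
#' @examples
#' # the L44 PO block (23 monomers): 6 segments at Kuhn length 4, 2 at 20
#' sum(kuhn_partition(l44_spec("semiflexible"))$block == "PO")
#' @export
kuhn_partition <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  blocks <- list(c("EO", spec$n_head_EO, spec$kuhn_EO),
                 c("PO", spec$n_PO, spec$kuhn_PO),
                 c("EO", spec$n_tail_EO, spec$kuhn_EO))
  out <- list()
  start <- 1L
  for (b in blocks) {
    len <- as.integer(b[2]); kuhn <- as.integer(b[3])
    pos <- start
    while (pos < start + len) {
      seg_len <- min(kuhn, start + len - pos)
      out[[length(out) + 1L]] <- tibble::tibble(
        block = b[1], from = pos, to = pos + seg_len - 1L, length = seg_len)
      pos <- pos + seg_len
    }
    start <- start + len
  }
  res <- dplyr::bind_rows(out)
  dplyr::mutate(res, segment = dplyr::row_number(), .before = 1)
}

# internal helpers shared with the C++ kernels
block_labels <- function(spec) {
  c(rep(0L, spec$n_head_EO), rep(1L, spec$n_PO), rep(0L, spec$n_tail_EO))
}
segment_ends <- function(spec) {
  as.integer(kuhn_partition(spec)$to - 1L)   # 0-based last bead per segment
}
segment_lengths <- function(spec) as.integer(kuhn_partition(spec)$length)

#' Sample a self-avoiding chain conformation
#'
#' Builds a freely-jointed chain of rigid Kuhn rods with isotropic segment
#' orientations, rejecting any conformation with a non-bonded bead pair
#' closer than one bead diameter.  Coordinates are in sigma units with the
#' first bead at the origin (use `center = TRUE` for a centre-of-mass at the
#' origin).  Uses R's RNG: `set.seed()` makes sampling reproducible.
#'
#' @param spec A [chain_spec()].
#' @param center Recentre the centre of mass at the origin?
#' @param max_attempts Attempt budget before failing with an error.
#' @return An object of class `conformation`: a numeric n x 3 matrix of bead
#'   positions with attributes `block` (0 = EO, 1 = PO) and `spec`.
#' @export
sample_conformation <- function(spec, center = FALSE, max_attempts = 10000L) {
  stopifnot(inherits(spec, "chain_spec"))
  pos <- cpp_sample_chain(segment_lengths(spec), as.integer(max_attempts))
  if (center) pos <- sweep(pos, 2, colMeans(pos))
  structure(pos, block = block_labels(spec), spec = spec,
            class = c("conformation", "matrix", "array"))
}

as_conformation <- function(pos, spec) {
  structure(as.matrix(pos), block = block_labels(spec), spec = spec,
            class = c("conformation", "matrix", "array"))
}

#' Exact intramolecular energy of a conformation
#'
#' Sum over non-bonded intra-chain EO-PO pairs whose centre distance lies
#' within the square well, each contributing the per-contact EO-PO energy;
#' same-species intra pairs carry no energy parameter and contribute zero.
#' Returns `Inf` when any non-bonded pair violates the hard core.
#'
#' @param conf A conformation (n x 3 matrix with a `block` attribute, or a
#'   plain matrix with `spec` supplied).
#' @param pot A [pair_potential()].
#' @param spec Optional [chain_spec()] when `conf` is a bare matrix.
#' @return Energy in kBT (possibly `Inf`).
#' @export
intra_energy <- function(conf, pot = pair_potential(), spec = NULL) {
  block <- attr(conf, "block")
  if (is.null(block)) {
    if (is.null(spec)) stop("need a conformation with block labels or a `spec`")
    block <- block_labels(spec)
  }
  cpp_intra_energy(unclass(conf)[, , drop = FALSE], block,
                   pot$contact_EO_PO, pot$well_outer)
}

#' Propose a symmetric local move of a conformation
#'
#' With equal probability either pivots one side of the chain about a random
#' inter-segment joint (rotation angle uniform in +/- amplitude radians about
#' a random axis) or translates the whole chain rigidly (step up to amplitude
#' sigma).  Bond lengths and all intra-segment distances are preserved; the
#' proposal is symmetric and is returned without any acceptance step
#' (hard-core violations are left to the caller's Metropolis filter).
#'
#' @param conf A conformation.
#' @param spec The [chain_spec()] (defaults to the conformation's own).
#' @param amplitude Dimensionless move amplitude; 0 returns the input.
#' @return The proposed conformation.
#' @export
perturb_conformation <- function(conf, spec = NULL, amplitude = 0.5) {
  if (is.null(spec)) spec <- attr(conf, "spec")
  stopifnot(inherits(spec, "chain_spec"))
  pos <- cpp_perturb(unclass(conf)[, , drop = FALSE], segment_ends(spec),
                     amplitude)
  structure(pos, block = attr(conf, "block") %||% block_labels(spec),
            spec = spec, class = c("conformation", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shape diagnostics of a conformation
#'
#' Radius of gyration of the PO block and of the whole chain (root mean
#' square bead distance from the respective centre of mass, sigma units) and
#' the angle (degrees, in \[0, 180\]) between the two vectors joining the PO
#' block's centre of mass to the centres of mass of the two EO blocks.  A
#' stretched chain approaches 180 degrees; a hairpin approaches 0.
#'
#' @param conf A conformation.
#' @return A tibble with columns `rg_PO`, `rg_whole`, `angle` (`angle` is
#'   `NA` with a warning if either EO-PO vector has zero length).
#' @export
shape_metrics <- function(conf) {
  block <- attr(conf, "block")
  if (is.null(block)) stop("conformation lacks block labels")
  pos <- unclass(conf)
  po <- pos[block == 1L, , drop = FALSE]
  com_po <- colMeans(po)
  rg_po <- sqrt(mean(rowSums(sweep(po, 2, com_po)^2)))
  rg_whole <- sqrt(mean(rowSums(sweep(pos, 2, colMeans(pos))^2)))
  ipo <- which(block == 1L)
  head_eo <- pos[seq_len(min(ipo) - 1L), , drop = FALSE]
  tail_eo <- pos[seq(max(ipo) + 1L, nrow(pos)), , drop = FALSE]
  v1 <- colMeans(head_eo) - com_po
  v2 <- colMeans(tail_eo) - com_po
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  ang <- if (n1 < 1e-12 || n2 < 1e-12) {
    warning("EO-PO-EO angle undefined: zero-length block vector")
    NA_real_
  } else {
    acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  }
  tibble::tibble(rg_PO = rg_po, rg_whole = rg_whole, angle = ang)
}

#' Write conformations as extended XYZ
#'
#' One frame per conformation; atom names are the block labels (EO/PO),
#' coordinates in sigma units; the comment line carries an optional seed and
#' a hash of the chain spec.
#'
#' @param confs A conformation or list of conformations.
#' @param path Output path.
#' @param seed Optional integer recorded in the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(confs, path, seed = NA_integer_) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  con <- file(path, "w")
  on.exit(close(con))
  for (conf in confs) {
    block <- attr(conf, "block")
    spec <- attr(conf, "spec")
    hash <- sum(unlist(spec[c("n_head_EO", "n_PO", "n_tail_EO",
                              "kuhn_EO", "kuhn_PO")]) * c(1, 1000, 1e6, 1e9, 1e11))
    writeLines(as.character(nrow(conf)), con)
    writeLines(sprintf("seed=%s spec_hash=%.0f units=sigma",
                       ifelse(is.na(seed), "NA", seed), hash), con)
    writeLines(sprintf("%s %.10f %.10f %.10f",
                       ifelse(block == 0L, "EO", "PO"),
                       conf[, 1], conf[, 2], conf[, 3]), con)
  }
  invisible(path)
}

#' Read conformations from an extended XYZ file
#'
#' @param path Path to an XYZ file written by [write_xyz()].
#' @param spec The [chain_spec()] of the stored chains.
#' @return A list of conformations.
#' @export
read_xyz <- function(path, spec) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop("malformed XYZ at line ", i)
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    pos <- t(vapply(parts, function(x) as.numeric(x[2:4]), numeric(3)))
    out[[length(out) + 1L]] <- as_conformation(pos, spec)
    i <- i + 2L + n
  }
  out
}
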