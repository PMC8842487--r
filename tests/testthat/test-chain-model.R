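test_that("Kuhn partition reproduces the stiffness-dependent segment counts", {
  po_segs <- function(spec) sum(kuhn_partition(spec)$block == "PO")
  expect_equal(po_segs(l44_spec("semiflexible")), 6L)   # ceil(23/4)
  expect_equal(po_segs(l44_spec("rigid")), 2L)          # ceil(23/20)
  expect_equal(po_segs(l44_spec("flexible")), 12L)      # ceil(23/2)
  # an EO block whose length equals its Kuhn length is one rigid segment
  kp <- kuhn_partition(chain_spec(kuhn_EO = 10, kuhn_PO = 20))
  expect_equal(sum(kp$block == "EO"), 2L)
})

test_that("segments tile the chain without overlap, within single blocks", {
  for (case in c("flexible", "semiflexible", "rigid")) {
    kp <- kuhn_partition(l44_spec(case))
    expect_equal(kp$from[1], 1L)
    expect_equal(kp$to[nrow(kp)], 43L)
    expect_true(all(kp$from[-1] == kp$to[-nrow(kp)] + 1L))
    expect_true(all(kp$to - kp$from + 1L == kp$length))
    # each segment stays inside one chemical block
    lbl <- c(rep("EO", 10), rep("PO", 23), rep("EO", 10))
    for (i in seq_len(nrow(kp))) {
      expect_true(all(lbl[kp$from[i]:kp$to[i]] == kp$block[i]))
    }
  }
})

test_that("sampled conformations satisfy the geometric invariants", {
  spec <- l44_spec("semiflexible")
  set.seed(5)
  for (i in 1:20) {
    conf <- sample_conformation(spec)
    d <- sqrt(rowSums(diff(unclass(conf))^2))
    expect_lt(max(abs(d - 1)), 1e-9)            # bonds exactly one sigma
    dm <- as.matrix(dist(unclass(conf)))
    nb <- abs(row(dm) - col(dm)) >= 2
    expect_gte(min(dm[nb]), 1 - 1e-9)           # hard core
  }
  # identical seeds give identical conformations
  set.seed(42); a <- sample_conformation(spec)
  set.seed(42); b <- sample_conformation(spec)
  expect_identical(unclass(a), unclass(b))
})

test_that("excluded volume swells the fully flexible chain beyond ideal", {
  # a 20-bead fully flexible (Kuhn length 1) chain; contact-sphere rejection
  # makes the full-length Kuhn-1 chain essentially unsamplable, which is the
  # documented failure mode tested below
  spec <- chain_spec(5, 10, 5, kuhn_EO = 1, kuhn_PO = 1)
  set.seed(7)
  n <- 20
  msee <- mean(replicate(10000, {
    conf <- sample_conformation(spec, max_attempts = 200000L)
    sum((conf[n, ] - conf[1, ])^2)
  }))
  expect_gt(msee, (n - 1))   # ideal freely jointed value is (n-1) sigma^2
})

test_that("pathological specs fail with a clear signal on budget exhaustion", {
  spec <- chain_spec(kuhn_EO = 1, kuhn_PO = 1)   # full-length Kuhn-1 chain
  set.seed(8)
  expect_error(sample_conformation(spec, max_attempts = 200L),
               "no self-avoiding conformation")
})

test_that("intramolecular energy handles contacts, rods and the brute-force oracle", {
  pot <- pair_potential()
  # single EO-PO contact at 1.3 sigma
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.845, 0.988, 0),
               c(2.495, 1.748, 0))
  pos[3, ] <- c(0.845, 0.988, 0)
  pos[4, ] <- pos[3, ] + c(0.845, 0.988, 0) / 1.3
  conf <- make_conformation(pos, c(0L, 1L, 1L, 0L))
  expect_equal(intra_energy(conf, pot), pot$contact_EO_PO, tolerance = 1e-12)
  # straight rod: nothing within the well beyond bonded neighbours
  rod <- make_conformation(cbind(0:9, 0, 0),
                           c(rep(0L, 3), rep(1L, 4), rep(0L, 3)))
  expect_equal(intra_energy(rod, pot), 0)
  # hard-core overlap is flagged as infinite energy
  bad <- make_conformation(rbind(c(0, 0, 0), c(1, 0, 0), c(0.2, 0.1, 0)),
                           c(0L, 1L, 0L))
  expect_identical(intra_energy(bad, pot), Inf)
  # random conformations against the O(n^2) R loop
  spec <- l44_spec("flexible")
  set.seed(9)
  for (i in 1:100) {
    conf <- sample_conformation(spec)
    expect_equal(intra_energy(conf, pot),
                 intra_energy_bruteforce(unclass(conf), attr(conf, "block"),
                                         pot$contact_EO_PO, pot$well_outer),
                 tolerance = 1e-12)
  }
})

test_that("local moves preserve rigidity and are symmetric", {
  spec <- l44_spec("semiflexible")
  set.seed(11)
  conf <- sample_conformation(spec)
  kp <- kuhn_partition(spec)
  for (i in 1:50) {
    prop <- perturb_conformation(conf, amplitude = 0.7)
    # bonds and intra-segment distances unchanged
    d <- sqrt(rowSums(diff(unclass(prop))^2))
    expect_lt(max(abs(d - 1)), 1e-9)
    for (s in seq_len(nrow(kp))) {
      idx <- kp$from[s]:kp$to[s]
      if (length(idx) < 2) next
      d0 <- dist(unclass(conf)[idx, ])
      d1 <- dist(unclass(prop)[idx, ])
      expect_lt(max(abs(d1 - d0)), 1e-9)
    }
  }
  # zero amplitude is the identity
  expect_equal(unclass(perturb_conformation(conf, amplitude = 0)),
               unclass(conf))
  # proposal symmetry: centre-of-mass displacement has zero mean
  disp <- t(replicate(4000, {
    prop <- perturb_conformation(conf, amplitude = 0.7)
    colMeans(unclass(prop)) - colMeans(unclass(conf))
  }))
  se <- apply(disp, 2, sd) / sqrt(nrow(disp))
  expect_true(all(abs(colMeans(disp)) < 4 * se + 1e-12))
})

test_that("shape metrics match closed forms and bounds", {
  # a fully stretched chain has an EO-PO-EO angle of 180 degrees
  straight <- make_conformation(cbind(0:42, 0, 0),
                                c(rep(0L, 10), rep(1L, 23), rep(0L, 10)))
  sm <- shape_metrics(straight)
  expect_equal(sm$angle, 180, tolerance = 1e-9)
  # discrete rod of n beads at spacing sigma: Rg^2 = (n^2 - 1)/12
  n <- 23
  expect_equal(sm$rg_PO^2, (n^2 - 1) / 12, tolerance = 1e-12)
  # mirror-symmetric hairpin with both EO centres nearly coincident on the
  # same side of the PO block: angle -> 0
  hair <- rbind(c(0.9, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                c(1.1, 1, 0))
  hp <- make_conformation(hair, c(0L, 1L, 1L, 1L, 0L))
  expect_lt(shape_metrics(hp)$angle, 15)
  # angles always within [0, 180]
  spec <- l44_spec("flexible")
  set.seed(13)
  angs <- replicate(200, shape_metrics(sample_conformation(spec))$angle)
  expect_true(all(angs >= 0 & angs <= 180))
})

test_that("mean radius of gyration grows with chain stiffness", {
  set.seed(17)
  rg <- vapply(c("flexible", "semiflexible", "rigid"), function(case) {
    spec <- l44_spec(case)
    mean(replicate(1000, shape_metrics(sample_conformation(spec))$rg_whole))
  }, 0.0)
  expect_lt(rg[["flexible"]], rg[["semiflexible"]])
  expect_lt(rg[["semiflexible"]], rg[["rigid"]])
})

test_that("XYZ round trip preserves coordinates and labels", {
  spec <- l44_spec("semiflexible")
  set.seed(19)
  confs <- list(sample_conformation(spec), sample_conformation(spec))
  path <- tempfile(fileext = ".xyz")
  write_xyz(confs, path, seed = 19L)
  back <- read_xyz(path, spec)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(unclass(back[[i]]), unclass(confs[[i]]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_match(readLines(path)[2], "seed=19")
})
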