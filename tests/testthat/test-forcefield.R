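test_that("Ashbaugh-Hatch potential reproduces its closed-form identities", {
  tab <- forcefield_table()
  pp <- pair_params(tab, "Y", "S")
  rmin <- 2^(1 / 6) * pp$sigma_ij
  # pure LJ minimum at lambda = 1, before the cutoff shift (huge cutoff)
  pp1 <- list(sigma_ij = pp$sigma_ij, lam_ij = 1)
  expect_equal(ashbaugh_hatch_energy(rmin, pp1, tab$eps_ah, cutoff = 50),
               -tab$eps_ah, tolerance = 1e-9)
  # lambda = 0: the attractive branch vanishes at the splice point exactly
  pp0 <- list(sigma_ij = pp$sigma_ij, lam_ij = 0)
  expect_equal(ashbaugh_hatch_energy(rmin, pp0, tab$eps_ah, cutoff = 2), 0)
  # location of the minimum in units of sigma_ij, two decimals
  opt <- optimize(function(r) ashbaugh_hatch_energy(r, pp, tab$eps_ah, 2),
                  c(0.3, 1.9))
  expect_equal(round(opt$minimum / pp$sigma_ij, 2), 1.12)
  # zero beyond cutoff, and shifted to zero at the cutoff
  expect_equal(ashbaugh_hatch_energy(2.5, pp, tab$eps_ah, 2), 0)
  expect_equal(ashbaugh_hatch_energy(2 - 1e-12, pp, tab$eps_ah, 2), 0,
               tolerance = 1e-8)
  expect_error(ashbaugh_hatch_energy(-1, pp, tab$eps_ah, 2), "positive")
  expect_error(ashbaugh_hatch_energy(1, list(sigma_ij = 0.6, lam_ij = 2),
                                     tab$eps_ah, 2), "lambda")
})

test_that("AH energy is continuous at the lambda splice for all lambda", {
  tab <- forcefield_table()
  for (lam in seq(0, 1, by = 0.1)) {
    pp <- list(sigma_ij = 0.6, lam_ij = lam)
    rmin <- 2^(1 / 6) * 0.6
    lo <- ashbaugh_hatch_energy(rmin * (1 - 1e-12), pp, tab$eps_ah, 2)
    hi <- ashbaugh_hatch_energy(rmin * (1 + 1e-12), pp, tab$eps_ah, 2)
    expect_lt(abs(lo - hi), 1e-10)
  }
})

test_that("Debye screening length matches the electrolyte closed form", {
  # independent oracle: kappa^-1 = sqrt(eps0 er kB T / (2 NA e^2 I*1e3))
  oracle <- function(I, T, er) {
    1e9 * sqrt(8.8541878128e-12 * er * 1.380649e-23 * T /
                 (2 * 6.02214076e23 * 1.602176634e-19^2 * I * 1e3))
  }
  dh <- compute_debye_length(0.15, 300, 80)
  expect_equal(dh$debye_length, oracle(0.15, 300, 80), tolerance = 1e-12)
  expect_gt(dh$debye_length, 0.78)
  expect_lt(dh$debye_length, 0.80)
  # square-root law and the unscreened limit
  expect_equal(compute_debye_length(0.6, 300, 80)$debye_length,
               dh$debye_length / 2, tolerance = 1e-12)
  expect_true(is.infinite(compute_debye_length(0)$debye_length))
  expect_error(compute_debye_length(-0.1), ">= 0")
})

test_that("Debye-Hueckel energy is screened, shifted and sign-correct", {
  dh <- compute_debye_length(0.15, 300, 80)
  r <- seq(0.3, 3.9, by = 0.1)
  expect_equal(debye_huckel_energy(r, 0, dh, 4), rep(0, length(r)))
  u <- debye_huckel_energy(r, 1, dh, 4)
  expect_true(all(diff(u) < 0) || all(u > 0)) # repulsive, decaying
  expect_true(all(diff(u) < 0))
  expect_equal(debye_huckel_energy(4 - 1e-10, 1, dh, 4), 0, tolerance = 1e-8)
  expect_true(all(debye_huckel_energy(r, -1, dh, 4) < 0))
  # weak-screening limit approaches the bare Coulomb law within 1%
  dh0 <- compute_debye_length(1e-6, 300, 80)
  r_short <- 0.5 # far below kappa^-1 ~ 300 nm
  bare <- dh0$bjerrum_prefactor * (1 / r_short - 1 / 4)
  expect_equal(debye_huckel_energy(r_short, 1, dh0, 4), bare, tolerance = 0.01)
})

test_that("bonded energies follow the harmonic forms and the ledger gating", {
  tab <- forcefield_table()
  rec <- sequence_record("TRI", "GGG", "protein")
  ann <- larks_annotation("TRI", 1, 3, e_dis = 1, e_str = 40)
  topo <- build_topology(list(rec), 1, tab, ann)
  bp <- bonded_params()
  straight <- cbind(c(0, bp$bond_length, 2 * bp$bond_length), 0, 0) + 5
  cfg <- toy_config(straight, c(10, 10, 10))
  e <- bonded_energy(cfg, topo, state = NULL, bonded = bp)
  expect_equal(e$bond, 0, tolerance = 1e-12)
  expect_equal(e$angle, 0) # disordered: angle term identically absent
  # one bond stretched by delta
  delta <- 0.07
  stretched <- straight
  stretched[3, 1] <- stretched[3, 1] + delta
  e2 <- bonded_energy(toy_config(stretched, c(10, 10, 10)), topo, bonded = bp)
  expect_equal(e2$bond, 0.5 * bp$bond_k * delta^2, tolerance = 1e-10)
  # structured straight segment at theta0 = pi has zero angle energy
  led <- larks_ledger(topo)
  led$state[1] <- "structured"
  e3 <- bonded_energy(cfg, topo, state = led, bonded = bp)
  expect_equal(e3$angle, 0, tolerance = 1e-12)
  # bent structured segment pays the harmonic angle penalty
  bent <- straight
  bent[3, ] <- bent[2, ] + bp$bond_length * c(0, 1, 0)
  e4 <- bonded_energy(toy_config(bent, c(10, 10, 10)), topo, state = led, bonded = bp)
  expect_equal(e4$angle, 0.5 * bp$angle_k * (pi / 2 - pi)^2, tolerance = 1e-10)
})

test_that("forces are the analytic gradient and obey Newton's third law", {
  tab <- forcefield_table()
  dh <- compute_debye_length(0.15, 300, 80)
  set.seed(42)
  codes <- c("Y", "R", "E", "G", "S", "K", "F", "D")
  h <- 1e-6
  for (k in 1:100) {
    ci <- sample(codes, 1); cj <- sample(codes, 1)
    rec1 <- sequence_record("A1", ci, "protein")
    rec2 <- sequence_record("A2", cj, "protein")
    topo <- build_topology(list(rec1, rec2), c(1, 1), tab)
    sij <- pair_params(tab, ci, cj)$sigma_ij
    r <- runif(1, 0.85 * sij, 1.8)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pos <- rbind(c(5, 5, 5), c(5, 5, 5) + r * dir)
    cfg <- toy_config(pos, c(10, 10, 10))
    ef <- total_energy_forces(cfg, topo, tab, dh)
    # Newton's third law
    expect_equal(ef$forces[1, ], -ef$forces[2, ], tolerance = 1e-10)
    # central finite differences, both beads, all axes
    for (i in 1:2) for (d in 1:3) {
      cp <- cfg; cp$positions[i, d] <- cp$positions[i, d] + h
      cm <- cfg; cm$positions[i, d] <- cm$positions[i, d] - h
      fn <- -(total_energy_forces(cp, topo, tab, dh)$energy -
                total_energy_forces(cm, topo, tab, dh)$energy) / (2 * h)
      if (abs(fn) > 1e-8)
        expect_equal(ef$forces[i, d], fn, tolerance = 1e-4)
    }
  }
})

test_that("two-bead total energy is the sum of the AH and DH pair terms", {
  tab <- forcefield_table()
  dh <- compute_debye_length(0.15, 300, 80)
  topo <- build_topology(list(sequence_record("A", "R", "protein"),
                              sequence_record("B", "E", "protein")), c(1, 1), tab)
  r <- 0.8
  cfg <- toy_config(rbind(c(5, 5, 5), c(5 + r, 5, 5)), c(12, 12, 12))
  ef <- total_energy_forces(cfg, topo, tab, dh)
  pp <- pair_params(tab, "R", "E")
  expected <- ashbaugh_hatch_energy(r, pp, tab$eps_ah, tab$cutoff_ah) +
    debye_huckel_energy(r, pp$qq, dh, tab$cutoff_dh)
  expect_equal(ef$energy, expected, tolerance = 1e-12)
  # all pairs beyond cutoffs: exactly zero energy and forces
  cfg2 <- toy_config(rbind(c(1, 1, 1), c(6, 1, 1)), c(12, 12, 12))
  ef2 <- total_energy_forces(cfg2, topo, tab, dh)
  expect_equal(ef2$energy, 0)
  expect_equal(max(abs(ef2$forces)), 0)
})

test_that("overlapping beads raise a numerical-overlap error", {
  tab <- forcefield_table()
  dh <- compute_debye_length(0.15, 300, 80)
  topo <- build_topology(list(sequence_record("A", "G", "protein"),
                              sequence_record("B", "G", "protein")), c(1, 1), tab)
  cfg <- toy_config(rbind(c(5, 5, 5), c(5, 5, 5 + 1e-8)), c(10, 10, 10))
  expect_error(total_energy_forces(cfg, topo, tab, dh), "overlap")
})

test_that("force-field table validates and round-trips through TSV", {
  tab <- forcefield_table()
  expect_equal(nrow(tab$residues), 20)
  expect_true(all(tab$residues$lambda >= 0 & tab$residues$lambda <= 1))
  bad <- calvados_residues()[-1, ]
  expect_error(forcefield_table(bad), "missing canonical")
  expect_error(forcefield_table(cutoff_ah = 0.5), "cutoffs")
  tmp <- tempfile(fileext = ".tsv")
  write_forcefield_tsv(tab$residues, tmp)
  back <- read_forcefield_tsv(tmp)
  expect_equal(back, tab$residues)
  # histidine titration switch gives a fractional positive charge
  tab_ph <- forcefield_table(histidine_ph = 6.0)
  expect_equal(tab_ph$residues$charge[tab_ph$residues$code == "H"], 0.5)
})
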