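test_that("white-noise stress gives a vanishing relaxation modulus beyond lag zero", {
  set.seed(4)
  stress <- matrix(rnorm(3 * 5000), ncol = 3)
  gm <- relaxation_modulus(stress, volume = 100, temperature = 300, dt = 0.1,
                           max_lag = 100)
  g <- gm$gt$G
  expect_lt(mean(abs(g[-1])), 0.05 * g[1])
})

test_that("an OU stress series recovers its correlation time and G0", {
  set.seed(14)
  tau <- 5; dt <- 0.25; n <- 40000
  stress <- vapply(1:3, function(k) ou_series(n, tau, dt), numeric(n))
  V <- 50; T <- 300
  gm <- relaxation_modulus(stress, volume = V, temperature = T, dt = dt,
                           max_lag = 160)
  # dominant recovered mode has tau within 10%
  lead <- which.max(gm$modes$G_i)
  expect_equal(gm$modes$tau_i[lead], tau, tolerance = 0.1)
  kB <- 0.008314463
  expect_equal(sum(gm$modes$G_i), V / (kB * T), tolerance = 0.1)
  # eta equals sum(G_i tau_i) identically, by definition
  expect_identical(gm$eta, sum(gm$modes$G_i * gm$modes$tau_i))
})

test_that("single-Maxwell spectra obey the crossover and low-frequency limits", {
  G0 <- 12; tau <- 3
  modes <- tibble::tibble(G_i = G0, tau_i = tau)
  # crossover at omega = 1/tau: G' = G'' = G0/2
  sp <- moduli_spectrum(modes, omega = 1 / tau)
  expect_equal(sp$spectrum$G_storage, G0 / 2)
  expect_equal(sp$spectrum$G_loss, G0 / 2)
  # omega -> 0: loss dominates as 1/(omega tau) -> liquid classification
  sp2 <- moduli_spectrum(modes)
  expect_equal(sp2$classification, "liquid")
  low <- head(sp2$spectrum, 5)
  expect_true(all(low$G_loss > low$G_storage))
  expect_equal(low$G_loss / low$G_storage, 1 / (low$omega * tau),
               tolerance = 1e-10)
  # adding a permanent plateau mode flips the classification to solid
  sp3 <- moduli_spectrum(dplyr::bind_rows(modes,
                                          tibble::tibble(G_i = 0.5, tau_i = Inf)))
  expect_equal(sp3$classification, "solid")
  expect_true(all(sp3$spectrum$G_storage >= 0.5))
})

test_that("contact maps threshold at 1.2 sigma_ij and stay symmetric", {
  tab <- forcefield_table()
  sigma_gg <- tab$residues$sigma[tab$residues$code == "G"]
  mk <- function(r) {
    topo <- build_topology(list(sequence_record("P", "G", "protein")), 2, tab)
    pos <- rbind(c(5, 5, 5), c(5 + r, 5, 5))
    list(topo = topo, traj = toy_trajectory(list(pos), c(12, 12, 12),
                                            topology = topo))
  }
  near <- mk(1.19 * sigma_gg)
  cm_near <- contact_map(near$traj, near$topo, "P", factor = 1.2)
  expect_equal(cm_near$matrix[1, 1], 100)
  far <- mk(1.21 * sigma_gg)
  cm_far <- contact_map(far$traj, far$topo, "P", factor = 1.2)
  expect_equal(cm_far$matrix[1, 1], 0)
  # homotypic map symmetry on a multi-residue system
  sys <- mini_larks_system(n_chains = 4, density = 600, seed = 2)
  params <- integrator_params(dt = 0.01, friction = 0.5, temperature = 300, seed = 3)
  tr <- run_nvt(sys, params, 2000, thin = 200)
  cm <- contact_map(tr, sys$topology, "MINI_LARKS")
  expect_equal(cm$matrix, t(cm$matrix))
  expect_true(all(cm$matrix >= 0 & cm$matrix <= 100))
  expect_error(contact_map(tr, sys$topology, "NOPE"), "not present")
})

test_that("radius of gyration matches closed forms and is translation invariant", {
  tab <- forcefield_table()
  N <- 12; b <- 0.38
  topo <- build_topology(list(sequence_record("ROD", strrep("G", N), "protein")),
                         1, tab)
  rod <- cbind(b * (0:(N - 1)), 0, 0) + 2
  traj <- toy_trajectory(list(rod), c(30, 30, 30), topology = topo)
  rg <- radius_of_gyration(traj, topo)
  expect_equal(rg$rg, b * sqrt((N^2 - 1) / 12), tolerance = 1e-12)
  # rigid translation leaves Rg unchanged
  traj2 <- toy_trajectory(list(rod + 7.3), c(30, 30, 30), topology = topo)
  expect_equal(radius_of_gyration(traj2, topo)$rg, rg$rg, tolerance = 1e-12)
  # coincident beads: zero
  traj3 <- toy_trajectory(list(matrix(5, N, 3)), c(30, 30, 30), topology = topo)
  expect_equal(radius_of_gyration(traj3, topo)$rg, 0)
  # a chain crossing the boundary is unwrapped first
  wrapped <- rod; wrapped[, 1] <- (wrapped[, 1] + 28) %% 30
  traj4 <- toy_trajectory(list(wrapped), c(30, 30, 30), topology = topo)
  expect_equal(radius_of_gyration(traj4, topo)$rg, rg$rg, tolerance = 1e-10)
})

test_that("diffusion estimates respect immobility, time scaling and arrest flags", {
  tab <- forcefield_table()
  topo <- build_topology(list(sequence_record("P", "GG", "protein")), 3, tab)
  pos <- matrix(runif(18, 0, 10), 6, 3)
  frames <- rep(list(pos), 20)
  traj <- toy_trajectory(frames, c(10, 10, 10), topology = topo)
  D0 <- diffusion_coefficient(traj, topo)
  expect_true(D0$arrested)
  expect_equal(D0$D, 0)
  # analytic diffusive MSD: D = slope/6 exactly
  lag <- 0:30
  msd <- tibble::tibble(lag = lag, msd = 0.6 * lag)
  D1 <- diffusion_coefficient(msd)
  expect_false(D1$arrested)
  expect_equal(D1$D, 0.1, tolerance = 1e-10)
  # rescaling time t -> 2t halves D
  msd2 <- tibble::as_tibble(data.frame(lag = 2 * lag, msd = 0.6 * lag))
  expect_equal(diffusion_coefficient(msd2)$D, 0.05, tolerance = 1e-10)
  # sub-diffusive input raises the arrested flag instead of a coefficient
  msd3 <- tibble::tibble(lag = lag, msd = c(0, (lag[-1])^0.4))
  D3 <- diffusion_coefficient(msd3)
  expect_true(D3$arrested)
  expect_true(is.na(D3$D))
})

test_that("contact maps at LARKS rows drop when a binding peptide is added", {
  # toy mirror of the screening readout: a sticky 24-mer recruits to the
  # protein LARKS and competes for inter-protein LARKS contacts
  params <- integrator_params(dt = 0.01, friction = 0.5, temperature = 300, seed = 6)
  pure <- mini_larks_system(n_chains = 6, density = 650, seed = 4)
  tr_p <- run_nvt(pure, params, 6000, thin = 200)
  cm_p <- contact_map(tr_p, pure$topology, "MINI_LARKS")
  rec <- condage:::mini_larks_record()
  pep <- expand_repeat_notation("(SY)12", name = "PEP")
  tab <- pure$table
  ann <- larks_annotation("MINI_LARKS", 13, 18, e_dis = 4.5, e_str = 40)
  topo_m <- build_topology(list(rec, pep), c(6, 3), tab, ann)
  cfg_m <- build_bulk(topo_m, 650, seed = 4)
  mix <- minimize_config(cg_system(topo_m, cfg_m, tab,
                                   compute_debye_length(0.15, 300, 80)))
  tr_m <- run_nvt(mix, params, 6000, thin = 200)
  cm_m <- contact_map(tr_m, mix$topology, "MINI_LARKS")
  larks_rows <- 13:18
  expect_lt(mean(cm_m$matrix[larks_rows, larks_rows]),
            mean(cm_p$matrix[larks_rows, larks_rows]))
  # the peptide-protein map has the right shape and is populated
  cm_x <- contact_map(tr_m, mix$topology, "PEP", "MINI_LARKS")
  expect_equal(dim(cm_x$matrix), c(24, 30))
  expect_gt(max(cm_x$matrix), 0)
  tmp <- tempfile(fileext = ".tsv")
  write_contact_map_tsv(cm_x, tmp)
  back <- as.matrix(read.delim(tmp, row.names = 1))
  expect_equal(unname(back), unname(cm_x$matrix), tolerance = 1e-6)
})
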