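# tiny construction helpers shared across the suite

# configuration with explicit positions (nm) in a periodic box
toy_config <- function(positions, box) {
  structure(list(positions = positions, box = box,
                 periodic = c(TRUE, TRUE, TRUE)),
            class = "cg_config")
}

# n single-bead chains of one residue at given positions
toy_bead_system <- function(code, positions, box, table = forcefield_table(),
                            ionic_strength = 0.15, temperature = 300) {
  rec <- sequence_record("BEAD", code, "protein")
  topo <- build_topology(list(rec), nrow(positions), table)
  cg_system(topo, toy_config(positions, box), table,
            compute_debye_length(ionic_strength, temperature, table$dielectric))
}

# a residue table with all interactions switched off (ideal gas)
ideal_gas_table <- function() {
  res <- calvados_residues()
  res$lambda[] <- 0
  res$charge[] <- 0
  forcefield_table(res, eps_ah = 0)
}

# minimal trajectory wrapper so analysis functions can run on synthetic frames
toy_trajectory <- function(frames, box, dt = 1, temperature = 300,
                           topology = NULL) {
  nf <- length(frames)
  structure(list(
    time = seq_len(nf) * dt,
    frames = frames,
    box = matrix(rep(box, each = nf), nf, 3),
    temperature = rep(temperature, nf),
    energy = rep(0, nf),
    pressure = matrix(0, nf, 6),
    final = list(positions = frames[[nf]], velocities = NULL, box = box),
    diverged = FALSE,
    params = integrator_params(dt = dt, temperature = temperature),
    topology_mass = if (is.null(topology)) NA_real_ else topology_mass(topology)),
    class = "cg_trajectory")
}

# a topology whose LARKS instances can be placed by hand: k chains, each a
# single-residue LARKS (segment of length 1), for detection-rule tests
point_larks_topology <- function(n_chains, code = "Y", e_str = 40) {
  rec <- sequence_record("PT", code, "protein")
  ann <- larks_annotation("PT", 1, 1, e_dis = 0.1, e_str = e_str)
  build_topology(rep(list(rec), 1), n_chains, forcefield_table(), ann)
}

# Ornstein-Uhlenbeck series with correlation time tau
ou_series <- function(n, tau, dt, sigma = 1) {
  a <- exp(-dt / tau)
  x <- numeric(n)
  for (i in 2:n) x[i] <- a * x[i - 1] + sigma * sqrt(1 - a^2) * rnorm(1)
  x
}
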