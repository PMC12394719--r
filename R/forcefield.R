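#' Per-residue parameters of the residue-resolution condensate model
#'
#' Embedded parameter table of the published CALVADOS2 residue-level model:
#' one bead per amino acid, with a van der Waals diameter `sigma` (nm), a
#' hydrophobicity ("stickiness") scale `lambda` in \[0, 1\], a charge at
#' neutral pH (e) and an average residue mass (Da).
#'
#' @return A tibble with columns `code`, `sigma`, `lambda`, `charge`, `mass`.
#' @export
#' @examples
#' calvados_residues()
calvados_residues <- function() {
  tibble::tribble(
    ~code, ~sigma, ~lambda,              ~charge, ~mass,
    "A",   0.504,  0.2743297969040348,    0, 71.0788,
    "R",   0.656,  0.7307624767517166,    1, 156.1875,
    "N",   0.568,  0.4255859009787713,    0, 114.1038,
    "D",   0.558,  0.0416040480605567,   -1, 115.0886,
    "C",   0.548,  0.5615435099141777,    0, 103.1388,
    "Q",   0.602,  0.3934318551056041,    0, 128.1307,
    "E",   0.592,  0.0006935460962935,   -1, 129.1155,
    "G",   0.450,  0.7058843733666401,    0, 57.0519,
    "H",   0.608,  0.4663667290557992,    0, 137.1411,
    "I",   0.618,  0.5423623610671892,    0, 113.1594,
    "L",   0.618,  0.6440005007782226,    0, 113.1594,
    "K",   0.636,  0.1790211738990582,    1, 128.1741,
    "M",   0.618,  0.5308481134337497,    0, 131.1926,
    "F",   0.636,  0.8672358982062975,    0, 147.1766,
    "P",   0.556,  0.3593126576364644,    0, 97.1167,
    "S",   0.518,  0.4625416811611541,    0, 87.0782,
    "T",   0.562,  0.3713162976273964,    0, 101.1051,
    "W",   0.678,  0.9893764740371644,    0, 186.2132,
    "Y",   0.646,  0.9774611449343455,    0, 163.1760,
    "V",   0.586,  0.2083769608174481,    0, 99.1326
  )
}

#' Assemble a force-field table
#'
#' Bundles the per-residue parameters with the global energy scale, cutoffs and
#' solvent description of the model. Residue-residue interactions combine an
#' Ashbaugh-Hatch (hydrophobicity-scaled Lennard-Jones) term with a screened
#' Coulomb (Debye-Hueckel) term; both are truncated and shifted to zero at
#' their cutoffs.
#'
#' @param residues Per-residue parameter tibble, defaults to
#'   [calvados_residues()]. Must contain all 20 canonical one-letter codes with
#'   `sigma > 0` and `lambda` in \[0, 1\].
#' @param eps_ah Hydrophobic energy scale (kJ/mol).
#' @param cutoff_ah,cutoff_dh Cutoffs (nm) of the Ashbaugh-Hatch and
#'   Debye-Hueckel terms.
#' @param dielectric Relative permittivity of the implicit solvent.
#' @param temperature_ref Reference temperature (K), used when converting
#'   energies to kBT.
#' @param histidine_ph If non-`NULL`, assign histidine a fractional
#'   Henderson-Hasselbalch charge `1 / (1 + 10^(pH - pKa))` with pKa 6.0
#'   instead of the default 0.
#' @param terminal_charges Add +1e / -1e to the first/last residue of each
#'   chain when building topologies. Off by default.
#' @return An object of class `forcefield_table`.
#' @export
forcefield_table <- function(residues = calvados_residues(),
                             eps_ah = 0.8368,
                             cutoff_ah = 2.0,
                             cutoff_dh = 4.0,
                             dielectric = 80,
                             temperature_ref = 300,
                             histidine_ph = NULL,
                             terminal_charges = FALSE) {
  stopifnot(is.data.frame(residues),
            all(c("code", "sigma", "lambda", "charge", "mass") %in% names(residues)))
  missing <- setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], residues$code)
  if (length(missing) > 0)
    stop("residue table is missing canonical residues: ", paste(missing, collapse = ", "))
  if (any(residues$sigma <= 0)) stop("all sigma must be > 0")
  if (any(residues$lambda < 0 | residues$lambda > 1)) stop("lambda must lie in [0, 1]")
  if (dielectric <= 0) stop("dielectric must be > 0")
  if (!is.null(histidine_ph)) {
    residues$charge[residues$code == "H"] <- 1 / (1 + 10^(histidine_ph - 6.0))
  }
  max_rmin <- 2^(1 / 6) * max(residues$sigma)
  if (cutoff_ah <= max_rmin || cutoff_dh <= max_rmin)
    stop("cutoffs must exceed the largest 2^(1/6) sigma_ij (", signif(max_rmin, 3), " nm)")
  structure(list(residues = residues, eps_ah = eps_ah,
                 cutoff_ah = cutoff_ah, cutoff_dh = cutoff_dh,
                 dielectric = dielectric, temperature_ref = temperature_ref,
                 terminal_charges = terminal_charges),
            class = "forcefield_table")
}

#' @export
print.forcefield_table <- function(x, ...) {
  cat("<forcefield_table> residue-resolution condensate model\n")
  cat(sprintf("  eps_ah %.4f kJ/mol | cutoffs AH %.1f nm, DH %.1f nm | eps_r %g | T_ref %g K\n",
              x$eps_ah, x$cutoff_ah, x$cutoff_dh, x$dielectric, x$temperature_ref))
  invisible(x)
}

#' Read or write a force-field residue table as TSV
#'
#' The on-disk format has columns `code`, `sigma_nm`, `lambda`, `charge_e`,
#' `mass_Da`; a user file can override the embedded defaults.
#'
#' @param path File path.
#' @return `read_forcefield_tsv()` returns a residue tibble suitable for
#'   [forcefield_table()]; `write_forcefield_tsv()` returns `path` invisibly.
#' @export
read_forcefield_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("code", "sigma_nm", "lambda", "charge_e", "mass_Da")
  if (!all(need %in% names(df)))
    stop("force-field TSV must have columns: ", paste(need, collapse = ", "))
  tibble::tibble(code = df$code, sigma = df$sigma_nm, lambda = df$lambda,
                 charge = df$charge_e, mass = df$mass_Da)
}

#' @rdname read_forcefield_tsv
#' @param residues Residue tibble as returned by [calvados_residues()].
#' @export
write_forcefield_tsv <- function(residues, path) {
  out <- data.frame(code = residues$code, sigma_nm = residues$sigma,
                    lambda = residues$lambda, charge_e = residues$charge,
                    mass_Da = residues$mass)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair-combination parameters for two residues
#'
#' Arithmetic (Lorentz-Berthelot-style) combining rules of the model:
#' `sigma_ij` and `lambda_ij` are the means of the per-residue values, `qq` is
#' the product of charges.
#'
#' @param table A [forcefield_table()].
#' @param code_i,code_j One-letter residue codes.
#' @return A list with `sigma_ij` (nm), `lam_ij`, `qq` (e^2).
#' @export
pair_params <- function(table, code_i, code_j) {
  res <- table$residues
  i <- match(code_i, res$code); j <- match(code_j, res$code)
  if (anyNA(c(i, j))) stop("unknown residue code: ", code_i, "/", code_j)
  list(sigma_ij = (res$sigma[i] + res$sigma[j]) / 2,
       lam_ij = (res$lambda[i] + res$lambda[j]) / 2,
       qq = res$charge[i] * res$charge[j])
}

#' Ashbaugh-Hatch pair potential
#'
#' Hydrophobicity-scaled Lennard-Jones interaction: at or inside the LJ
#' minimum distance 2^(1/6) sigma_ij the energy is
#' `U_LJ(r) + (1 - lambda_ij) * eps`;
#' beyond it, `lambda_ij * U_LJ(r)`. The whole form is shifted so that
#' `U(cutoff) = 0` and is continuous at the splice point.
#'
#' @param r Distance(s), nm. Must be positive.
#' @param pair Pair parameters from [pair_params()] (or any list with
#'   `sigma_ij` and `lam_ij`).
#' @param eps Energy scale (kJ/mol).
#' @param cutoff Cutoff distance (nm); energy is 0 beyond it.
#' @return Energy in kJ/mol, vectorized over `r`.
#' @export
ashbaugh_hatch_energy <- function(r, pair, eps, cutoff = 2.0) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be positive and finite")
  lam <- pair$lam_ij
  if (lam < 0 || lam > 1) stop("lambda_ij must lie in [0, 1]")
  sij <- pair$sigma_ij
  ulj <- function(rr) 4 * eps * ((sij / rr)^12 - (sij / rr)^6)
  rmin <- 2^(1 / 6) * sij
  shift <- lam * ulj(cutoff)
  u <- ifelse(r <= rmin, ulj(r) + (1 - lam) * eps - shift, lam * ulj(r) - shift)
  ifelse(r > cutoff, 0, u)
}

#' Debye-Hueckel screened electrostatic pair potential
#'
#' `U(r) = qq * B * exp(-r / debye_length) / r`, shifted to zero at the
#' cutoff, where `B` is the Bjerrum prefactor of the solvent
#' (`e^2 NA / (4 pi eps0 eps_r)` in kJ nm/mol).
#'
#' @param r Distance(s), nm.
#' @param qq Product of the two charges (e^2).
#' @param dh Debye parameters from [compute_debye_length()].
#' @param cutoff Cutoff (nm).
#' @return Energy in kJ/mol, vectorized over `r`.
#' @export
debye_huckel_energy <- function(r, qq, dh, cutoff = 4.0) {
  if (any(!is.finite(r)) || any(r <= 0) || !is.finite(qq)) stop("non-finite input")
  pref <- dh$bjerrum_prefactor
  if (is.finite(dh$debye_length)) {
    kappa <- 1 / dh$debye_length
    u <- pref * qq * (exp(-kappa * r) / r - exp(-kappa * cutoff) / cutoff)
  } else {
    u <- pref * qq * (1 / r - 1 / cutoff)
  }
  ifelse(r > cutoff, 0, u)
}

#' Debye screening length of the electrolyte
#'
#' Closed-form inverse screening length for a 1:1 electrolyte:
#' `kappa^-1 = sqrt(eps0 eps_r kB T / (2 NA e^2 I))` with `I` in mol/L.
#' `I = 0` returns an infinite Debye length (unscreened Coulomb).
#'
#' @param ionic_strength Ionic strength, mol/L. Must be >= 0.
#' @param temperature Temperature, K.
#' @param dielectric Relative permittivity.
#' @return An object of class `debye_params`: list with `ionic_strength`,
#'   `debye_length` (nm, possibly `Inf`), `bjerrum_prefactor` (kJ nm/mol per
#'   e^2), `temperature`, `dielectric`.
#' @export
#' @examples
#' compute_debye_length(0.15, 300, 80)$debye_length # ~0.79 nm
compute_debye_length <- function(ionic_strength, temperature = 300, dielectric = 80) {
  if (!is.finite(ionic_strength) || ionic_strength < 0)
    stop("ionic_strength must be >= 0")
  eps0 <- 8.8541878128e-12   # F/m
  e <- 1.602176634e-19       # C
  NA_ <- 6.02214076e23
  kB_SI <- 1.380649e-23
  if (ionic_strength == 0) {
    lam <- Inf
  } else {
    kappa2 <- 2 * NA_ * e^2 * ionic_strength * 1e3 /
      (eps0 * dielectric * kB_SI * temperature)
    lam <- 1e9 / sqrt(kappa2) # m -> nm
  }
  structure(list(ionic_strength = ionic_strength,
                 debye_length = lam,
                 bjerrum_prefactor = .coulomb_const / dielectric,
                 temperature = temperature, dielectric = dielectric),
            class = "debye_params")
}

# Bonded parameter defaults of the model (harmonic bonds; angles only on
# structured LARKS segments).
#' Bonded interaction parameters
#'
#' @param bond_length Equilibrium bond length r0 (nm).
#' @param bond_k Bond force constant (kJ/mol/nm^2).
#' @param angle_theta0 Equilibrium angle for structured segments (rad);
#'   straight (pi) mimics the extended cross-beta strand.
#' @param angle_k Angle force constant (kJ/mol/rad^2).
#' @return A list of class `bonded_params`.
#' @export
bonded_params <- function(bond_length = 0.38, bond_k = 8033,
                          angle_theta0 = pi, angle_k = 50) {
  stopifnot(bond_k > 0, bond_length > 0, angle_k >= 0)
  structure(list(bond_length = bond_length, bond_k = bond_k,
                 angle_theta0 = angle_theta0, angle_k = angle_k),
            class = "bonded_params")
}

#' Bonded energies of a configuration
#'
#' Harmonic bond energy over consecutive intra-chain pairs and harmonic angle
#' energy over triplets inside structured LARKS segments. A fully disordered
#' system has angle energy exactly zero.
#'
#' @param config A `cg_config` (see [build_bulk()]).
#' @param topology A `cg_topology` (see [build_topology()]).
#' @param state Optional LARKS state ledger ([larks_ledger()]); `NULL` means
#'   fully disordered.
#' @param bonded [bonded_params()].
#' @return List with `bond` and `angle` energies (kJ/mol).
#' @export
bonded_energy <- function(config, topology, state = NULL, bonded = bonded_params()) {
  pos <- config$positions
  box <- config$box
  b <- topology$bonds
  if (any(b < 1) || any(b > nrow(pos))) stop("bond indices outside topology")
  d <- pos[b[, 1], , drop = FALSE] - pos[b[, 2], , drop = FALSE]
  d <- sweep_minimum_image(d, box)
  r <- sqrt(rowSums(d^2))
  e_bond <- sum(0.5 * bonded$bond_k * (r - bonded$bond_length)^2)
  ang <- structured_angle_triplets(topology, state)
  e_angle <- 0
  if (nrow(ang) > 0) {
    for (k in seq_len(nrow(ang))) {
      r1 <- sweep_minimum_image(pos[ang[k, 1], , drop = FALSE] - pos[ang[k, 2], , drop = FALSE], box)
      r2 <- sweep_minimum_image(pos[ang[k, 3], , drop = FALSE] - pos[ang[k, 2], , drop = FALSE], box)
      cth <- sum(r1 * r2) / (sqrt(sum(r1^2)) * sqrt(sum(r2^2)))
      th <- acos(max(-1, min(1, cth)))
      e_angle <- e_angle + 0.5 * bonded$angle_k * (th - bonded$angle_theta0)^2
    }
  }
  list(bond = e_bond, angle = e_angle)
}

# minimum-image displacement matrix for an orthorhombic box
sweep_minimum_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# angle triplets (n x 3 bead indices) inside structured LARKS
structured_angle_triplets <- function(topology, state) {
  if (is.null(state)) return(matrix(integer(0), ncol = 3))
  st <- topology$larks[state$state == "structured", , drop = FALSE]
  if (nrow(st) == 0) return(matrix(integer(0), ncol = 3))
  out <- lapply(seq_len(nrow(st)), function(i) {
    beads <- st$bead_start[i]:st$bead_end[i]
    if (length(beads) < 3) return(NULL)
    cbind(beads[1:(length(beads) - 2)], beads[2:(length(beads) - 1)], beads[3:length(beads)])
  })
  m <- do.call(rbind, out)
  if (is.null(m)) matrix(integer(0), ncol = 3) else m
}

#' Total potential energy and forces
#'
#' Assembles all model terms (Ashbaugh-Hatch, Debye-Hueckel, bonds, structured
#' angles) for a configuration, including the cross-beta pair-strength rescaling
#' carried by the LARKS state ledger. Forces are the analytic gradient,
#' `-dU/dx`, and obey Newton's third law pairwise.
#'
#' @inheritParams bonded_energy
#' @param table [forcefield_table()].
#' @param dh [compute_debye_length()].
#' @return List with per-term energies (kJ/mol), total `energy`, an `n x 3`
#'   `forces` matrix (kJ/mol/nm) and the 6-component virial tensor.
#' @export
total_energy_forces <- function(config, topology, table, dh, state = NULL,
                                bonded = bonded_params()) {
  ang <- structured_angle_triplets(topology, state)
  scale <- ledger_pair_scale(topology, state)
  larks_id <- topology$beads$larks_instance
  larks_id[is.na(larks_id)] <- 0L
  kappa <- if (is.finite(dh$debye_length)) 1 / dh$debye_length else 0
  cg_energy_forces_cpp(config$positions, config$box,
                       topology$beads$chain,
                       topology$beads$sigma, topology$beads$lambda,
                       topology$beads$charge,
                       topology$bonds, bonded$bond_length, bonded$bond_k,
                       ang, bonded$angle_theta0, bonded$angle_k,
                       table$eps_ah, table$cutoff_ah, table$cutoff_dh,
                       dh$bjerrum_prefactor, kappa,
                       as.integer(larks_id), scale)
}

# pair-scale matrix (n_larks x n_larks) from a ledger; identity when NULL
ledger_pair_scale <- function(topology, state) {
  n <- nrow(topology$larks)
  m <- matrix(1, max(n, 1), max(n, 1))
  if (!is.null(state) && !is.null(state$pair_scale)) m <- state$pair_scale
  m
}
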