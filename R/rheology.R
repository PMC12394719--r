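#' Shear-stress relaxation modulus by the Green-Kubo route
#'
#' `G(t) = V/(kB T) <sigma_ab(0) sigma_ab(t)>`, averaged over the three
#' independent off-diagonal components of the pressure tensor, followed by a
#' Maxwell-mode fit whose integral gives the zero-shear viscosity
#' `eta = sum(G_i tau_i)`.
#'
#' @param traj A `cg_trajectory` (NVT, fixed box), or a numeric matrix of
#'   off-diagonal stress components (columns = components, model units) with
#'   `volume`, `temperature` and `dt` supplied.
#' @param volume Box volume (nm^3); taken from the trajectory if omitted.
#' @param temperature K; taken from the trajectory parameters if omitted.
#' @param dt Frame spacing (ps); inferred from trajectory times if omitted.
#' @param max_lag Maximum lag (frames). Must not exceed 10% of the series
#'   length; that is also the default.
#' @param max_modes Maximum Maxwell modes tried by the fit.
#' @return Object of class `relaxation_modulus`: tibble `gt` (`time`, `G`),
#'   `modes` (tibble `G_i`, `tau_i`), `eta`, `volume`, `temperature`.
#' @export
relaxation_modulus <- function(traj, volume = NULL, temperature = NULL,
                               dt = NULL, max_lag = NULL, max_modes = 4) {
  if (inherits(traj, "cg_trajectory")) {
    stress <- traj$pressure[, 4:6, drop = FALSE]
    if (is.null(volume)) volume <- prod(traj$box[1, ])
    if (is.null(temperature)) temperature <- traj$params$temperature
    if (is.null(dt)) dt <- diff(traj$time[1:2])
  } else {
    stress <- as.matrix(traj)
    if (is.null(volume) || is.null(temperature) || is.null(dt))
      stop("volume, temperature and dt are required for a raw stress matrix")
  }
  n <- nrow(stress)
  if (is.null(max_lag)) max_lag <- floor(0.1 * n)
  if (max_lag > 0.1 * n)
    stop("series too short: max lag exceeds 10% of the series length")
  if (max_lag < 2) stop("series too short for a relaxation modulus")
  acfs <- vapply(seq_len(ncol(stress)), function(k) {
    stats::acf(stress[, k], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1))
  G <- volume / (.kB * temperature) * rowMeans(acfs)
  gt <- tibble::tibble(time = (0:max_lag) * dt, G = G)
  modes <- fit_maxwell_modes(gt$time, gt$G, max_modes = max_modes)
  structure(list(gt = gt, modes = modes, eta = sum(modes$G_i * modes$tau_i),
                 volume = volume, temperature = temperature),
            class = "relaxation_modulus")
}

#' Fit a sum of Maxwell modes to a relaxation modulus
#'
#' `G(t) ~ sum_i G_i exp(-t / tau_i)`, log-parameterized and fitted by
#' Levenberg-Marquardt. The mode count grows until the RMS improvement over
#' the previous count is below `tol` (default 5%).
#'
#' @param t Lag times.
#' @param G Modulus values.
#' @param max_modes Maximum number of modes.
#' @param tol Relative RMS improvement threshold for adding a mode.
#' @return Tibble with columns `G_i`, `tau_i` (sorted by `tau_i`).
#' @export
fit_maxwell_modes <- function(t, G, max_modes = 4, tol = 0.05) {
  keep <- is.finite(G) & t >= 0
  t <- t[keep]; G <- G[keep]
  t_pos <- t[t > 0]
  tau0 <- if (length(t_pos)) exp(mean(log(range(t_pos)))) else 1
  g0 <- max(abs(G[1]), 1e-12)
  best <- NULL; best_rms <- Inf
  for (K in seq_len(max_modes)) {
    taus <- tau0 * 10^(seq(-1, 1, length.out = K))
    start <- c(log(rep(g0 / K, K)), log(taus))
    fn <- function(p) {
      Gi <- exp(p[1:K]); ti <- exp(p[(K + 1):(2 * K)])
      pred <- vapply(t, function(tt) sum(Gi * exp(-tt / ti)), numeric(1))
      pred - G
    }
    fit <- try(minpack.lm::nls.lm(par = start, fn = fn,
                                  control = minpack.lm::nls.lm.control(maxiter = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    rms <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rms < best_rms * (1 - tol)) {
      best <- fit; best_rms <- rms; best_K <- K
    } else break
  }
  if (is.null(best)) stop("Maxwell-mode fit failed")
  Gi <- exp(best$par[1:best_K]); ti <- exp(best$par[(best_K + 1):(2 * best_K)])
  ord <- order(ti)
  tibble::tibble(G_i = Gi[ord], tau_i = ti[ord])
}

#' @export
print.relaxation_modulus <- function(x, ...) {
  cat(sprintf("<relaxation_modulus> %d lags, %d Maxwell mode(s), eta = %.3g kJ ps/mol/nm^3\n",
              nrow(x$gt), nrow(x$modes), x$eta))
  invisible(x)
}

#' Storage and loss moduli of a Maxwell-mode spectrum
#'
#' Closed forms `G'(w) = sum G_i w^2 tau_i^2 / (1 + w^2 tau_i^2)` and
#' `G''(w) = sum G_i w tau_i / (1 + w^2 tau_i^2)`; a mode with `tau_i = Inf`
#' is a pure elastic plateau contributing `G_i` to the storage modulus at all
#' frequencies. The material is classified
#' `"solid"` when the storage modulus dominates over the lowest frequency
#' decade of the grid (gel/solid-like response), `"liquid"` otherwise.
#'
#' @param modes Tibble with `G_i`, `tau_i` (e.g. from
#'   [relaxation_modulus()]`$modes`), or a `relaxation_modulus`.
#' @param omega Frequency grid (rad/ps); default 4 decades around the
#'   relaxation times.
#' @return Object of class `viscoelastic_spectrum`: tibble `spectrum`
#'   (`omega`, `G_storage`, `G_loss`) plus `classification`.
#' @export
moduli_spectrum <- function(modes, omega = NULL) {
  if (inherits(modes, "relaxation_modulus")) modes <- modes$modes
  stopifnot(nrow(modes) >= 1)
  if (is.null(omega)) {
    finite <- modes$tau_i[is.finite(modes$tau_i)]
    if (length(finite) == 0) finite <- 1
    w0 <- 1 / max(finite); w1 <- 1 / min(finite)
    omega <- 10^seq(log10(w0) - 2, log10(w1) + 2, length.out = 80)
  }
  inf_G <- sum(modes$G_i[!is.finite(modes$tau_i)])
  fin <- modes[is.finite(modes$tau_i), , drop = FALSE]
  gp <- inf_G + vapply(omega, function(w)
    sum(fin$G_i * w^2 * fin$tau_i^2 / (1 + w^2 * fin$tau_i^2)), numeric(1))
  gl <- vapply(omega, function(w)
    sum(fin$G_i * w * fin$tau_i / (1 + w^2 * fin$tau_i^2)), numeric(1))
  # a permanent (infinite-tau) plateau dominates as omega -> 0 by construction;
  # otherwise compare the moduli over the lowest frequency decade of the grid
  low <- omega <= min(omega) * 10
  classification <- if (inf_G > 0 || mean(gp[low]) > mean(gl[low])) "solid" else "liquid"
  structure(list(spectrum = tibble::tibble(omega = omega, G_storage = gp,
                                           G_loss = gl),
                 classification = classification, modes = modes),
            class = "viscoelastic_spectrum")
}

#' @export
print.viscoelastic_spectrum <- function(x, ...) {
  cat(sprintf("<viscoelastic_spectrum> %d frequencies, classification: %s\n",
              nrow(x$spectrum), x$classification))
  invisible(x)
}

#' Elastic plateau mode of a cross-linked cross-beta network
#'
#' Once LARKS have structured, their strengthened inter-chain pairs act as
#' permanent cross-links on all practical timescales, and the affine network
#' model gives an elastic plateau `G_p = nu kB T` with `nu` the cross-link
#' number density. The plateau is returned as a Maxwell mode with a very long
#' relaxation time so it can be appended to the measured relaxation modes of
#' the fast dynamics; appending it to a liquid spectrum flips the
#' low-frequency classification to solid, mirroring the aged-condensate
#' rheology. (At small system sizes the plateau sits below the statistical
#' noise floor of a Green-Kubo estimate, which is why it is computed from the
#' ledger rather than extracted from the stress autocorrelation.)
#'
#' @param ledger A [larks_ledger()] after ageing.
#' @param volume Box volume, nm^3.
#' @param temperature K.
#' @param tau Relaxation time of the permanent network; `Inf` (the default)
#'   makes it a pure elastic plateau in [moduli_spectrum()].
#' @return Tibble with one Maxwell mode (`G_i`, `tau_i`); zero rows when no
#'   cross-links exist.
#' @export
network_plateau_mode <- function(ledger, volume, temperature, tau = Inf) {
  sc <- ledger$pair_scale
  n_links <- sum(sc[upper.tri(sc)] > 1)
  if (n_links == 0) return(tibble::tibble(G_i = numeric(), tau_i = numeric()))
  tibble::tibble(G_i = n_links / volume * .kB * temperature, tau_i = tau)
}

#' Intermolecular residue-residue contact map
#'
#' Two residues on different chains are in contact when their minimum-image
#' distance is below `factor * sigma_ij` (`sigma_ij` the mean diameter;
#' `factor = 1.2` sits just outside the pair-potential minimum at
#' ~1.12 sigma_ij). Frequencies are percentages over frames and chain
#' pairings; homotypic maps are symmetric.
#'
#' @param traj A `cg_trajectory`.
#' @param topology Matching `cg_topology`.
#' @param role_a,role_b Sequence names (or `"protein"`/`"peptide"` kinds)
#'   selecting the two chain sets.
#' @param factor Contact threshold in units of sigma_ij.
#' @return Object of class `contact_map`: `matrix` (percent, `len_a x len_b`),
#'   `role_a`, `role_b`, `n_frames`, `n_pairings`.
#' @export
contact_map <- function(traj, topology, role_a, role_b = role_a, factor = 1.2) {
  sel <- function(role) {
    ch <- topology$chains
    hits <- ch$chain[ch$seq_name == role | ch$kind == role]
    if (length(hits) == 0) stop("role '", role, "' not present in the system")
    hits
  }
  ca <- sel(role_a); cb <- sel(role_b)
  len_a <- unique(topology$chains$length[topology$chains$chain %in% ca])
  len_b <- unique(topology$chains$length[topology$chains$chain %in% cb])
  stopifnot(length(len_a) == 1, length(len_b) == 1)
  counts <- cg_contact_counts_cpp(traj$frames, traj$box,
                                  topology$beads$chain, topology$beads$resid,
                                  topology$beads$sigma,
                                  as.integer(ca), as.integer(cb),
                                  len_a, len_b, factor)
  homotypic <- setequal(ca, cb)
  n_pairings <- if (homotypic) length(ca) * (length(ca) - 1) / 2 else
    length(ca) * length(cb)
  pct <- counts / (length(traj$frames) * n_pairings) * 100
  structure(list(matrix = pct, role_a = role_a, role_b = role_b,
                 n_frames = length(traj$frames), n_pairings = n_pairings,
                 factor = factor),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s x %s (%d x %d), max %.1f%% over %d frames\n",
              x$role_a, x$role_b, nrow(x$matrix), ncol(x$matrix),
              max(x$matrix), x$n_frames))
  invisible(x)
}

#' Write a contact map as a TSV matrix with residue-index headers
#' @param map A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map_tsv <- function(map, path) {
  m <- map$matrix
  rownames(m) <- seq_len(nrow(m)); colnames(m) <- seq_len(ncol(m))
  write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

# unwrap chain coordinates so no bond crosses the periodic boundary
unwrap_chain <- function(p, box) {
  if (nrow(p) < 2) return(p)
  d <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  out <- matrix(0, nrow(p), 3)
  for (k in 1:3) {
    dk <- d[, k] - box[k] * round(d[, k] / box[k])
    out[, k] <- p[1, k] + c(0, cumsum(dk))
  }
  out
}

#' Radius of gyration per chain and frame
#'
#' Mass-weighted Rg from unwrapped chain coordinates (chains with a bond
#' longer than half the box are unwrapped first).
#'
#' @param traj A `cg_trajectory`.
#' @param topology Matching `cg_topology`.
#' @param chains Chain ids to include (default: all protein chains, falling
#'   back to all chains).
#' @return Tibble `time`, `chain`, `rg` (nm).
#' @export
radius_of_gyration <- function(traj, topology, chains = NULL) {
  if (is.null(chains)) {
    chains <- topology$chains$chain[topology$chains$kind == "protein"]
    if (length(chains) == 0) chains <- topology$chains$chain
  }
  out <- list()
  for (f in seq_along(traj$frames)) {
    pos <- traj$frames[[f]]; box <- traj$box[f, ]
    for (c_id in chains) {
      beads <- which(topology$beads$chain == c_id)
      p <- pos[beads, , drop = FALSE]
      d <- diff(p)
      if (any(abs(d) > matrix(box / 2, nrow(d), 3, byrow = TRUE)))
        p <- unwrap_chain(p, box)
      m <- topology$beads$mass[beads]
      com <- colSums(p * m) / sum(m)
      rg <- sqrt(sum(m * rowSums(sweep(p, 2, com)^2)) / sum(m))
      out[[length(out) + 1]] <- tibble::tibble(time = traj$time[f],
                                               chain = c_id, rg = rg)
    }
  }
  dplyr::bind_rows(out)
}

#' Mean-squared displacement of chain centres of mass
#'
#' Chain displacements are measured relative to the instantaneous system
#' centre of mass by default, which removes the collective drift a
#' non-momentum-conserving (Langevin) thermostat imparts and isolates the
#' intra-condensate mobility the arrest diagnostics care about.
#'
#' @param traj A `cg_trajectory` (unwrapped positions).
#' @param topology Matching `cg_topology`.
#' @param chains Chain ids (default protein chains).
#' @param remove_com Subtract the global mass-weighted centre of mass per
#'   frame.
#' @return Tibble `lag` (ps), `msd` (nm^2); `msd(0) = 0`.
#' @export
chain_msd <- function(traj, topology, chains = NULL, remove_com = TRUE) {
  if (is.null(chains)) {
    chains <- topology$chains$chain[topology$chains$kind == "protein"]
    if (length(chains) == 0) chains <- topology$chains$chain
  }
  nf <- length(traj$frames)
  coms <- array(NA_real_, c(nf, length(chains), 3))
  all_m <- topology$beads$mass
  for (f in seq_len(nf)) {
    pos <- traj$frames[[f]]
    gcom <- if (remove_com) colSums(pos * all_m) / sum(all_m) else c(0, 0, 0)
    for (j in seq_along(chains)) {
      beads <- which(topology$beads$chain == chains[j])
      m <- topology$beads$mass[beads]
      coms[f, j, ] <- colSums(pos[beads, , drop = FALSE] * m) / sum(m) - gcom
    }
  }
  dtf <- diff(traj$time[1:2])
  lags <- 0:(nf - 1)
  msd <- vapply(lags, function(l) {
    if (l == 0) return(0)
    d <- coms[(1 + l):nf, , , drop = FALSE] - coms[1:(nf - l), , , drop = FALSE]
    mean(apply(d, c(1, 2), function(v) sum(v^2)))
  }, numeric(1))
  tibble::tibble(lag = lags * dtf, msd = msd)
}

#' Diffusion coefficient from the MSD slope
#'
#' `D = slope(MSD)/6` over the fit window (default: the central third of the
#' available lags), with a log-log linearity diagnostic: a local exponent
#' below 0.8 flags sub-diffusive, arrested dynamics instead of reporting D.
#'
#' @param traj A `cg_trajectory`, or a precomputed tibble from [chain_msd()].
#' @param topology Matching `cg_topology` (ignored for a precomputed MSD).
#' @param chains Chain selector, as in [chain_msd()].
#' @param fit_window Two lag fractions delimiting the fit range.
#' @return List of class `diffusion_estimate`: `D` (nm^2/ps; `NA` when
#'   arrested), `arrested`, `exponent`, `msd`.
#' @export
diffusion_coefficient <- function(traj, topology = NULL, chains = NULL,
                                  fit_window = c(1 / 3, 2 / 3)) {
  msd <- if (is.data.frame(traj)) tibble::as_tibble(traj) else
    chain_msd(traj, topology, chains)
  sel <- msd$lag >= fit_window[1] * max(msd$lag) &
    msd$lag <= fit_window[2] * max(msd$lag) & msd$lag > 0
  if (sum(sel) < 3) stop("too few lags in the fit window")
  x <- msd$lag[sel]; y <- msd$msd[sel]
  if (all(y <= 0) || max(y) < 1e-12)
    return(structure(list(D = 0, arrested = TRUE, exponent = 0, msd = msd),
                     class = "diffusion_estimate"))
  pos <- y > 0
  expo <- unname(coef(stats::lm(log(y[pos]) ~ log(x[pos])))[2])
  if (expo < 0.8)
    return(structure(list(D = NA_real_, arrested = TRUE, exponent = expo,
                          msd = msd),
                     class = "diffusion_estimate"))
  slope <- unname(coef(stats::lm(y ~ x))[2])
  structure(list(D = slope / 6, arrested = FALSE, exponent = expo, msd = msd),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  if (x$arrested) cat(sprintf("<diffusion_estimate> arrested (exponent %.2f)\n", x$exponent))
  else cat(sprintf("<diffusion_estimate> D = %.3g nm^2/ps (exponent %.2f)\n", x$D, x$exponent))
  invisible(x)
}
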