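#' Peptide-screening campaign configuration
#'
#' Describes a screening campaign: the target protein, the candidate peptides
#' with their stoichiometries, the NPT temperature ladder used for stability
#' bracketing, the reduced ageing temperature and replicate seeds, plus the
#' step budgets that set the campaign scale.
#'
#' @param protein A [sequence_record()] for the condensate-forming protein.
#' @param larks LARKS annotation tibble for the protein.
#' @param peptides Named character vector of repeat-notation specs (may be
#'   empty for a pure-protein campaign).
#' @param mass_ratios Mass ratios (mg peptide / mg protein) to scan.
#' @param temperatures NPT temperature ladder (K), ascending.
#' @param reduced_temperature T/Tc used for ageing runs (< 1).
#' @param replicates Number of independent ageing trajectories per system.
#' @param seeds Distinct integer velocity seeds, one per replicate.
#' @param protein_copies Protein chains per box.
#' @param density Pre-ageing bulk density (g/L) used to build systems.
#' @param table A [forcefield_table()].
#' @param ionic_strength mol/L.
#' @param op_params [order_parameter_params()].
#' @param n_steps_npt,n_steps_ageing Step budgets per run.
#' @param dt,friction Integrator settings.
#' @param fit_kinetics Fit the secondary-nucleation model per replicate (the
#'   slowest analysis step; disable for quick structural scans).
#' @return List of class `campaign_config`.
#' @export
campaign_config <- function(protein, larks, peptides = character(),
                            mass_ratios = 0.075, temperatures,
                            reduced_temperature = 0.95,
                            replicates = 6, seeds = seq_len(replicates),
                            protein_copies = 8, density = 600,
                            table = forcefield_table(),
                            ionic_strength = 0.15,
                            op_params = order_parameter_params(),
                            n_steps_npt = 5000, n_steps_ageing = 50000,
                            dt = 0.01, friction = 0.01, fit_kinetics = TRUE) {
  if (anyDuplicated(seeds)) stop("replicate seeds must be pairwise distinct")
  if (length(seeds) != replicates) stop("need one seed per replicate")
  if (reduced_temperature >= 1) stop("reduced ageing temperature must be < 1")
  if (is.unsorted(temperatures)) stop("temperature ladder must be ascending")
  structure(list(protein = protein, larks = larks, peptides = peptides,
                 mass_ratios = mass_ratios, temperatures = temperatures,
                 reduced_temperature = reduced_temperature,
                 replicates = as.integer(replicates), seeds = as.integer(seeds),
                 protein_copies = as.integer(protein_copies), density = density,
                 table = table, ionic_strength = ionic_strength,
                 op_params = op_params,
                 n_steps_npt = as.integer(n_steps_npt),
                 n_steps_ageing = as.integer(n_steps_ageing),
                 dt = dt, friction = friction,
                 fit_kinetics = isTRUE(fit_kinetics)),
            class = "campaign_config")
}

campaign_systems <- function(config) {
  rows <- tibble::tibble(system = "pure", peptide = NA_character_,
                         mass_ratio = 0)
  for (pep in names(config$peptides)) {
    for (mr in config$mass_ratios) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        system = sprintf("%s@%.3g", pep, mr), peptide = pep, mass_ratio = mr))
    }
  }
  rows
}

build_campaign_system <- function(config, peptide_spec, mass_ratio,
                                  temperature, seed) {
  recs <- list(config$protein); copies <- config$protein_copies
  if (!is.na(peptide_spec)) {
    pep <- expand_repeat_notation(config$peptides[[peptide_spec]],
                                  name = peptide_spec, kind = "peptide")
    st <- resolve_stoichiometry(mass_ratio, config$protein, pep,
                                config$protein_copies, config$table)
    if (st$peptide_copies > 0) {
      recs <- c(recs, list(pep)); copies <- c(copies, st$peptide_copies)
    }
  }
  topo <- build_topology(recs, copies, config$table, config$larks)
  cfg <- build_bulk(topo, config$density, seed = seed)
  sys <- cg_system(topo, cfg, config$table,
                   compute_debye_length(config$ionic_strength, temperature,
                                        config$table$dielectric))
  minimize_config(sys)
}

#' Phase-stability scan over the campaign systems
#'
#' For each system (the pure condensate plus every peptide/stoichiometry
#' combination) runs the NPT ladder at P = 0, classifies each run as
#' condensed or diluted, and brackets the critical solution temperature.
#' Fails fast on a non-monotone stability sequence.
#'
#' @param config A [campaign_config()].
#' @param base_seed Seed offset for build/velocity streams.
#' @return Tibble of class `phase_scan`: one row per system with the bracket,
#'   the condensed-phase density at the warmest stable temperature, and the
#'   per-temperature stability flags (list column).
#' @export
run_phase_scan <- function(config, base_seed = 1) {
  systems <- campaign_systems(config)
  out <- list()
  for (i in seq_len(nrow(systems))) {
    flags <- character(length(config$temperatures))
    dens <- rep(NA_real_, length(config$temperatures))
    for (j in seq_along(config$temperatures)) {
      Tj <- config$temperatures[j]
      sys <- build_campaign_system(config, systems$peptide[i],
                                   systems$mass_ratio[i], Tj, base_seed + i)
      params <- integrator_params(config$dt, config$friction, Tj,
                                  seed = base_seed * 1000L + i * 100L + j)
      tr <- run_npt(sys, params, barostat_params(pressure = 0),
                    n_steps = config$n_steps_npt,
                    thin = max(1, config$n_steps_npt %/% 50))
      flags[j] <- classify_stability(tr)
      s <- trajectory_summary(tr)
      dens[j] <- mean(tail(s$density, max(1, floor(nrow(s) / 4))))
    }
    br <- tc_bracket_from_npt(tibble::tibble(T = config$temperatures,
                                             stable = flags == "condensed"))
    stable_idx <- which(flags == "condensed")
    out[[i]] <- tibble::tibble(
      system = systems$system[i], peptide = systems$peptide[i],
      mass_ratio = systems$mass_ratio[i],
      T_stable_max = br$T_stable_max, T_unstable_min = br$T_unstable_min,
      tc_estimate = br$estimate, tc_halfwidth = br$halfwidth,
      density_condensed = if (length(stable_idx)) dens[max(stable_idx)] else NA_real_,
      flags = list(setNames(flags, config$temperatures)))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("phase_scan", class(res))
  res
}

#' Ageing campaign with replicate statistics and peptide ranking
#'
#' Runs `replicates` independent ageing trajectories per system (distinct
#' velocity seeds) at the configured density, collects half-times and
#' nucleation lag times (right-censored at the step budget when no event
#' occurs), tests every mixture against the pure system with a Mann-Whitney U
#' test on t1/2, fits the secondary-nucleation model where identifiable, and
#' ranks systems by mean half-time (all-censored systems rank last).
#'
#' @param config A [campaign_config()].
#' @param temperature Ageing temperature (K); by default
#'   `reduced_temperature * Tc` requires `tc` to be given.
#' @param tc Critical temperature estimate (K) used to place the ageing
#'   temperature when `temperature` is missing.
#' @return List of class `screening_report`: `table` (per-system tibble) and
#'   `replicates` (per-trajectory tibble).
#' @export
run_ageing_campaign <- function(config, temperature = NULL, tc = NULL) {
  if (is.null(temperature)) {
    if (is.null(tc)) stop("give either temperature or tc")
    temperature <- absolute_temperature(config$reduced_temperature, tc)
  }
  systems <- campaign_systems(config)
  budget_time <- config$n_steps_ageing * config$dt
  reps <- list(); per_sys <- list()
  for (i in seq_len(nrow(systems))) {
    th <- lag <- rep(NA_real_, config$replicates)
    nlogkn <- rep(NA_real_, config$replicates)
    for (r in seq_len(config$replicates)) {
      sys <- build_campaign_system(config, systems$peptide[i],
                                   systems$mass_ratio[i], temperature, 7000L + i)
      params <- integrator_params(config$dt, config$friction, temperature,
                                  seed = config$seeds[r])
      res <- ageing_run(sys, params, config$op_params,
                        n_steps = config$n_steps_ageing)
      th[r] <- half_time(res$curve)
      lag[r] <- nucleation_lag_time(res$events)
      if (config$fit_kinetics) {
        fit <- fit_kinetic_model(res$curve)
        if (isTRUE(fit$converged) && !isTRUE(fit$censored))
          nlogkn[r] <- fit$neg_log10_kn
      }
      reps[[length(reps) + 1]] <- tibble::tibble(
        system = systems$system[i], seed = config$seeds[r],
        t_half = th[r], lag = lag[r],
        censored = !is.finite(lag[r]),
        final_fraction = tail(res$curve$structured_fraction, 1))
    }
    per_sys[[i]] <- list(t_half = th, lag = lag, nlogkn = nlogkn)
  }
  reps <- dplyr::bind_rows(reps)
  pure_th <- per_sys[[1]]$t_half
  # censored trajectories enter the box plots at the budget
  as_boxdata <- function(x) ifelse(is.finite(x), x, budget_time)
  rows <- list()
  for (i in seq_len(nrow(systems))) {
    th <- per_sys[[i]]$t_half
    st <- replicate_stats(as_boxdata(th), as_boxdata(per_sys[[i]]$lag))
    p <- if (i == 1) NA_real_ else
      mann_whitney_u(as_boxdata(th), as_boxdata(pure_th))$p_value
    rows[[i]] <- tibble::tibble(
      system = systems$system[i], peptide = systems$peptide[i],
      mass_ratio = systems$mass_ratio[i],
      mean_t_half = st$mean[1], median_t_half = st$median[1],
      mean_lag = st$mean[2], n_censored = sum(!is.finite(th)),
      all_censored = all(!is.finite(th)),
      neg_log10_kn = if (any(is.finite(per_sys[[i]]$nlogkn)))
        mean(per_sys[[i]]$nlogkn, na.rm = TRUE) else NA_real_,
      p_vs_pure = p)
  }
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::arrange(tab, dplyr::desc(.data$all_censored),
                        dplyr::desc(.data$mean_t_half))
  tab$rank <- seq_len(nrow(tab))
  tab <- dplyr::arrange(tab, match(tab$system, systems$system))
  structure(list(table = tab, replicates = reps,
                 temperature = temperature, budget_time = budget_time),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d systems at T = %.0f K\n",
              nrow(x$table), x$temperature))
  print(x$table)
  invisible(x)
}

#' Merge phase and ageing results into a screening summary
#'
#' Adds the peptide-acceptance flag of the screening protocol: a candidate
#' decelerator lowers Tc by 1-5% of the pure-system Tc at a stoichiometry of
#' at most 0.1 mg peptide / mg protein.
#'
#' @param phase A [run_phase_scan()] result.
#' @param ageing A [run_ageing_campaign()] result.
#' @return Tibble with Delta Tc (K and fraction), condensed-density change
#'   (%), the ageing statistics and the candidate flag.
#' @export
screening_summary <- function(phase, ageing) {
  pure <- phase[phase$system == "pure", ]
  out <- dplyr::left_join(
    dplyr::select(phase, "system", "peptide", "mass_ratio", "tc_estimate",
                  "tc_halfwidth", "density_condensed"),
    dplyr::select(ageing$table, -"peptide", -"mass_ratio"), by = "system")
  out$delta_tc <- out$tc_estimate - pure$tc_estimate
  out$delta_tc_frac <- out$delta_tc / pure$tc_estimate
  out$density_change_pct <- 100 * (out$density_condensed - pure$density_condensed) /
    pure$density_condensed
  out$candidate <- out$system != "pure" &
    out$delta_tc_frac >= -0.05 & out$delta_tc_frac <= -0.01 &
    out$mass_ratio <= 0.1
  out
}
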