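#' Normalize a raw cross-beta count series to an ageing curve
#'
#' Divides a non-decreasing raw count series by a plateau estimate (mean over
#' the final window) and caps at 1. A curve still rising at its end (last
#' point above the plateau estimate by more than 2%, or strictly increasing
#' throughout with no flattening) is flagged censored.
#'
#' @param time Time stamps (ps or reduced units).
#' @param raw Raw cross-beta counts, non-decreasing.
#' @param plateau_window_fraction Final fraction of the series used for the
#'   plateau estimate.
#' @return Tibble of class `ageing_curve`: `time_ps`, `structured_count`,
#'   `structured_fraction` (in \[0, 1\]), with attributes `plateau` and
#'   `censored`.
#' @export
normalize_curve <- function(time, raw, plateau_window_fraction = 0.1) {
  if (is.unsorted(raw)) stop("raw counts must be non-decreasing")
  n <- length(raw)
  w <- max(2L, ceiling(n * plateau_window_fraction))
  tail_vals <- tail(raw, w)
  plateau <- mean(tail_vals)
  # censored: still rising within the plateau window
  censored <- plateau <= 0 ||
    (tail_vals[length(tail_vals)] > tail_vals[1] &&
       (tail_vals[length(tail_vals)] - tail_vals[1]) > 0.02 * plateau)
  frac <- if (plateau > 0) pmin(raw / plateau, 1) else rep(0, n)
  out <- tibble::tibble(time_ps = time, structured_count = raw,
                        structured_fraction = frac)
  attr(out, "plateau") <- plateau
  attr(out, "censored") <- censored
  class(out) <- c("ageing_curve", class(out))
  out
}

#' Half-time of an ageing curve
#'
#' Time at which the relative cross-beta concentration is halfway between its
#' initial value and its final plateau value, by linear interpolation.
#'
#' @param curve An `ageing_curve` (from [normalize_curve()] or
#'   [ageing_run()]), or any tibble with `time_ps` and `structured_fraction`.
#' @return Half-time in the curve's time units; `NA` for censored curves.
#' @export
half_time <- function(curve) {
  if (isTRUE(attr(curve, "censored"))) return(NA_real_)
  c0 <- curve$structured_fraction[1]
  cp <- tail(curve$structured_fraction, 1)
  target <- (c0 + cp) / 2
  above <- which(curve$structured_fraction >= target)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(curve$time_ps[1])
  t0 <- curve$time_ps[i - 1]; t1 <- curve$time_ps[i]
  y0 <- curve$structured_fraction[i - 1]; y1 <- curve$structured_fraction[i]
  if (y1 == y0) return(t1)
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}

#' Nucleation lag time from a transition event log
#'
#' The time at which the first inter-protein cross-beta sheet is formed, i.e.
#' the timestamp of the first transition event.
#'
#' @param events Events tibble (from [ageing_run()]), or a numeric vector of
#'   event times.
#' @return Lag time; `NA` (censored) when no event occurred.
#' @export
nucleation_lag_time <- function(events) {
  t <- if (is.numeric(events)) events else events$time_ps
  if (length(t) == 0) return(NA_real_)
  min(t)
}

#' Secondary-nucleation-dominated kinetic model
#'
#' Moment equations of the nucleation-elongation mechanism with secondary
#' nucleation: `dP/dt = kn m^nc + k2 m^n2 M`, `dM/dt = 2 kplus m P`, with
#' monomer conservation `m = mtot - M`. Returns the aggregated mass fraction
#' `M(t)/mtot`.
#'
#' @param params Named list/vector with `kn`, `k2`, `kplus`, `nc`, `n2`,
#'   `mtot` (rates >= 0; reaction orders >= 1).
#' @param times Time grid (first entry is t0).
#' @param M0,P0 Initial aggregate mass and number concentrations.
#' @return Tibble `time`, `mass_fraction`.
#' @export
simulate_kinetic_model <- function(params, times, M0 = 0, P0 = 0) {
  p <- as.list(params)
  stopifnot(all(unlist(p[c("kn", "k2", "kplus")]) >= 0), p$nc >= 1, p$n2 >= 1,
            p$mtot > 0)
  rhs <- function(t, y, parms) {
    m <- max(parms$mtot - y[2], 0)
    dP <- parms$kn * m^parms$nc + parms$k2 * m^parms$n2 * y[2]
    dM <- 2 * parms$kplus * m * y[1]
    list(c(dP, dM))
  }
  sol <- deSolve::ode(y = c(P = P0, M = M0), times = times, func = rhs,
                      parms = p, method = "lsoda", rtol = 1e-8, atol = 1e-10)
  tibble::tibble(time = sol[, "time"],
                 mass_fraction = pmin(sol[, "M"] / p$mtot, 1))
}

#' Fit the secondary-nucleation kinetic model to an ageing curve
#'
#' Least squares over log-spaced rate parameters against
#' [simulate_kinetic_model()] with the reaction orders and total monomer
#' concentration held fixed, from a small multistart. A single normalized
#' curve constrains only the rate products `kn * kplus` and `k2 * kplus`;
#' absolute nucleation rates are therefore reported after fixing the
#' elongation rate `kplus` (supply it in `fixed`; when absent all three rates
#' are fitted and only the products should be interpreted). Reports the
#' rates, the `-log10(kn)` deceleration metric and fit diagnostics.
#'
#' @param curve An `ageing_curve` (normalized, monotone) or tibble with
#'   `time_ps`/`structured_fraction` (or `time`/`mass_fraction`).
#' @param fixed Named list with `nc`, `n2`, `mtot` (defaults 2, 2, 1) and
#'   optionally `kplus`.
#' @param n_starts Multistart count.
#' @return Object of class `kinetic_fit` with elements `kn`, `k2`, `kplus`,
#'   `neg_log10_kn`, `rms`, `fitted` curve, `fixed`, `converged`.
#' @export
fit_kinetic_model <- function(curve, fixed = list(nc = 2, n2 = 2, mtot = 1),
                              n_starts = 4) {
  t <- if ("time" %in% names(curve)) curve$time else curve$time_ps
  y <- if ("mass_fraction" %in% names(curve)) curve$mass_fraction else
    curve$structured_fraction
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (max(y) - min(y) < 0.2)
    return(structure(list(kn = NA_real_, k2 = NA_real_, kplus = NA_real_,
                          neg_log10_kn = NA_real_, rms = NA_real_,
                          fitted = NULL, fixed = fixed, converged = FALSE,
                          censored = TRUE),
                     class = "kinetic_fit"))
  t0 <- t[1]
  ts <- t - t0
  t_half <- ts[which.min(abs(y - (min(y) + max(y)) / 2))]
  t_half <- max(t_half, diff(range(ts)) / 100)
  fix_kplus <- "kplus" %in% names(fixed) && is.finite(fixed$kplus %||% NA)
  fixed_orders <- fixed[setdiff(names(fixed), "kplus")]
  free <- if (fix_kplus) c("kn", "k2") else c("kn", "k2", "kplus")
  obj <- function(lp) {
    pr <- c(as.list(setNames(10^lp, free)),
            if (fix_kplus) list(kplus = fixed$kplus), fixed_orders)
    sim <- try(simulate_kinetic_model(pr, ts), silent = TRUE)
    if (inherits(sim, "try-error") || any(!is.finite(sim$mass_fraction)))
      return(1e6)
    sum((sim$mass_fraction - y)^2)
  }
  # scale-informed starts: rate scale ~ 1/t_half
  base <- log10(1 / t_half)
  starts <- if (fix_kplus) {
    base2 <- base - log10(fixed$kplus * t_half) # crude product split
    list(c(base2, base2), c(base2 - 1, base2 + 1),
         c(base2 + 1, base2 - 1), c(base2 - 2, base2 + 1))
  } else {
    list(c(base, base, base), c(base - 1, base, base + 1),
         c(base + 1, base - 1, base), c(base - 2, base + 1, base + 1))
  }
  best <- NULL
  for (s in head(starts, n_starts)) {
    fit <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pr <- c(as.list(setNames(10^best$par, free)),
          if (fix_kplus) list(kplus = fixed$kplus), fixed_orders)
  sim <- simulate_kinetic_model(pr, ts)
  structure(list(kn = pr$kn, k2 = pr$k2, kplus = pr$kplus,
                 neg_log10_kn = -log10(pr$kn),
                 rms = sqrt(best$value / length(y)),
                 fitted = tibble::tibble(time = ts + t0, mass_fraction = sim$mass_fraction),
                 fixed = fixed, converged = best$convergence == 0,
                 censored = FALSE),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (isTRUE(x$censored)) {
    cat("<kinetic_fit> censored (flat / non-identifiable curve)\n")
  } else {
    cat(sprintf("<kinetic_fit> kn = %.3g, k2 = %.3g, kplus = %.3g (-log10 kn = %.2f, rms %.2g)\n",
                x$kn, x$k2, x$kplus, x$neg_log10_kn, x$rms))
  }
  invisible(x)
}

#' Replicate statistics of half-times and lag times
#'
#' Box-plot-ready summary over independent ageing trajectories: mean, median,
#' quartiles, whiskers and censoring counts for t1/2 and the nucleation lag.
#'
#' @param t_half Numeric vector of half-times (`NA` = censored).
#' @param lag Numeric vector of lag times (`NA` = censored).
#' @return Tibble of class `replicate_stats` with one row per metric.
#' @export
replicate_stats <- function(t_half, lag = NULL) {
  summarise_one <- function(x, name) {
    obs <- x[is.finite(x)]
    tibble::tibble(metric = name, n = length(x), n_censored = sum(!is.finite(x)),
                   mean = if (length(obs)) mean(obs) else NA_real_,
                   median = if (length(obs)) median(obs) else NA_real_,
                   q25 = if (length(obs)) unname(quantile(obs, 0.25)) else NA_real_,
                   q75 = if (length(obs)) unname(quantile(obs, 0.75)) else NA_real_,
                   whisker_low = if (length(obs)) min(obs) else NA_real_,
                   whisker_high = if (length(obs)) max(obs) else NA_real_)
  }
  out <- summarise_one(t_half, "t_half")
  if (!is.null(lag)) out <- dplyr::bind_rows(out, summarise_one(lag, "lag"))
  class(out) <- c("replicate_stats", class(out))
  out
}

#' Mann-Whitney U rank test
#'
#' Exact enumeration-based p-value when `n1 + n2 <= 20` and there are no ties;
#' tie-corrected normal approximation otherwise (the standard two-regime
#' protocol). Used to decide whether a peptide significantly shifts the
#' distribution of ageing half-times relative to the pure condensate.
#'
#' @param sample_a,sample_b Numeric samples (each non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (for
#'   `sample_a` vs `sample_b`).
#' @return Object of class `rank_test`: `U`, `p_value`, `method`, sample
#'   sizes.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")$p_value # 0.05
mann_whitney_u <- function(sample_a, sample_b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(sample_a) == 0 || length(sample_b) == 0) stop("empty sample")
  exact <- (length(sample_a) + length(sample_b) <= 20) &&
    !any(duplicated(c(sample_a, sample_b)))
  wt <- suppressWarnings(wilcox.test(sample_a, sample_b,
                                     alternative = alternative,
                                     exact = exact, correct = !exact))
  structure(list(U = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal-approx",
                 n1 = length(sample_a), n2 = length(sample_b),
                 alternative = alternative),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> Mann-Whitney U = %g, p = %.4g (%s, n1 = %d, n2 = %d, %s)\n",
              x$U, x$p_value, x$method, x$n1, x$n2, x$alternative))
  invisible(x)
}

#' Memoryless-arrival fit of nucleation lag times
#'
#' Fits a one-parameter exponential (memoryless inter-arrival) model to the
#' observed lag times — the continuous counterpart of Poisson nucleation
#' counting — and reports a Kolmogorov-Smirnov goodness of fit against the
#' fitted distribution. Degenerate (zero-dispersion) samples are rejected
#' outright.
#'
#' @param lags Numeric lag times; needs >= 4 uncensored values.
#' @return List of class `lag_dispersion`: `rate`, `mean`, `cv`
#'   (coefficient of variation; 1 under the model), `ks_statistic`,
#'   `p_value`, `accepted` at the 5% level.
#' @export
lag_distribution_test <- function(lags) {
  x <- lags[is.finite(lags)]
  if (length(x) < 4) stop("need at least 4 uncensored lag times")
  if (var(x) == 0)
    return(structure(list(rate = 1 / mean(x), mean = mean(x), cv = 0,
                          ks_statistic = 1, p_value = 0, accepted = FALSE),
                     class = "lag_dispersion"))
  m <- mean(x)
  ks <- suppressWarnings(ks.test(x, "pexp", rate = 1 / m))
  structure(list(rate = 1 / m, mean = m, cv = sd(x) / m,
                 ks_statistic = unname(ks$statistic), p_value = ks$p.value,
                 accepted = ks$p.value > 0.05),
            class = "lag_dispersion")
}

#' Write an ageing curve as CSV
#' @param curve An `ageing_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read an ageing curve from CSV
#' @param path CSV with `time_ps`, `structured_count`, `structured_fraction`.
#' @return An `ageing_curve` tibble.
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- tibble::as_tibble(df)
  class(out) <- c("ageing_curve", class(out))
  out
}
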