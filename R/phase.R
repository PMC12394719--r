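#' Mass-density profile along the long axis of a slab trajectory
#'
#' Frames are recentred so the system centre of mass sits at the box middle
#' along the chosen axis, binned, converted to g/L and time-averaged. Binned
#' mass sums to the total system mass in every frame.
#'
#' @param traj A `cg_trajectory` (slab geometry, equilibrated frames).
#' @param topology Matching `cg_topology`.
#' @param n_bins Number of bins along the axis.
#' @param axis Axis index (1-3); default the longest box edge.
#' @param recentre Recentre each frame on its centre of mass.
#' @return Tibble of class `density_profile`: `z` (bin centre, nm), `density`
#'   (g/L), with the box and totals as attributes.
#' @export
density_profile <- function(traj, topology, n_bins = 50, axis = NULL,
                            recentre = TRUE) {
  if (length(traj$frames) == 0) stop("no frames to average")
  box <- traj$box[1, ]
  if (is.null(axis)) axis <- which.max(box)
  L <- box[axis]
  m <- topology$beads$mass
  edges <- seq(0, L, length.out = n_bins + 1)
  acc <- numeric(n_bins)
  for (f in seq_along(traj$frames)) {
    z <- traj$frames[[f]][, axis] %% L
    if (recentre) {
      # circular-mean recentring so a slab crossing the boundary stays whole
      th <- 2 * pi * z / L
      com <- atan2(sum(m * sin(th)), sum(m * cos(th))) * L / (2 * pi)
      z <- (z - com + L / 2) %% L
    }
    idx <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE), 1), n_bins)
    acc <- acc + tapply(m, factor(idx, levels = seq_len(n_bins)), sum, default = 0)
  }
  bin_vol <- prod(box[-axis]) * L / n_bins
  out <- tibble::tibble(z = (edges[-1] + edges[-length(edges)]) / 2,
                        density = as.numeric(acc) / length(traj$frames) *
                          .dens_conv / bin_vol)
  attr(out, "box") <- box
  attr(out, "axis") <- axis
  attr(out, "total_mass") <- sum(m)
  class(out) <- c("density_profile", class(out))
  out
}

#' Coexistence densities from a slab density profile
#'
#' Locates the dense slab as the contiguous region above the half-range
#' density threshold around the profile maximum; the dense density is the mean
#' over the central 50% of that region, the dilute density the mean over the
#' outermost 25% of the box on each side (relative to the slab centre), so the
#' 10-90% interfacial regions are excluded from both.
#'
#' @param profile A [density_profile()].
#' @param temperature Temperature label attached to the phase point (K).
#' @return Tibble of class `phase_point`: `T`, `rho_dilute`, `rho_dense`
#'   (g/L). Emits a near-critical warning (and `NA` dense density) when no
#'   plateau is detectable.
#' @export
coexistence_densities <- function(profile, temperature = NA_real_) {
  rho <- profile$density
  n <- length(rho)
  thr <- min(rho) + 0.5 * (max(rho) - min(rho))
  if (max(rho) <= 2 * pmax(min(rho), 1e-12) || all(rho > thr)) {
    warning("no detectable dense plateau: profile is near-critical or single-phase")
    return(structure(tibble::tibble(T = temperature,
                                    rho_dilute = mean(rho), rho_dense = NA_real_),
                     class = c("phase_point", class(tibble::tibble()))))
  }
  # contiguous above-threshold region around the maximum (circular)
  i_max <- which.max(rho)
  above <- rho > thr
  lo <- i_max; hi <- i_max
  while (above[((lo - 2) %% n) + 1] && (hi - lo) < n - 1) lo <- lo - 1
  while (above[(hi %% n) + 1] && (hi - lo) < n - 1) hi <- hi + 1
  idx_slab <- ((lo:hi - 1) %% n) + 1
  w <- length(idx_slab)
  core <- idx_slab[seq.int(floor(w / 4) + 1, ceiling(3 * w / 4))]
  rho_dense <- mean(rho[core])
  centre <- (lo + hi) / 2
  offset <- ((seq_len(n) - centre) %% n)
  offset <- pmin(offset, n - offset) / n   # circular distance fraction from slab centre
  tails <- which(offset >= 0.25)
  rho_dilute <- mean(rho[tails])
  structure(tibble::tibble(T = temperature, rho_dilute = rho_dilute,
                           rho_dense = rho_dense),
            class = c("phase_point", class(tibble::tibble())))
}

#' Fit the critical point from coexistence densities
#'
#' Simultaneous least squares of the critical-exponent width law
#' `rho_dense - rho_dilute = A (1 - T/Tc)^beta` and the law of rectilinear
#' diameters `(rho_dense + rho_dilute)/2 = rho_c + B (Tc - T)`, with the
#' 3D-Ising exponent `beta = 0.325` held fixed. Given `Tc` both laws are
#' linear in `(A, rho_c, B)`, so the fit profiles them out and optimises `Tc`
#' in one dimension.
#'
#' @param points Tibble with columns `T`, `rho_dilute`, `rho_dense` (>= 3
#'   subcritical points).
#' @param beta Critical exponent (fixed).
#' @return Object of class `critical_fit` with `Tc` (K), `rho_c` (g/L),
#'   amplitude `A`, slope `B`, `beta`, residual summary and the input points.
#' @export
fit_critical_point <- function(points, beta = 0.325) {
  pts <- tibble::as_tibble(points)[, c("T", "rho_dilute", "rho_dense")]
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 coexistence points")
  if (any(pts$rho_dense < pts$rho_dilute)) stop("rho_dense < rho_dilute in input")
  width <- pts$rho_dense - pts$rho_dilute
  if (is.unsorted(rev(width[order(pts$T)])))
    warning("coexistence width is not monotone in T; fit may be unreliable")
  dia <- (pts$rho_dense + pts$rho_dilute) / 2
  Tmax <- max(pts$T)
  rho_scale <- max(width)
  sse <- function(Tc) {
    x <- (1 - pts$T / Tc)^beta
    A <- sum(width * x) / sum(x^2)
    fit2 <- stats::lm.fit(cbind(1, Tc - pts$T), dia)
    sum((width - A * x)^2) / rho_scale^2 + sum(fit2$residuals^2) / rho_scale^2
  }
  opt <- optimize(sse, interval = c(Tmax + 1e-3, Tmax + 200))
  Tc <- opt$minimum
  x <- (1 - pts$T / Tc)^beta
  A <- sum(width * x) / sum(x^2)
  fit2 <- stats::lm.fit(cbind(1, Tc - pts$T), dia)
  structure(list(Tc = Tc, rho_c = unname(fit2$coefficients[1]),
                 A = A, B = unname(fit2$coefficients[2]), beta = beta,
                 rss = opt$objective * rho_scale^2,
                 residual_width = width - A * x,
                 residual_diameter = unname(fit2$residuals),
                 points = pts),
            class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  cat(sprintf("<critical_fit> Tc = %.2f K, rho_c = %.1f g/L (A = %.1f, B = %.3f, beta = %.3f)\n",
              x$Tc, x$rho_c, x$A, x$B, x$beta))
  invisible(x)
}

#' Bracket the critical temperature from an NPT stability scan
#'
#' The critical solution temperature is estimated as the midpoint between the
#' highest temperature at which the condensate is stable at P = 0 and the
#' lowest at which it evolves into the diluted phase; the half-width of that
#' interval is the error bar.
#'
#' @param scan Tibble/data frame with columns `T` (K) and `stable` (logical,
#'   or a [classify_stability()] string where `"condensed"` means stable).
#' @return List of class `tc_bracket`: `T_stable_max`, `T_unstable_min`,
#'   `estimate`, `halfwidth`.
#' @export
tc_bracket_from_npt <- function(scan) {
  scan <- tibble::as_tibble(scan)
  st <- scan$stable
  if (is.character(st)) st <- st == "condensed"
  if (all(st)) stop("open bracket: no unstable temperature in the scan")
  if (!any(st)) stop("open bracket: no stable temperature in the scan")
  t_s <- max(scan$T[st]); t_u <- min(scan$T[!st])
  if (t_u <= t_s)
    stop("non-monotone stability sequence (stable above an unstable T); rerun advised")
  structure(list(T_stable_max = t_s, T_unstable_min = t_u,
                 estimate = (t_s + t_u) / 2, halfwidth = (t_u - t_s) / 2),
            class = "tc_bracket")
}

#' @export
print.tc_bracket <- function(x, ...) {
  cat(sprintf("<tc_bracket> Tc = %.1f +/- %.1f K (stable <= %.1f, unstable >= %.1f)\n",
              x$estimate, x$halfwidth, x$T_stable_max, x$T_unstable_min))
  invisible(x)
}

#' Reduced temperature and its inverse
#'
#' `reduced_temperature()` returns T/Tc; `absolute_temperature()` inverts it,
#' rounding to the nearest kelvin by default (the convention used when quoting
#' run temperatures such as T/Tc = 0.95).
#'
#' @param T Absolute temperature, K.
#' @param Tc Critical temperature, K (> 0).
#' @return Dimensionless ratio, or kelvin for the inverse.
#' @export
#' @examples
#' absolute_temperature(0.95, 308) # 293 K
reduced_temperature <- function(T, Tc) {
  if (any(Tc <= 0)) stop("Tc must be positive")
  T / Tc
}

#' @rdname reduced_temperature
#' @param ratio Reduced temperature T/Tc.
#' @param round Round the result to the nearest kelvin.
#' @export
absolute_temperature <- function(ratio, Tc, round = TRUE) {
  if (any(Tc <= 0)) stop("Tc must be positive")
  out <- ratio * Tc
  if (round) round(out) else out
}
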