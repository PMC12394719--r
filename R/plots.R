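#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: ageing
#' curves, viscoelastic spectra, contact maps, density profiles and
#' critical-point fits.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name condage-plots
NULL

#' @rdname condage-plots
#' @exportS3Method ggplot2::autoplot
autoplot.ageing_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ps,
                                       y = .data$structured_fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ps)", y = "relative cross-β-sheet concentration") +
    ggplot2::ylim(0, 1)
}

#' @rdname condage-plots
#' @exportS3Method ggplot2::autoplot
autoplot.viscoelastic_spectrum <- function(object, ...) {
  df <- tidyr::pivot_longer(object$spectrum, c("G_storage", "G_loss"),
                            names_to = "modulus", values_to = "G")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega, y = .data$G,
                                   colour = .data$modulus)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(omega ~ "(rad/ps)"), y = "modulus",
                  colour = NULL,
                  subtitle = paste("classification:", object$classification))
}

#' @rdname condage-plots
#' @exportS3Method ggplot2::autoplot
autoplot.contact_map <- function(object, ...) {
  df <- tibble::as_tibble(expand.grid(i = seq_len(nrow(object$matrix)),
                                      j = seq_len(ncol(object$matrix))))
  df$freq <- as.vector(object$matrix)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$freq)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "contact (%)") +
    ggplot2::labs(x = object$role_a, y = object$role_b)
}

#' @rdname condage-plots
#' @exportS3Method ggplot2::autoplot
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "density (g/L)")
}

#' @rdname condage-plots
#' @exportS3Method ggplot2::autoplot
autoplot.critical_fit <- function(object, ...) {
  pts <- tidyr::pivot_longer(object$points, c("rho_dilute", "rho_dense"),
                             names_to = "branch", values_to = "rho")
  Tgrid <- seq(min(object$points$T), object$Tc, length.out = 100)
  w <- object$A * pmax(1 - Tgrid / object$Tc, 0)^object$beta
  d <- object$rho_c + object$B * (object$Tc - Tgrid)
  env <- tibble::tibble(T = rep(Tgrid, 2),
                        rho = c(d - w / 2, d + w / 2),
                        branch = rep(c("rho_dilute", "rho_dense"), each = 100))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$rho, y = .data$T)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$branch)) +
    ggplot2::geom_path(data = env, ggplot2::aes(group = .data$branch)) +
    ggplot2::annotate("point", x = object$rho_c, y = object$Tc, shape = 1, size = 3) +
    ggplot2::labs(x = "density (g/L)", y = "T (K)", shape = NULL)
}

#' Box plot of replicate half-times per system
#'
#' @param replicates Replicate tibble from [run_ageing_campaign()]
#'   (`$replicates`).
#' @param budget_time Right-censoring value substituted for censored
#'   trajectories.
#' @return A ggplot mirroring the screening box-plot layout (25-75% boxes,
#'   median bar, mean cross, min/max whiskers).
#' @export
plot_half_times <- function(replicates, budget_time = NULL) {
  df <- replicates
  if (!is.null(budget_time)) df$t_half[!is.finite(df$t_half)] <- budget_time
  ggplot2::ggplot(df, ggplot2::aes(x = .data$system, y = .data$t_half)) +
    ggplot2::geom_boxplot(coef = Inf) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = expression(t[1/2] ~ "(ps)"))
}
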