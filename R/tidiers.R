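#' Tidy and glance methods for fitted objects
#'
#' broom-style accessors: `tidy()` returns one row per estimated term,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object (`critical_fit`, `kinetic_fit`,
#'   `relaxation_modulus`, `rank_test` or `lag_dispersion`).
#' @param ... Unused.
#' @return A tibble.
#' @name condage-tidiers
NULL

#' @rdname condage-tidiers
#' @exportS3Method generics::tidy
tidy.critical_fit <- function(x, ...) {
  tibble::tibble(term = c("Tc", "rho_c", "A", "B"),
                 estimate = c(x$Tc, x$rho_c, x$A, x$B),
                 unit = c("K", "g/L", "g/L", "g/L/K"))
}

#' @rdname condage-tidiers
#' @exportS3Method generics::glance
glance.critical_fit <- function(x, ...) {
  tibble::tibble(Tc = x$Tc, rho_c = x$rho_c, beta = x$beta,
                 rss = x$rss, n_points = nrow(x$points))
}

#' @rdname condage-tidiers
#' @exportS3Method generics::tidy
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(term = c("kn", "k2", "kplus", "neg_log10_kn"),
                 estimate = c(x$kn, x$k2, x$kplus, x$neg_log10_kn))
}

#' @rdname condage-tidiers
#' @exportS3Method generics::glance
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(rms = x$rms, converged = x$converged,
                 censored = isTRUE(x$censored),
                 nc = x$fixed$nc, n2 = x$fixed$n2, mtot = x$fixed$mtot)
}

#' @rdname condage-tidiers
#' @exportS3Method generics::tidy
tidy.relaxation_modulus <- function(x, ...) {
  tibble::tibble(term = paste0("mode_", seq_len(nrow(x$modes))),
                 G_i = x$modes$G_i, tau_i = x$modes$tau_i)
}

#' @rdname condage-tidiers
#' @exportS3Method generics::glance
glance.relaxation_modulus <- function(x, ...) {
  tibble::tibble(eta = x$eta, n_modes = nrow(x$modes),
                 volume = x$volume, temperature = x$temperature)
}

#' @rdname condage-tidiers
#' @exportS3Method generics::tidy
tidy.rank_test <- function(x, ...) {
  tibble::tibble(U = x$U, p_value = x$p_value, method = x$method,
                 n1 = x$n1, n2 = x$n2, alternative = x$alternative)
}

#' @rdname condage-tidiers
#' @exportS3Method generics::tidy
tidy.lag_dispersion <- function(x, ...) {
  tibble::tibble(rate = x$rate, mean = x$mean, cv = x$cv,
                 ks_statistic = x$ks_statistic, p_value = x$p_value,
                 accepted = x$accepted)
}
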