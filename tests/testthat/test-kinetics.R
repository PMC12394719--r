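test_that("curve normalization estimates the plateau and flags censored series", {
  t <- 0:100
  # constant raw count: flat curve at 1
  flat <- normalize_curve(t, rep(7, 101))
  expect_true(all(flat$structured_fraction == 1))
  expect_false(attr(flat, "censored"))
  # saturating curve: plateau recovered within 1%
  raw <- 40 * (1 - exp(-t / 12))
  nc <- normalize_curve(t, raw, plateau_window_fraction = 0.1)
  expect_equal(attr(nc, "plateau"), 40, tolerance = 0.01)
  expect_true(all(nc$structured_fraction <= 1))
  # strictly linear raw series: still rising, censored
  lin <- normalize_curve(t, t)
  expect_true(attr(lin, "censored"))
  expect_error(normalize_curve(t, rev(t)), "non-decreasing")
})

test_that("half-time interpolates to the mid-amplitude point", {
  # linear ramp 0 -> 1 over [0, 10]: exactly 5
  ramp <- tibble::tibble(time_ps = seq(0, 10, by = 0.5),
                         structured_fraction = seq(0, 1, length.out = 21))
  expect_equal(half_time(ramp), 5)
  # initial 0.1, plateau 0.9: the time where c = 0.5
  shifted <- tibble::tibble(time_ps = seq(0, 10, by = 0.5),
                            structured_fraction = seq(0.1, 0.9, length.out = 21))
  expect_equal(shifted$structured_fraction[11], 0.5)
  expect_equal(half_time(shifted), 5)
  # logistic with midpoint t0 and c0 ~ 0: recovers t0 (closed form)
  t <- seq(0, 60, by = 0.05)
  t0 <- 23.4
  curve <- tibble::tibble(time_ps = t,
                          structured_fraction = 1 / (1 + exp(-(t - t0) / 2)))
  expect_equal(half_time(curve), t0, tolerance = 0.02)
  # censored curves propagate NA
  cen <- ramp; attr(cen, "censored") <- TRUE
  expect_true(is.na(half_time(cen)))
})

test_that("nucleation lag time is the first event, censored when none", {
  expect_equal(nucleation_lag_time(c(12, 30, 31)), 12)
  expect_true(is.na(nucleation_lag_time(numeric(0))))
  ev <- tibble::tibble(time_ps = c(40, 15, 90))
  expect_equal(nucleation_lag_time(ev), 15)
})

test_that("the kinetic moment equations behave as the mechanism dictates", {
  tg <- seq(0, 200, by = 1)
  # no primary nucleation and no seeds: identically zero
  zero <- simulate_kinetic_model(list(kn = 0, k2 = 1, kplus = 10, nc = 2,
                                      n2 = 2, mtot = 1), tg)
  expect_true(all(zero$mass_fraction == 0))
  # mass conservation to integrator tolerance
  p <- list(kn = 1e-4, k2 = 1e-2, kplus = 50, nc = 2, n2 = 2, mtot = 1)
  sim <- simulate_kinetic_model(p, tg)
  expect_true(all(sim$mass_fraction >= 0 & sim$mass_fraction <= 1 + 1e-8))
  expect_true(all(diff(sim$mass_fraction) >= -1e-9))
  # secondary nucleation sharpens the sigmoid: larger max-slope/plateau ratio
  p0 <- p; p0$k2 <- 0; p0$kn <- 1e-3
  sim0 <- simulate_kinetic_model(p0, seq(0, 2000, by = 5))
  shape <- function(s) max(diff(s$mass_fraction) / diff(s$time)) /
    max(s$mass_fraction)
  expect_gt(shape(sim), shape(sim0))
})

test_that("fitting model-generated curves recovers the generating rates", {
  p <- list(kn = 1e-4, k2 = 1e-2, kplus = 50, nc = 2, n2 = 2, mtot = 1)
  sim <- simulate_kinetic_model(p, seq(0, 400, by = 2))
  fit <- fit_kinetic_model(sim, fixed = list(nc = 2, n2 = 2, mtot = 1,
                                             kplus = 50))
  expect_lt(abs(fit$kn / p$kn - 1), 0.1)
  expect_lt(abs(fit$k2 / p$k2 - 1), 0.1)
  expect_lt(fit$rms, 1e-3)
  expect_equal(fit$neg_log10_kn, -log10(fit$kn))
  # free-kplus fit still nails the identifiable products
  fit3 <- fit_kinetic_model(sim)
  expect_lt(abs((fit3$kn * fit3$kplus) / (p$kn * p$kplus) - 1), 0.1)
  expect_lt(abs((fit3$k2 * fit3$kplus) / (p$k2 * p$kplus) - 1), 0.1)
  # flat curve: censored fit
  flat <- tibble::tibble(time = 0:50, mass_fraction = rep(0.01, 51))
  expect_true(fit_kinetic_model(flat)$censored)
})

test_that("doubling all times halves the fitted rate scales", {
  p <- list(kn = 2e-4, k2 = 5e-3, kplus = 40, nc = 2, n2 = 2, mtot = 1)
  sim <- simulate_kinetic_model(p, seq(0, 300, by = 2))
  f1 <- fit_kinetic_model(sim, fixed = list(nc = 2, n2 = 2, mtot = 1, kplus = 40))
  sim2 <- sim; sim2$time <- 2 * sim$time
  f2 <- fit_kinetic_model(sim2, fixed = list(nc = 2, n2 = 2, mtot = 1, kplus = 20))
  expect_equal(f2$kn, f1$kn / 2, tolerance = 0.05)
  expect_equal(f2$k2, f1$k2 / 2, tolerance = 0.05)
})

test_that("Mann-Whitney U matches full enumeration and its symmetry", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- mann_whitney_u(a, b, alternative = "less")
  expect_equal(res$U, 0)
  expect_equal(res$method, "exact")
  # enumeration oracle over all C(6,3) assignments of ranks to sample A
  pooled <- c(a, b)
  combos <- utils::combn(6, 3)
  u_of <- function(idx) {
    xa <- pooled[idx]; xb <- pooled[-idx]
    sum(outer(xa, xb, ">")) # U statistic for A
  }
  u_all <- apply(combos, 2, u_of)
  p_exact <- mean(u_all <= res$U)
  expect_equal(p_exact, 1 / 20)
  expect_equal(res$p_value, p_exact)
  # swapping the samples maps U -> n1 n2 - U
  res_sw <- mann_whitney_u(b, a, alternative = "greater")
  expect_equal(res_sw$U, 9 - res$U)
  expect_equal(res_sw$p_value, res$p_value)
  expect_error(mann_whitney_u(numeric(0), b), "empty")
})

test_that("exact and normal-approximation p-values agree at moderate n", {
  set.seed(31)
  x <- rnorm(10); y <- rnorm(10, 0.8)
  exact_p <- mann_whitney_u(x, y, alternative = "less")$p_value
  approx_p <- suppressWarnings(
    wilcox.test(x, y, alternative = "less", exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(approx_p / exact_p - 1), 0.15)
  # ties force the tie-corrected normal route
  res_t <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 4, 5))
  expect_equal(res_t$method, "normal-approx")
})

test_that("the memoryless lag-distribution fit accepts exponential, rejects constant", {
  set.seed(12)
  lags <- rexp(40, rate = 1 / 30)
  fit <- lag_distribution_test(lags)
  expect_true(fit$accepted)
  expect_equal(fit$mean, mean(lags))
  # scale equivariance: doubling the lags doubles the fitted mean
  fit2 <- lag_distribution_test(2 * lags)
  expect_equal(fit2$mean, 2 * fit$mean)
  # degenerate zero-dispersion sample is rejected
  const <- lag_distribution_test(rep(5, 10))
  expect_false(const$accepted)
  expect_equal(const$cv, 0)
  expect_error(lag_distribution_test(c(1, 2, NA)), "at least 4")
})

test_that("replicate statistics expose right-skew (median below mean)", {
  set.seed(9)
  th <- rexp(200, 1 / 50) # right-skewed nucleation-dominated half-times
  st <- replicate_stats(th, lag = th * 0.6)
  expect_lte(st$median[1], st$mean[1])
  expect_equal(st$n[1], 200)
  expect_equal(st$whisker_low[1], min(th))
  expect_equal(st$whisker_high[1], max(th))
  # censored entries are counted, not averaged
  st2 <- replicate_stats(c(th, NA, NA))
  expect_equal(st2$n_censored[1], 2)
  expect_equal(st2$mean[1], mean(th))
})

test_that("ageing curves round-trip through CSV", {
  curve <- normalize_curve(0:20, pmin(0:20, 15))
  tmp <- tempfile(fileext = ".csv")
  write_curve_csv(curve, tmp)
  back <- read_curve_csv(tmp)
  expect_equal(back$structured_fraction, curve$structured_fraction)
  expect_s3_class(back, "ageing_curve")
})
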