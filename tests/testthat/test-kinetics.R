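test_that("coloc_model matches the closed form and its limits", {
  # P(0) = a1, both bracketed terms vanish
  expect_identical(coloc_model(0, 0.37, 0.01, 0.05, 0.2), 0.37)
  # independent numeric evaluation at t = 10 (frozen from the closed form)
  expect_equal(coloc_model(10, 0.4, 0.006, 0.1, 0.2), 0.5198729, tolerance = 1e-6)
  # plateau a1 + a2/(k1 k2)
  expect_equal(coloc_model(1e6, 0.4, 0.006, 0.1, 0.2), 0.7, tolerance = 1e-9)
  # k1 -> k2 limit agrees with the analytic L'Hopital form
  t_grid <- c(0.5, 5, 17, 60)
  near <- coloc_model(t_grid, 0.3, 0.004, 0.2 - 1e-12, 0.2)
  at <- coloc_model(t_grid, 0.3, 0.004, 0.2, 0.2)
  expect_equal(near, at, tolerance = 1e-9)
  expect_error(coloc_model(-1, 0.4, 0.006, 0.1, 0.2), "non-negative")
  expect_error(coloc_model(10, 0.4, 0.006, -0.1, 0.2), "positive")
})

test_that("half_time and efficiency follow their definitions", {
  expect_equal(half_time(log(2)), 1.0)
  expect_equal(half_time(0.0533), 13.005, tolerance = 1e-3)
  expect_equal(half_time(0.2), half_time(0.1) / 2)
  expect_error(half_time(0), "positive")

  expect_equal(cici_efficiency(0.4, 0.7), 0.5)
  expect_equal(cici_efficiency(0.33, 0.33), 0)
  expect_equal(cici_efficiency(0.2, 1.0), 1.0)
  expect_error(cici_efficiency(1, 1), "< 1")
})

test_that("fit_timecourse recovers noiseless model parameters to 4 sig figs", {
  tt <- c(0, 5, 10, 15, 20, 30, 45, 60, 90, 120)
  p <- coloc_model(tt, 0.4, 0.006, 0.1, 0.2)
  tc <- timecourse(tt, round(p * 1e7), rep(1e7, length(tt)))
  f <- fit_timecourse(tc)
  expect_equal(f$a1, 0.4, tolerance = 5e-4)
  expect_equal(f$a2, 0.006, tolerance = 5e-4)
  expect_equal(f$k1, 0.1, tolerance = 5e-4)
  expect_equal(f$half_time, log(2) / f$k1)
  expect_equal(f$efficiency, 0.5, tolerance = 1e-3)
})

test_that("fit_timecourse pins a2 to 0 on a flat series", {
  tt <- seq(0, 90, by = 10)
  tc <- timecourse(tt, rep(40, length(tt)), rep(100, length(tt)))
  f <- fit_timecourse(tc)
  expect_equal(f$a1, 0.4, tolerance = 1e-9)
  expect_identical(f$a2, 0)
  expect_error(fit_timecourse(timecourse(c(0, 10, 20), c(1, 2, 3), c(10, 10, 10))),
               ">= 4")
})

test_that("fit_timecourse is invariant to time-unit rescaling", {
  tt <- c(0, 5, 10, 15, 20, 30, 45, 60, 90, 120)
  p <- coloc_model(tt, 0.4, 0.006, 0.1, 0.2)
  n <- round(p * 1e6)
  f_min <- fit_timecourse(timecourse(tt, n, rep(1e6, 10)))
  f_hr <- fit_timecourse(timecourse(tt / 60, n, rep(1e6, 10)),
                         k2_fixed = 0.2 * 60, k1_bounds = c(1e-4, 10) * 60)
  expect_equal(f_hr$k1 / 60, f_min$k1, tolerance = 1e-4)
  expect_equal(f_hr$a1, f_min$a1, tolerance = 1e-4)
  expect_equal(f_hr$p_final, f_min$p_final, tolerance = 1e-4)
})

test_that("model curve is monotone and bounded for a2 >= 0", {
  tg <- seq(0, 500, length.out = 2000)
  for (par in list(c(0.1, 0.003, 0.05, 0.2), c(0.4, 0.006, 0.1, 0.2),
                   c(0, 0.01, 0.3, 0.2))) {
    p <- coloc_model(tg, par[1], par[2], par[3], par[4])
    expect_true(all(diff(p) >= -1e-12))
    expect_lte(max(p), par[1] + par[2] / (par[3] * par[4]) + 1e-12)
  }
})

test_that("single-exponential MLE equals the sample mean", {
  x <- sample_formation_times(20, 20, 1, 1e4, seed = 7)
  f <- fit_exponential_mixture(x, 1)
  expect_equal(f$t1, mean(x))
  expect_equal(f$aic, 2 - 2 * sum(dexp(x, 1 / mean(x), log = TRUE)))
  # MLE of a pure exponential converges: mean within 1% at n = 1e4 (~3 SE)
  expect_equal(f$t1, 20, tolerance = 0.01 * 3)
})

test_that("two-component fit recovers mixture parameters", {
  x <- sample_formation_times(13, 73, 0.5, 1e4, seed = 11)
  f <- fit_exponential_mixture(x, 2)
  expect_lte(f$t1, f$t2)
  expect_equal(f$t1, 13, tolerance = 0.10)
  expect_equal(f$t2, 73, tolerance = 0.10)
  expect_lt(abs(f$A1 - 0.5), 0.05)
  # nesting: 2-component log-likelihood can never fall below 1-component
  f1 <- fit_exponential_mixture(x, 1)
  expect_gte(f$loglik, f1$loglik - 1e-8)
})

test_that("histogram-LSQ mode agrees broadly with MLE", {
  x <- sample_formation_times(13, 73, 0.5, 5e3, seed = 3)
  fh <- fit_exponential_mixture(x, 2, method = "histogram")
  expect_equal(fh$t1, 13, tolerance = 0.25)
  expect_equal(fh$t2, 73, tolerance = 0.25)
})

test_that("degenerate and invalid mixture inputs are rejected", {
  expect_error(fit_exponential_mixture(rep(1, 5), 2), "at least 10")
  expect_warning(f <- fit_exponential_mixture(rep(2, 50), 2), "degenerate")
  expect_identical(f$n_components, 1L)
  expect_error(fit_exponential_mixture(c(-1, 1:20), 2), "positive")
})

test_that("mixture Wald CIs cover the truth at nominal rate", {
  # coverage of 95% intervals for t1 and t2 across simulated cohorts at the
  # single-cell scale (n = 773); 120 cohorts keeps the run inside the test
  # budget while leaving the coverage bound unchanged
  n_cohorts <- 120L
  cov_t1 <- cov_t2 <- 0L
  for (s in seq_len(n_cohorts)) {
    x <- sample_formation_times(13, 73, 0.5, 773, seed = 7000 + s)
    f <- fit_exponential_mixture(x, 2, compute_se = TRUE)
    if (abs(f$t1 - 13) <= 1.96 * f$se[["t1"]]) cov_t1 <- cov_t1 + 1L
    if (abs(f$t2 - 73) <= 1.96 * f$se[["t2"]]) cov_t2 <- cov_t2 + 1L
  }
  expect_gte(cov_t1 / n_cohorts, 0.9)
  expect_gte(cov_t2 / n_cohorts, 0.9)
})

test_that("compare_models_aic applies the AIC arithmetic", {
  mk <- function(ll, k, n) {
    structure(list(loglik = ll, aic = 2 * k - 2 * ll, n = n),
              class = "cici_mixfit")
  }
  # equal log-likelihoods: single wins by the 2*(3-1) = 4 unit penalty
  r <- compare_models_aic(mk(-100, 1, 50), mk(-100, 3, 50))
  expect_equal(r$delta_aic, -4)
  expect_identical(r$preferred, "single")
  # double's logL exceeds single's by 10: delta = 20 - 4 = 16
  r <- compare_models_aic(mk(-110, 1, 50), mk(-100, 3, 50))
  expect_equal(r$delta_aic, 16)
  expect_identical(r$preferred, "double")
  expect_error(compare_models_aic(mk(-1, 1, 50), mk(-1, 3, 60)), "different")
})

test_that("joint fit shares time constants and recovers per-group amplitudes", {
  # group sizes as in the reference single-cell cohort (480 G1 / 255 budded)
  g <- list(G1 = sample_formation_times(13, 73, 0.54, 480, seed = 21),
            budded = sample_formation_times(13, 73, 0.20, 255, seed = 22))
  f <- joint_mixture_fit(g)
  expect_lte(f$t1, f$t2)
  expect_lt(abs(f$A1[["G1"]] - 0.54), 0.08)
  expect_lt(abs(f$A1[["budded"]] - 0.20), 0.08)
  # identical groups get equal amplitudes
  x <- sample_formation_times(13, 73, 0.4, 300, seed = 5)
  f2 <- joint_mixture_fit(list(a = x, b = x))
  expect_equal(unname(f2$A1["a"]), unname(f2$A1["b"]), tolerance = 1e-6)
  # a pure fast-component group drives its A1 to the boundary without error
  g3 <- list(fast = sample_formation_times(10, 10, 1, 100, seed = 6),
             mixed = sample_formation_times(10, 80, 0.3, 200, seed = 7))
  f3 <- joint_mixture_fit(g3)
  expect_gt(f3$A1[["fast"]], 0.85)
  expect_error(joint_mixture_fit(list(a = 1:20)), ">= 2")
  expect_error(joint_mixture_fit(list(a = 1:20, b = rep(3, 20))), "degenerate")
})
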