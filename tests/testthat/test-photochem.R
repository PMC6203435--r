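# Visual-pigment template fits, retinal-release kinetics and replicate
# comparison.

test_that("noiseless template spectra recover lambda_max to 0.05 nm", {
  for (lm in c(492.6, 500.0, 520.0)) {
    sp <- simulate_spectrum(lm, scale = 0.8, noise_sd = 0)
    fit <- fit_a1_template(sp$wavelength_nm, sp$absorbance)
    expect_lt(abs(fit$lambda_max - lm), 0.05)
    expect_equal(fit$scale, 0.8, tolerance = 1e-3)
  }
})

test_that("template fit equals an exhaustive fine-grid oracle", {
  sp <- simulate_spectrum(503.7, scale = 1.2, noise_sd = 0.01, seed = 1)
  fit <- fit_a1_template(sp$wavelength_nm, sp$absorbance)
  rss_at <- function(lm) {
    tmpl <- a1_template(sp$wavelength_nm, lm)
    sc <- sum(tmpl * sp$absorbance) / sum(tmpl^2)
    sum((sp$absorbance - sc * tmpl)^2)
  }
  grid <- seq(450, 550, by = 0.01)
  oracle <- grid[which.min(vapply(grid, rss_at, 1.0))]
  expect_lt(abs(fit$lambda_max - oracle), 0.05)
})

test_that("template fit is invariant to absorbance scaling", {
  sp <- simulate_spectrum(498.2, noise_sd = 0.005, seed = 2)
  f1 <- fit_a1_template(sp$wavelength_nm, sp$absorbance)
  f2 <- fit_a1_template(sp$wavelength_nm, 7.3 * sp$absorbance)
  expect_equal(f1$lambda_max, f2$lambda_max, tolerance = 1e-6)
  expect_equal(f2$scale, 7.3 * f1$scale, tolerance = 1e-6)
})

test_that("template fit rejects inadequate spectra", {
  expect_error(fit_a1_template(seq(480, 520, 5), rnorm(9)), "10 points")
  expect_error(fit_a1_template(seq(470, 540, 1), rep(1, 71)), "window")
  sp <- simulate_spectrum(500)
  ab <- sp$absorbance; ab[3] <- NA
  expect_error(fit_a1_template(sp$wavelength_nm, ab), "non-finite")
})

test_that("release kinetics honor the t1/2 = ln2/b identity exactly", {
  tr <- simulate_release_trace(y0 = 1, a = 2, b = log(2), noise_sd = 0,
                               t_end = 10, dt = 0.5)
  fit <- fit_retinal_release(tr$time_min, tr$fluorescence)
  expect_equal(fit$t_half, 1.0, tolerance = 1e-8)
  expect_equal(fit$t_half, log(2) / fit$b) # exact identity by construction
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_true(fit$quality_ok)
})

test_that("release fit is scale-equivariant", {
  tr <- simulate_release_trace(2, 5, 0.1, noise_sd = 0.05, t_end = 40,
                               seed = 3)
  f1 <- fit_retinal_release(tr$time_min, tr$fluorescence)
  f2 <- fit_retinal_release(tr$time_min, 3 * tr$fluorescence)
  expect_equal(f2$y0, 3 * f1$y0, tolerance = 1e-5)
  expect_equal(f2$a, 3 * f1$a, tolerance = 1e-5)
  expect_equal(f2$b, f1$b, tolerance = 1e-7)
  expect_equal(f2$t_half, f1$t_half, tolerance = 1e-7)
})

test_that("degenerate traces are rejected as unidentifiable", {
  tt <- seq(0, 10, 0.5)
  expect_error(fit_retinal_release(tt, rep(2, length(tt))), "constant trace")
  set.seed(4)
  expect_error(fit_retinal_release(tt, rnorm(length(tt), 2, 0.5)),
               "unidentifiable|noise|converge")
  expect_error(fit_retinal_release(c(0, 1, 1, 2, 3), rnorm(5)), "increasing")
})

test_that("slow fits that miss the r2 gate are flagged", {
  set.seed(5)
  tr <- simulate_release_trace(1, 0.4, 0.05, noise_sd = 0.25, t_end = 20)
  fit <- tryCatch(fit_retinal_release(tr$time_min, tr$fluorescence),
                  error = function(e) NULL)
  if (!is.null(fit)) expect_false(fit$quality_ok)
})

test_that("Welch test matches a hand-worked case and stars follow the scale", {
  a <- c(12.1, 13.0, 12.7); b <- c(14.3, 15.1, 14.6)
  w <- welch_t_test(a, b)
  # closed-form Welch statistic
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  x <- c(1, 2, 3)
  w0 <- welch_t_test(x, x)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_equal(w0$stars, "")
  # large separation with tiny variance
  ws <- welch_t_test(x, x + 10 + rnorm(3, 0, 1e-3))
  expect_lt(ws$p, 0.001)
  expect_equal(ws$stars, "***")
  expect_error(welch_t_test(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
})

test_that("replicate summaries aggregate mean and standard error", {
  cons <- list(WT = list(motif = "LEIA", lambda_max = c(498.1, 498.3),
                         t_half = c(13.1, 13.5, 13.3)))
  rs <- replicate_summary(cons)
  expect_equal(rs$lambda_max_mean, 498.2)
  expect_equal(rs$n_t_half, 3L)
  expect_equal(rs$t_half_se, sd(c(13.1, 13.5, 13.3)) / sqrt(3))
})
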