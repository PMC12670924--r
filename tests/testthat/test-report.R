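test_that("percent change transforms the log scale monotonically", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(2)), 100)
  # independent evaluation by truncated exponential series
  series <- sum(0.0049^(1:10) / factorial(1:10)) * 100
  expect_equal(percent_change(0.0049), series, tolerance = 1e-10)
  expect_equal(round(percent_change(0.0049), 6), 0.491202)
  x <- seq(-3, 3, length.out = 101)
  expect_true(all(diff(percent_change(x)) > 0))
  expect_true(all(percent_change(x) > -100))
  expect_error(percent_change(NA), "finite")
})

fake_fit <- function(levels, sds, converged = TRUE) {
  structure(list(effects = list(levels = levels),
                 effect_sds = list(levels = sds),
                 converged = converged),
            class = "rr_fit")
}

test_that("summarize_rr reports one calibrated row per exposure level", {
  fit <- fake_fit(
    levels = list(temp = c(low = -0.006, high = 0.004),
                  spi = c(a = 0, b = 0.01, c = -0.01)),
    sds = list(temp = c(low = 0.001, high = 0.003),
               spi = c(a = 0.001, b = 0.002, c = 0.02)))
  out <- summarize_rr(fit)
  expect_equal(nrow(out), 5)
  expect_identical(out$covariate, c("temp", "temp", "spi", "spi", "spi"))
  expect_identical(out$level, c(0L, 1L, 0L, 1L, 2L))
  expect_true(all(out$ci_low <= out$percent_change &
                    out$percent_change <= out$ci_high))
  # a null level: 0% change, interval symmetric on the log scale, not significant
  expect_equal(out$percent_change[3], 0)
  expect_equal(log1p(out$ci_low[3] / 100), -log1p(out$ci_high[3] / 100),
               tolerance = 1e-12)
  expect_false(out$significant[3])
  # signs follow the interval-excludes-zero rule
  expect_true(out$significant[1])   # -0.006 +/- 1.96e-3
  expect_false(out$significant[5])  # -0.01 +/- 1.96 * 0.02
  # CI endpoints preserve log-scale ordering
  expect_true(all(out$ci_low < out$ci_high))
})

test_that("summaries from a non-converged fit carry a prominent warning", {
  fit <- fake_fit(levels = list(t = c(a = 0.1, b = -0.1)),
                  sds = list(t = c(a = 0.01, b = 0.01)), converged = FALSE)
  expect_warning(out <- summarize_rr(fit), "NON-CONVERGED")
  expect_true(attr(out, "nonconverged_fit"))
})

test_that("the exposure-response summary is invariant to panel row order", {
  cfg <- sim_config(seed = 15, n_regions = 8, n_countries = 2, n_weeks = 40,
                    tweet_volume_mean = 400)
  gen <- generate_panel(cfg)
  panel <- gen$panel
  theta <- compute_theta_tot(panel)
  fused <- country_fused_intervals(panel, theta)
  suppressWarnings({
    f1 <- fit_rr_model(panel, model_spec(), fused = fused, theta = theta)
    set.seed(77)
    shuffled <- as_st_panel(as.data.frame(panel)[sample(nrow(panel)), ])
    attr(shuffled, "schemes") <- attr(panel, "schemes")
    f2 <- fit_rr_model(shuffled, model_spec(), fused = fused, theta = theta)
    s1 <- summarize_rr(f1)
    s2 <- summarize_rr(f2)
  })
  expect_equal(s1$percent_change, s2$percent_change, tolerance = 1e-6)
  expect_identical(s1$covariate, s2$covariate)
})

test_that("a 0.5% level effect is detected as significant at high volume", {
  # the probe effect sits on the SPI rainfall level: drought is not
  # seasonally shared across regions, so the effect is identified by
  # cross-sectional contrast rather than confounded with the weekly field
  eff <- zero_effects()
  eff$spi <- c(-0.0025, -0.0025, 0.005)
  hits <- 0
  for (s in 1:20) {
    gen <- generate_panel(sim_config(
      seed = 600 + s, tweet_volume_mean = 8000,
      category_effects_true = eff, country_jump_schedule = list()))
    fit <- suppressWarnings(
      fit_rr_model(gen$panel, model_spec(include_fused = FALSE),
                   theta = compute_theta_tot(gen$panel)))
    out <- suppressWarnings(summarize_rr(fit))
    row <- out[out$covariate == "spi" & out$level == 2L, ]
    hits <- hits + (row$significant && row$percent_change > 0)
  }
  expect_gte(hits / 20, 0.8)
})
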