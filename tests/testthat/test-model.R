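make_binned_panel <- function(seed = 19, ...) {
  gen <- generate_panel(sim_config(seed = seed, ...))
  gen$panel
}

zero_latents <- function(panel, fused = NULL) {
  covs <- names(default_true_effects())
  eff <- list(intercept = 0,
              temporal = numeric(length(unique(panel$week))),
              spatial = numeric(length(unique(panel$region))),
              levels = lapply(default_true_effects(), function(v) v * 0))
  if (!is.null(fused)) {
    eff$fused <- lapply(split(fused$interval, fused$country),
                        function(v) numeric(max(v) + 1))
  }
  eff
}

default_hyper <- function() {
  c(list(tau_temporal = 1000, rho = 0.5, tau_spatial = 400, tau_fused = 25),
    stats::setNames(as.list(rep(1e4, 7)),
                    paste0("tau_", names(default_true_effects()))))
}

test_that("log_posterior reduces to the Poisson log-likelihood at null effects", {
  panel <- make_binned_panel(seed = 19, n_regions = 8, n_countries = 2,
                             n_weeks = 30, tweet_volume_mean = 300)
  theta <- compute_theta_tot(panel)
  fused <- country_fused_intervals(panel, theta)
  spec <- model_spec()
  hyp <- default_hyper()
  eff <- zero_latents(panel, fused)
  lp <- log_posterior(eff, hyp, panel, spec, fused = fused, theta = theta)

  obs <- panel$total_count > 0
  mu <- theta$theta_tot * panel$total_count[obs]
  ll <- sum(dpois(panel$negative_count[obs], mu, log = TRUE))
  # prior normalisation at zero effects, from the closed-form AR(1)
  # determinant tau^T / (1-rho^2)^(T-1) and the iid block densities
  Tn <- length(unique(panel$week))
  prior0 <- dnorm(0, 0, spec$intercept_prior_sd, log = TRUE) +
    0.5 * (Tn * log(hyp$tau_temporal) - (Tn - 1) * log(1 - hyp$rho^2) -
             Tn * log(2 * pi)) +
    sum(dnorm(numeric(8), 0, 1 / sqrt(hyp$tau_spatial), log = TRUE)) +
    sum(vapply(names(default_true_effects()), function(nm) {
      k <- length(default_true_effects()[[nm]])
      sum(dnorm(numeric(k), 0, 1 / sqrt(hyp[[paste0("tau_", nm)]]), log = TRUE))
    }, numeric(1))) +
    sum(dnorm(numeric(sum(tapply(fused$interval, fused$country, max) + 1)),
              0, 1 / sqrt(hyp$tau_fused), log = TRUE))
  expect_equal(lp - prior0, ll, tolerance = 1e-8)
})

test_that("the analytic gradient matches central finite differences", {
  panel <- make_binned_panel(seed = 9, n_regions = 6, n_countries = 2,
                             n_weeks = 20, tweet_volume_mean = 300)
  theta <- compute_theta_tot(panel)
  fused <- country_fused_intervals(panel, theta)
  spec <- model_spec()
  hyp <- default_hyper()
  set.seed(2)
  eff <- zero_latents(panel, fused)
  eff$intercept <- 0.01
  eff$temporal <- rnorm(20, 0, 0.02)
  eff$spatial <- rnorm(6, 0, 0.02)
  eff$levels <- lapply(eff$levels, function(v) v + rnorm(length(v), 0, 0.01))
  eff$fused <- lapply(eff$fused, function(v) v + rnorm(length(v), 0, 0.05))
  ga <- log_posterior_grad(eff, hyp, panel, spec, fused = fused, theta = theta)
  h <- 1e-5
  fd <- function(mutate) {
    ep <- mutate(eff, +h); em <- mutate(eff, -h)
    (log_posterior(ep, hyp, panel, spec, fused, theta) -
       log_posterior(em, hyp, panel, spec, fused, theta)) / (2 * h)
  }
  for (j in c(1, 7, 20)) {
    num <- fd(function(e, d) { e$temporal[j] <- e$temporal[j] + d; e })
    expect_lt(abs(ga$temporal[j] - num) / max(abs(num), 1), 1e-5)
  }
  for (j in 1:4) {
    num <- fd(function(e, d) {
      e$levels$max_temperature[j] <- e$levels$max_temperature[j] + d; e
    })
    expect_lt(abs(ga$levels$max_temperature[j] - num) / max(abs(num), 1), 1e-5)
  }
  num <- fd(function(e, d) { e$intercept <- e$intercept + d; e })
  expect_lt(abs(ga$intercept - num) / max(abs(num), 1), 1e-5)
  num <- fd(function(e, d) { e$spatial[3] <- e$spatial[3] + d; e })
  expect_lt(abs(ga$spatial[3] - num) / max(abs(num), 1), 1e-5)
})

test_that("a constant swap between temporal and spatial leaves the likelihood term fixed", {
  panel <- make_binned_panel(seed = 4, n_regions = 6, n_countries = 2,
                             n_weeks = 16, tweet_volume_mean = 200)
  theta <- compute_theta_tot(panel)
  spec <- model_spec(include_fused = FALSE)
  # vanishing precisions make the Gaussian priors locally flat, isolating
  # the likelihood's invariance under the confounded direction
  hyp <- default_hyper()
  hyp$tau_temporal <- 1e-10
  hyp$tau_spatial <- 1e-10
  eff <- zero_latents(panel)
  set.seed(3)
  eff$temporal <- rnorm(16, 0, 0.05)
  eff$spatial <- rnorm(6, 0, 0.05)
  lp1 <- log_posterior(eff, hyp, panel, spec, theta = theta)
  eff$temporal <- eff$temporal + 0.3
  eff$spatial <- eff$spatial - 0.3
  lp2 <- log_posterior(eff, hyp, panel, spec, theta = theta)
  expect_equal(lp1, lp2, tolerance = 1e-6)
})

test_that("with only level effects and weak priors the fit matches a Poisson GLM", {
  gen <- generate_panel(sim_config(
    seed = 5, n_regions = 10, n_countries = 2, n_weeks = 80,
    tweet_volume_mean = 800,
    category_effects_true = list(max_temperature = c(-0.02, 0.005, 0.005, 0.01)),
    country_jump_schedule = list()))
  panel <- gen$panel
  theta <- compute_theta_tot(panel)
  spec <- model_spec(covariates = c(max_temperature = 4L),
                     include_temporal_ar1 = FALSE,
                     include_spatial_iid = FALSE, include_fused = FALSE,
                     fixed_precisions = list(max_temperature = 1e-6),
                     intercept_prior_sd = 100)
  fit <- fit_rr_model(panel, spec, theta = theta)
  sub <- panel[panel$total_count > 0, ]
  g <- glm(negative_count ~ 0 + factor(max_temperature_level) +
             offset(log(theta$theta_tot * total_count)),
           family = poisson(), data = sub, control = list(epsilon = 1e-12))
  ours <- fit$effects$intercept + fit$effects$levels$max_temperature
  expect_lt(max(abs(ours - unname(coef(g)))), 1e-4)
  # and the constrained block still sums to zero
  expect_lt(abs(sum(fit$effects$levels$max_temperature)), 1e-10)
})

test_that("the inner Newton objective is nondecreasing from a cold start", {
  panel <- make_binned_panel(seed = 23, n_regions = 8, n_countries = 2,
                             n_weeks = 40, tweet_volume_mean = 500)
  theta <- compute_theta_tot(panel)
  spec <- model_spec(include_fused = FALSE)
  frame <- climsent:::build_frame(panel, spec, NULL, theta$theta_tot)
  qq <- climsent:::make_Q_builder(frame, spec)(
    climsent:::hyper_from_par(
      as.list(climsent:::default_hyper_init(
        climsent:::hyper_layout(frame, spec))),
      climsent:::hyper_layout(frame, spec)))
  nw <- climsent:::inner_newton(frame, qq$Q, numeric(frame$p_z), spec$control)
  expect_true(nw$converged)
  expect_true(all(diff(nw$f_trace) >= -1e-9))
})

test_that("fitted models satisfy constraints and reproduce observed totals", {
  gen <- generate_panel(sim_config(seed = 41, n_regions = 16,
                                   n_countries = 4, n_weeks = 104))
  panel <- gen$panel
  theta <- compute_theta_tot(panel)
  fused <- country_fused_intervals(panel, theta)
  fit <- fit_rr_model(panel, model_spec(), fused = fused, theta = theta)
  expect_true(fit$converged)
  for (nm in names(fit$effects$levels)) {
    expect_lt(abs(sum(fit$effects$levels[[nm]])), 1e-10)
    expect_true(all(fit$effect_sds$levels[[nm]] > 0))
  }
  expect_lt(abs(sum(fit$effects$temporal)), 1e-9)
  expect_lt(abs(sum(fit$effects$spatial)), 1e-10)
  for (ctry in names(fit$effects$fused)) {
    expect_lt(abs(sum(fit$effects$fused[[ctry]])), 1e-10)
  }
  expect_lt(abs(fit$hyper$rho), 1)

  pred <- predict_rr(fit, panel)
  expect_true(all(pred$rr > 0))
  expect_equal(pred$mu[panel$total_count == 0],
               rep(0, sum(panel$total_count == 0)))
  expect_lt(abs(sum(pred$mu) / sum(panel$negative_count) - 1), 0.02)

  pr <- pearson_residuals(fit, panel)
  expect_equal(nrow(pr$residuals), sum(panel$total_count > 0))
  expect_lt(abs(pr$summary$mean), 0.05)
  expect_lt(abs(pr$summary$variance - 1), 0.15)

  # unseen indices are reported by name
  shifted <- as.data.frame(panel)
  shifted$week <- shifted$week + 500L
  expect_error(predict_rr(fit, as_st_panel(shifted)), "unseen week")
  bad_lev <- as.data.frame(panel)
  bad_lev$max_temperature_level[1] <- 9L
  expect_error(predict_rr(fit, as_st_panel(bad_lev)), "unseen level")
})

test_that("near-empty exposure levels are flagged and prior-dominated", {
  cfg <- sim_config(seed = 3, n_regions = 6, n_countries = 2, n_weeks = 30,
                    tweet_volume_mean = 200)
  gen <- generate_panel(cfg)
  panel <- gen$panel
  # this small panel has empty SPI extreme-drought cells
  expect_true(any(tabulate(panel$spi_level + 1L, 3) == 0))
  expect_warning(
    fit <- fit_rr_model(panel, model_spec(include_fused = FALSE),
                        theta = compute_theta_tot(panel)),
    "empty level")
  expect_true(all(fit$effect_sds$levels$spi > 0))
})
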