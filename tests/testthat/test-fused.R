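test_that("penalty limits reduce to identity and to the weighted mean", {
  set.seed(4)
  y <- rnorm(30)
  w <- runif(30, 0.3, 2)
  expect_equal(solve_fused_lasso_1d(y, 0, 0)$beta, y)
  expect_equal(solve_fused_lasso_1d(y, 0, 0, weights = w)$beta, y)
  full <- solve_fused_lasso_1d(y, 1e7, 0, weights = w)$beta
  expect_equal(full, rep(sum(w * y) / sum(w), 30), tolerance = 1e-10)
  expect_equal(max(full) - min(full), 0)
})

test_that("the DP solution matches the convex oracle on a forced example", {
  y <- c(1, 1, 5, 5)
  fit <- solve_fused_lasso_1d(y, lambda_fuse = 1)
  orc <- admm_fused_oracle(y, 1)
  expect_equal(fit$beta, orc, tolerance = 1e-6)
  expect_identical(fit$intervals, c(0L, 0L, 1L, 1L))
  expect_equal(max(fit$intervals) + 1,
               1 + sum(abs(diff(fit$beta)) > 1e-8))
})

test_that("solver output dominates feasible points and is translation-equivariant", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    y <- cumsum(rnorm(n)) + rnorm(n)
    w <- if (rep %% 2) NULL else runif(n, 0.2, 3)
    lf <- runif(1, 0, 2)
    ls <- if (is.null(w) && rep %% 3 == 0) runif(1, 0, 0.5) else 0
    fit <- solve_fused_lasso_1d(y, lf, ls, weights = w)
    expect_lte(fit$objective, fused_objective(y, y, lf, ls, w) + 1e-10)
    wm <- if (is.null(w)) mean(y) else sum(w * y) / sum(w)
    expect_lte(fit$objective,
               fused_objective(y, rep(wm, n), lf, ls, w) + 1e-10)
    if (ls == 0) {
      shifted <- solve_fused_lasso_1d(y + 3.7, lf, 0, weights = w)
      expect_equal(shifted$beta, fit$beta + 3.7, tolerance = 1e-9)
    }
  }
})

test_that("the interval count is nonincreasing in the fusion penalty", {
  set.seed(21)
  for (rep in 1:5) {
    y <- cumsum(rnorm(40, sd = 0.5)) + rnorm(40)
    grid <- sd(y) * 2^seq(-5, 5, by = 1)
    k <- vapply(grid, function(lf) {
      max(solve_fused_lasso_1d(y, lf, tol = 1e-6)$intervals) + 1L
    }, integer(1))
    expect_true(all(diff(k) <= 0))
  }
})

test_that("interval extraction splits exactly at super-tolerance jumps", {
  expect_identical(extract_intervals(rep(2.5, 8)), rep(0L, 8))
  expect_identical(extract_intervals(c(0, 0, 1, 1)), c(0L, 0L, 1L, 1L))
  expect_identical(extract_intervals(c(0, 1e-10, 1, 1 + 1e-10)),
                   c(0L, 0L, 1L, 1L))
  expect_identical(extract_intervals(numeric(0)), integer(0))
  expect_error(extract_intervals(c(1, NA)), "finite")
})

test_that("the sparse penalty needs uniform weights and empty input errors", {
  expect_error(solve_fused_lasso_1d(numeric(0), 1),
               class = "climsent_empty_fit_error")
  expect_error(solve_fused_lasso_1d(c(1, NaN), 1), "finite")
  expect_error(solve_fused_lasso_1d(1:4, 1, lambda_sparse = 0.5,
                                    weights = c(1, 2, 1, 1)), "uniform")
  # uniform non-unit weights rescale the sparse threshold
  y <- c(-2, -2, 3, 3)
  a <- solve_fused_lasso_1d(y, 0.5, 0.4, weights = rep(2, 4))$beta
  b <- admm_fused_oracle(y, 0.5, 0.4, weights = rep(2, 4))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("BIC penalty selection smooths noise but keeps a clear step", {
  # pure noise: few intervals at T = 100, across seeds
  for (s in 1:6) {
    set.seed(400 + s)
    y <- rnorm(100)
    pen <- select_penalties(y)
    fit <- solve_fused_lasso_1d(y, pen$lambda_fuse, pen$lambda_sparse)
    expect_lte(max(fit$intervals) + 1, 3)
  }
  # a large step: after merge-and-refit pruning of the L1 staircase,
  # exactly two segments split at the true location (+/- 1 week)
  for (s in 1:6) {
    set.seed(500 + s)
    y <- c(rep(0, 50), rep(4, 50)) + rnorm(100, sd = 0.3)
    pen <- select_penalties(y)
    fit <- solve_fused_lasso_1d(y, pen$lambda_fuse, pen$lambda_sparse)
    seg <- prune_segments(y, fit$intervals)
    expect_equal(max(seg$intervals) + 1, 2)
    cp <- which(diff(seg$intervals) > 0)
    expect_lte(abs(cp - 50), 1)
    # refit means are unbiased for the step size
    expect_lt(abs(diff(unique(seg$beta)) - 4), 0.3)
  }
  # degenerate cases
  one <- select_penalties(rnorm(20), grid = list(lambda_fuse = 0.37))
  expect_equal(one$lambda_fuse, 0.37)
  const <- select_penalties(rep(1, 20))
  expect_equal(const$lambda_fuse, max(default_penalty_grid(rep(1, 20))$lambda_fuse))
})

test_that("country signals measure the weekly log relative-rate anomaly", {
  # Y = theta * CT exactly: anomaly ~ 0 at large counts
  df <- data.frame(region = rep(c("A", "B"), each = 20),
                   country = rep(c("X", "Y"), each = 20),
                   week = rep(0:19, 2),
                   total_count = 50000L, negative_count = 10000L)
  p <- as_st_panel(df)
  sig <- country_signal(p, 0.2)
  expect_lt(max(abs(sig$X$signal)), 1e-4)
  # doubling one week's negatives shifts that week by ~ log 2
  df2 <- df
  df2$negative_count[df2$week == 7] <- 20000L
  sig2 <- country_signal(as_st_panel(df2), 0.2)
  expect_equal(sig2$X$signal[8] - sig$X$signal[8], log(2), tolerance = 1e-3)
  expect_equal(sig2$X$signal[3], sig$X$signal[3])
  # zero-volume country excluded with a warning
  df3 <- df
  df3$total_count[df3$country == "Y"] <- 0L
  df3$negative_count[df3$country == "Y"] <- 0L
  expect_warning(s3 <- country_signal(as_st_panel(df3), 0.2), "zero tweet")
  expect_named(s3, "X")
})

test_that("a configured country shock appears as a step in its fused signal", {
  gen <- generate_panel(sim_config(seed = 77))
  panel <- gen$panel
  theta <- compute_theta_tot(panel)
  fused <- country_fused_intervals(panel, theta)
  b <- fused[fused$country == "C2", ]
  b <- b[order(b$week), ]
  step <- mean(b$beta[b$week >= 22 & b$week <= 38]) -
    mean(b$beta[b$week > 45 | b$week < 15])
  expect_lt(abs(step - 0.5), 0.15)
  cps <- b$week[which(diff(b$interval) > 0) + 1]
  expect_true(any(abs(cps - 20) <= 2))
  expect_true(any(abs(cps - 41) <= 2))
})
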