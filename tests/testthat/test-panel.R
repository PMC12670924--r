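test_that("panel CSV round-trip is the identity, including on random panels", {
  p <- as_st_panel(toy_panel_df())
  expect_s3_class(p, "st_panel")
  expect_equal(nrow(p), 6)

  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(as.data.frame(p2), as.data.frame(p))
  expect_identical(panel_covariates(p2), panel_covariates(p))

  # property: random panels (several shapes incl. many countries/weeks)
  for (s in 1:5) {
    pr <- as_st_panel(random_panel(n_regions = 3 + 2 * s, n_weeks = 10 * s,
                                   n_countries = min(3 + 2 * s, 11),
                                   seed = s))
    write_panel(pr, f)
    back <- read_panel(f)
    expect_equal(as.data.frame(back), as.data.frame(pr))
  }
})

test_that("an empty panel round-trips as a header-only CSV", {
  p <- as_st_panel(toy_panel_df()[0, ])
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  expect_length(readLines(f), 1L)
  expect_equal(nrow(read_panel(f)), 0L)
})

test_that("validation rejects invariant violations with informative errors", {
  bad <- toy_panel_df()
  bad$negative_count[2] <- 99L
  err <- tryCatch(as_st_panel(bad), error = identity)
  expect_s3_class(err, "climsent_validation_error")
  expect_match(conditionMessage(err), "row 2")

  dup <- toy_panel_df()
  dup$week[2] <- 0L
  expect_error(as_st_panel(dup), "duplicated",
               class = "climsent_validation_error")

  frac <- toy_panel_df()
  frac$total_count[1] <- 10.5
  expect_error(as_st_panel(frac), "integer",
               class = "climsent_validation_error")

  neg <- toy_panel_df()
  neg$negative_count[1] <- -1L
  expect_error(as_st_panel(neg), class = "climsent_validation_error")

  two <- toy_panel_df()
  two$country[2] <- "Z"
  expect_error(as_st_panel(two), "more than one country",
               class = "climsent_validation_error")

  gap <- toy_panel_df()[-2, ]
  expect_error(as_st_panel(gap), "contiguous",
               class = "climsent_validation_error")

  expect_error(as_st_panel(toy_panel_df()[, -4]), "total_count",
               class = "climsent_schema_error")
})

test_that("read_panel applies a schema map and reports missing columns", {
  df <- toy_panel_df()
  names(df)[1] <- "nuts2"
  f <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(df, f)
  p <- read_panel(f, schema = c(region = "nuts2"))
  expect_equal(sort(unique(p$region)), c("A", "B"))
  expect_error(read_panel(f, schema = c(region = "missing_col")),
               "missing_col", class = "climsent_schema_error")
})

test_that("ISO year-week pairs convert to a contiguous 0-based index", {
  # 2020 has 53 ISO weeks
  idx <- iso_week_index(c(2020, 2020, 2020, 2021, 2021),
                        c(1, 52, 53, 1, 2))
  expect_identical(idx, c(0L, 51L, 52L, 53L, 54L))
  df <- toy_panel_df()
  df$week <- NULL
  df$iso_year <- rep(2020, 6)
  df$iso_week <- rep(10:12, 2)
  f <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(df, f)
  expect_equal(sort(unique(read_panel(f)$week)), 0:2)
})

test_that("theta_tot is the pooled negative proportion", {
  df <- toy_panel_df()[1:2, ]
  df$total_count <- c(10L, 10L)
  df$negative_count <- c(3L, 0L)
  expect_equal(compute_theta_tot(as_st_panel(df))$theta_tot, 0.15)

  all_neg <- toy_panel_df()
  all_neg$negative_count <- all_neg$total_count
  expect_equal(compute_theta_tot(as_st_panel(all_neg))$theta_tot, 1.0)

  zero <- toy_panel_df()
  zero$total_count <- 0L
  zero$negative_count <- 0L
  expect_error(compute_theta_tot(as_st_panel(zero)),
               class = "climsent_degenerate_error")
})

test_that("theta_tot is invariant to row permutation and region splitting", {
  p <- as_st_panel(random_panel(seed = 3))
  th <- compute_theta_tot(p)$theta_tot
  perm <- as_st_panel(as.data.frame(p)[sample(nrow(p)), ])
  expect_equal(compute_theta_tot(perm)$theta_tot, th)

  # split region R01's counts into two half regions with the same totals
  split_df <- as.data.frame(p)
  sub <- split_df[split_df$region == "R01", ]
  a <- sub; b <- sub
  a$total_count <- floor(sub$total_count / 2)
  a$negative_count <- pmin(a$total_count, floor(sub$negative_count / 2))
  b$total_count <- sub$total_count - a$total_count
  b$negative_count <- sub$negative_count - a$negative_count
  a$region <- "R01a"; b$region <- "R01b"
  stopifnot(all(b$negative_count <= b$total_count))
  split_p <- as_st_panel(rbind(split_df[split_df$region != "R01", ], a, b))
  expect_equal(compute_theta_tot(split_p)$theta_tot, th)
})
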