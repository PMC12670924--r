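#' Simulation configuration for synthetic panels
#'
#' Bundles every parameter of the synthetic-panel generator: panel
#' dimensions, the true baseline negative-sentiment proportion, the latent
#' AR(1) temporal field and iid spatial field, the true log-relative-risk
#' effect of each exposure level, country-level piecewise-constant shocks,
#' and the tweet-volume model.
#'
#' The defaults define the reference study conditions used throughout the
#' package's validation suite: 40 regions in 4 countries over 156 weeks
#' (three years), a baseline proportion of 0.2, an AR(1) temporal field
#' with correlation 0.7 and marginal SD 0.03, an iid spatial field with SD
#' 0.05, a mean tweet volume of 2000 per region-week, exposure-level
#' effects of a few tenths of a percent on the relative-risk scale
#' (magnitudes matching the reported exposure-response estimates for
#' temperature, pollen, drought, mortality and West Nile virus), and one
#' country-level log-RR shock of +0.5 over weeks 20-40.
#'
#' @param n_regions,n_countries,n_weeks panel dimensions.
#' @param theta_tot_true true baseline proportion in (0, 1).
#' @param ar1_rho AR(1) correlation of the weekly temporal field, |rho| < 1.
#' @param ar1_sd marginal SD of the temporal field (log-RR scale).
#' @param spatial_sd SD of the iid per-region effect (log-RR scale).
#' @param category_effects_true named list: covariate -> numeric vector of
#'   per-level log-RR effects, each summing to zero.
#' @param country_jump_schedule list of `list(country=, start=, end=,
#'   effect=)` piecewise-constant log-RR shocks (weeks inclusive, 0-based).
#' @param tweet_volume_mean mean total tweet count per region-week.
#' @param seed integer RNG seed.
#' @param schemes level schemes used to map simulated covariates to the
#'   exposure levels carrying `category_effects_true`; default
#'   [default_schemes()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_regions = 40L,
                       n_countries = 4L,
                       n_weeks = 156L,
                       theta_tot_true = 0.2,
                       ar1_rho = 0.7,
                       ar1_sd = 0.03,
                       spatial_sd = 0.05,
                       category_effects_true = default_true_effects(),
                       country_jump_schedule = list(
                         list(country = "C2", start = 20L, end = 40L,
                              effect = 0.5)),
                       tweet_volume_mean = 2000,
                       seed = 1L,
                       schemes = default_schemes()) {
  cfg <- list(n_regions = as.integer(n_regions),
              n_countries = as.integer(n_countries),
              n_weeks = as.integer(n_weeks),
              theta_tot_true = theta_tot_true,
              ar1_rho = ar1_rho, ar1_sd = ar1_sd, spatial_sd = spatial_sd,
              category_effects_true = category_effects_true,
              country_jump_schedule = country_jump_schedule,
              tweet_volume_mean = tweet_volume_mean,
              seed = as.integer(seed),
              schemes = schemes)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default true exposure-level effects (log-RR scale)
#'
#' Per-level log relative-risk effects with magnitudes on the order of the
#' reported exposure-response estimates (a few tenths of a percent); each
#' vector sums to zero, matching the model's identifiability convention.
#'
#' @return Named list of numeric vectors.
#' @export
default_true_effects <- function() {
  list(
    max_temperature = c(-0.00632, 0.00063, 0.00210, 0.00359),
    alder = c(-0.0048, 0.0008, 0.0019, 0.0021),
    birch = c(-0.0040, 0.0005, 0.0014, 0.0021),
    olive = c(0.0008, 0.0005, -0.0004, -0.0009),
    mortality = c(-0.0007, 0.0001, 0.0006),
    spi = c(0.0049, -0.0024, -0.0025),
    wnv = c(-0.0005, 0.0005)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_regions < cfg$n_countries || cfg$n_countries < 1) {
    csx_stop("need n_regions >= n_countries >= 1")
  }
  if (cfg$n_weeks < 1) csx_stop("need n_weeks >= 1")
  if (cfg$theta_tot_true <= 0 || cfg$theta_tot_true >= 1) {
    csx_stop("theta_tot_true must be in (0, 1)")
  }
  if (abs(cfg$ar1_rho) >= 1) {
    csx_stop("|ar1_rho| must be < 1 (stationarity)",
             class = "climsent_stationarity_error")
  }
  if (cfg$ar1_sd <= 0 || cfg$spatial_sd <= 0 || cfg$tweet_volume_mean <= 0) {
    csx_stop("ar1_sd, spatial_sd and tweet_volume_mean must be positive")
  }
  for (nm in names(cfg$category_effects_true)) {
    v <- cfg$category_effects_true[[nm]]
    if (abs(sum(v)) > 1e-8) {
      csx_stop("category effects for '", nm, "' must sum to zero (got sum ",
               format(sum(v)), ")")
    }
    if (!is.null(cfg$schemes[[nm]]) &&
        length(v) != length(cfg$schemes[[nm]]$labels)) {
      csx_stop("effect vector length for '", nm,
               "' does not match its level scheme")
    }
  }
  for (j in cfg$country_jump_schedule) {
    if (!all(c("country", "start", "end", "effect") %in% names(j))) {
      csx_stop("each country jump needs country, start, end, effect")
    }
    if (j$start > j$end) csx_stop("jump start must be <= end")
  }
  if (any(abs(unlist(cfg$category_effects_true) %||% 0) > 5) ||
      any(vapply(cfg$country_jump_schedule, function(j) abs(j$effect),
                 numeric(1)) > 5)) {
    csx_stop("configured log-RR effects would overflow exp()",
             class = "climsent_config_error")
  }
  cfg
}

#' Simulate a stationary AR(1) series
#'
#' Draws a stationary Gaussian AR(1) series with the given lag-1
#' correlation and *marginal* standard deviation: `x[1] ~ N(0, sd^2)` and
#' `x[t] = rho * x[t-1] + e[t]` with innovation variance
#' `sd^2 * (1 - rho^2)`, so every margin has variance `sd^2`.
#'
#' @param rho lag-1 correlation, |rho| < 1.
#' @param marginal_sd marginal standard deviation, > 0.
#' @param n series length, >= 1.
#' @param seed optional integer seed; identical seeds give identical draws.
#' @return Numeric vector of length `n`.
#' @export
simulate_ar1 <- function(rho, marginal_sd, n, seed = NULL) {
  if (abs(rho) >= 1) {
    csx_stop("|rho| must be < 1 for a stationary AR(1)",
             class = "climsent_stationarity_error")
  }
  stopifnot(marginal_sd > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, marginal_sd)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, marginal_sd * sqrt(1 - rho^2))
    for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  }
  x
}

# region/country labels and the region -> country map (regions split evenly)
region_layout <- function(cfg) {
  regions <- sprintf("R%02d", seq_len(cfg$n_regions))
  countries <- sprintf("C%d", seq_len(cfg$n_countries))
  list(regions = regions, countries = countries,
       country_of = countries[((seq_len(cfg$n_regions) - 1L) %%
                                 cfg$n_countries) + 1L])
}

#' Simulate the exposure covariate panel
#'
#' Emulates the marginal behaviour of the real exposure series: weekly
#' maximum temperature as an annual sinusoid with a region offset and
#' noise; pollen taxa as non-negative seasonal pulses (zero outside
#' season) with taxon-specific peak weeks; the standardized precipitation
#' index as standardized AR(1) noise with sparse multi-week extreme-drought
#' excursions (pooled mean 0, SD 1 by construction); heat-attributable
#' mortality as a non-negative warm-season rate, zero otherwise; and West
#' Nile virus cases as sparse warm-season counts, mostly zero.
#' Deterministic under the config seed when called from [generate_panel()];
#' consumes the current RNG stream when called directly.
#'
#' @param config a [sim_config()].
#' @param .seeded internal; set the seed from the config (default TRUE when
#'   called standalone).
#' @return data.frame with region, country, week and covariate columns.
#' @export
simulate_covariates <- function(config, .seeded = TRUE) {
  cfg <- validate_sim_config(config)
  if (.seeded) set.seed(cfg$seed)
  lay <- region_layout(cfg)
  nR <- cfg$n_regions; nT <- cfg$n_weeks
  week <- rep(seq_len(nT) - 1L, times = nR)
  region <- rep(lay$regions, each = nT)
  country <- rep(lay$country_of, each = nT)
  woy <- week %% 52L  # week of year, 0..51

  circ_dist <- function(w, peak) pmin(abs(w - peak), 52 - abs(w - peak))

  # temperature: annual cycle peaking mid-summer (week-of-year 29)
  temp_offset <- rnorm(nR, 0, 3)
  max_temperature <- 14 + temp_offset[rep(seq_len(nR), each = nT)] +
    12 * cos(2 * pi * (woy - 29) / 52) + rnorm(nR * nT, 0, 2)

  # pollen pulses: per region-year log-normal amplitude times a Gaussian
  # seasonal profile, hard zero outside the season window
  pollen_series <- function(peak, width = 3, meanlog = log(60), sdlog = 1) {
    year <- week %/% 52L
    n_years <- max(year) + 1L
    amp <- matrix(exp(rnorm(nR * n_years, meanlog, sdlog)), nR, n_years)
    a <- amp[cbind(rep(seq_len(nR), each = nT), year + 1L)]
    d <- circ_dist(woy, peak)
    prof <- exp(-0.5 * (d / width)^2)
    out <- a * prof * exp(rnorm(nR * nT, 0, 0.4))
    out[d > 10] <- 0
    out
  }
  alder <- pollen_series(peak = 12)
  birch <- pollen_series(peak = 18)
  olive <- pollen_series(peak = 26, meanlog = log(40))

  # SPI: per-region AR(1) plus sparse 6-week drought excursions, then
  # pooled standardization so mean 0 / SD 1 hold exactly
  spi_raw <- numeric(nR * nT)
  for (i in seq_len(nR)) {
    idx <- ((i - 1) * nT + 1):(i * nT)
    base <- simulate_ar1(0.8, 1, nT, seed = NULL)
    year_starts <- seq(0L, nT - 1L, by = 52L)
    for (ys in year_starts) {
      if (runif(1) < 0.1) {
        s <- ys + sample.int(46L, 1L) - 1L
        if (s <= nT - 1L) {
          weeks_hit <- s:min(s + 5L, nT - 1L)
          base[weeks_hit + 1L] <- base[weeks_hit + 1L] -
            (4.5 + abs(rnorm(1, 0, 0.5)))
        }
      }
    }
    spi_raw[idx] <- base
  }
  spi <- as.numeric(scale(spi_raw))

  # heat-attributable mortality: warm-season log-normal rate, else zero
  warm <- woy >= 22 & woy <= 38
  mortality <- numeric(nR * nT)
  mortality[warm] <- exp(rnorm(sum(warm), log(0.12), 1.1))

  # WNV: sparse warm-season counts
  wnv <- integer(nR * nT)
  hit <- warm & runif(nR * nT) < 0.08
  wnv[hit] <- 1L + rpois(sum(hit), 0.8)

  data.frame(region = region, country = country, week = week,
             max_temperature = max_temperature, alder = alder, birch = birch,
             olive = olive, mortality = mortality, spi = spi, wnv = wnv,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic panel with known ground truth
#'
#' Simulates the full data-generating process the relative-risk model
#' assumes: exposure covariates, a shared weekly AR(1) temporal field, an
#' iid per-region spatial field, per-level exposure effects applied through
#' the configured level schemes, country-level piecewise-constant log-RR
#' shocks, heterogeneous Poisson tweet volumes (region means log-normal
#' around `tweet_volume_mean`), and negative counts
#' `Y ~ Poisson(theta_tot_true * CT * RR)` truncated at `CT` (truncations
#' are logged and rare at the default settings).
#'
#' @param config a [sim_config()].
#' @param verbose log truncation counts.
#' @return List with elements `panel` (an `st_panel` including `_level`
#'   columns) and `truth` (temporal/spatial fields, per-row log-RR and its
#'   additive components, the true effects, schemes and config).
#' @export
generate_panel <- function(config, verbose = FALSE) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  covs <- simulate_covariates(cfg, .seeded = FALSE)
  lay <- region_layout(cfg)
  nR <- cfg$n_regions; nT <- cfg$n_weeks
  ridx <- match(covs$region, lay$regions)
  widx <- covs$week + 1L

  temporal_field <- simulate_ar1(cfg$ar1_rho, cfg$ar1_sd, nT, seed = NULL)
  spatial_field <- rnorm(nR, 0, cfg$spatial_sd)

  effect_part <- numeric(nrow(covs))
  level_cols <- list()
  for (nm in names(cfg$category_effects_true)) {
    sch <- cfg$schemes[[nm]]
    if (is.null(sch)) csx_stop("no level scheme for covariate '", nm, "'")
    lev <- assign_level(covs[[nm]], sch)
    level_cols[[paste0(nm, "_level")]] <- lev
    effect_part <- effect_part + cfg$category_effects_true[[nm]][lev + 1L]
  }

  jump_part <- numeric(nrow(covs))
  for (j in cfg$country_jump_schedule) {
    sel <- covs$country == j$country & covs$week >= j$start & covs$week <= j$end
    jump_part[sel] <- jump_part[sel] + j$effect
  }

  log_rr <- temporal_field[widx] + spatial_field[ridx] + effect_part + jump_part
  if (any(!is.finite(exp(log_rr)))) {
    csx_stop("configured effects overflow exp(log RR)",
             class = "climsent_config_error")
  }

  region_mean <- cfg$tweet_volume_mean *
    exp(rnorm(nR, 0, 0.5)) / exp(0.5^2 / 2)
  ct <- rpois(nrow(covs), region_mean[ridx])
  mu <- cfg$theta_tot_true * ct * exp(log_rr)
  y <- rpois(nrow(covs), mu)
  n_trunc <- sum(y > ct)
  if (n_trunc > 0) {
    csx_log("truncated ", n_trunc, " negative count(s) at CT (",
            format(100 * n_trunc / length(y), digits = 2), "% of rows)",
            verbose = verbose)
    y <- pmin(y, ct)
  }

  df <- data.frame(region = covs$region, country = covs$country,
                   week = covs$week, total_count = ct, negative_count = y,
                   covs[, setdiff(names(covs), c("region", "country", "week")),
                        drop = FALSE],
                   stringsAsFactors = FALSE)
  for (nm in names(level_cols)) df[[nm]] <- level_cols[[nm]]
  panel <- as_st_panel(df)
  attr(panel, "schemes") <- cfg$schemes

  truth <- list(
    temporal_field = temporal_field,
    spatial_field = stats::setNames(spatial_field, lay$regions),
    covariate_panel = covs,
    log_rr_panel = log_rr,
    components = list(temporal = temporal_field[widx],
                      spatial = spatial_field[ridx],
                      covariate = effect_part,
                      fused_jump = jump_part),
    category_effects_true = cfg$category_effects_true,
    country_jump_schedule = cfg$country_jump_schedule,
    theta_tot_true = cfg$theta_tot_true,
    n_truncated = n_trunc,
    schemes = cfg$schemes,
    config = cfg)
  list(panel = panel, truth = truth)
}
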