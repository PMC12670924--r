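# flatten a per-block effect list into the x-parameterisation vector
# matching the column layout of frame$X
flatten_effects <- function(frame, effects) {
  x <- numeric(frame$xoffs[["END"]])
  put <- function(name, v, k) {
    v <- as.numeric(v)
    if (length(v) != k) {
      csx_stop("effect block '", name, "' has length ", length(v),
               ", expected ", k)
    }
    x[frame$xoffs[[name]] + seq_len(k)] <<- v
  }
  put("intercept", effects$intercept %||% 0, 1L)
  if (!is.null(frame$zindex$temporal)) {
    put("temporal", effects$temporal %||% numeric(length(frame$weeks)),
        length(frame$weeks))
  }
  if (!is.null(frame$zindex$spatial)) {
    put("spatial", effects$spatial %||% numeric(length(frame$regions)),
        length(frame$regions))
  }
  for (nm in names(frame$covariates)) {
    put(nm, effects$levels[[nm]] %||% numeric(frame$covariates[[nm]]),
        frame$covariates[[nm]])
  }
  if (!is.null(frame$fused_levels)) {
    vals <- unlist(lapply(frame$fused_levels, function(fl) {
      v <- effects$fused[[fl$country]] %||% numeric(fl$m)
      if (length(v) != fl$m) {
        csx_stop("fused block for country ", fl$country, " has length ",
                 length(v), ", expected ", fl$m)
      }
      as.numeric(v)
    }))
    x[frame$xoffs[["fused"]] + seq_along(vals)] <- vals
  }
  x
}

#' Joint log posterior of the latent effects
#'
#' Evaluates, with all normalising constants, the Poisson log-likelihood
#' `sum(Y log mu - mu - log Y!)` with
#' `log mu = log theta_tot + log CT + intercept + temporal + spatial +
#' level effects + fused effect` over rows with `CT > 0`, plus the
#' Gaussian log-priors: the stationary AR(1) prior for the temporal block
#' (precision `tau_temporal`, correlation `rho`), iid priors for the
#' spatial, exposure-level and fused blocks with their block precisions,
#' and the intercept prior.  Values are comparable across hyperparameters.
#'
#' @param effects list with `intercept`, `temporal` (one value per panel
#'   week, sorted), `spatial` (per region, sorted), `levels` (named list
#'   of per-level vectors) and optionally `fused` (named list per country).
#' @param hyper list with `tau_temporal`, `rho`, `tau_spatial`,
#'   `tau_<covariate>` entries and `tau_fused` as applicable.
#' @param panel an `st_panel` with level columns.
#' @param spec a [model_spec()].
#' @param fused optional fused-interval table (see [fit_rr_model()]).
#' @param theta baseline rate; default computed from the panel.
#' @return A single number (log posterior density).
#' @export
log_posterior <- function(effects, hyper, panel, spec = model_spec(),
                          fused = NULL, theta = NULL) {
  theta <- theta %||% compute_theta_tot(panel)
  if (inherits(theta, "baseline_rate")) theta <- theta$theta_tot
  frame <- build_frame(panel, spec, fused, theta)
  x <- flatten_effects(frame, effects)
  eta <- frame$offset + as.numeric(frame$X %*% x)
  clip <- spec$control$eta_clip
  if (any(eta > clip)) {
    warning("linear predictor clipped at ", clip, call. = FALSE)
    eta <- pmin(eta, clip)
  }
  ll <- sum(frame$y * eta - exp(eta) - lfactorial(frame$y))
  lp <- dnorm(effects$intercept %||% 0, 0, spec$intercept_prior_sd, log = TRUE)
  if (!is.null(frame$zindex$temporal)) {
    xt <- as.numeric(effects$temporal)
    Tn <- length(xt)
    P <- ar1_precision(Tn, hyper$rho)
    quad <- hyper$tau_temporal * sum(xt * as.numeric(P %*% xt))
    logdet <- Tn * log(hyper$tau_temporal) -
      (Tn - 1) * log(1 - hyper$rho^2)
    lp <- lp + 0.5 * (logdet - Tn * log(2 * pi) - quad)
  }
  iid_lp <- function(v, tau) sum(dnorm(v, 0, 1 / sqrt(tau), log = TRUE))
  if (!is.null(frame$zindex$spatial)) {
    lp <- lp + iid_lp(as.numeric(effects$spatial), hyper$tau_spatial)
  }
  for (nm in names(frame$covariates)) {
    lp <- lp + iid_lp(as.numeric(effects$levels[[nm]]),
                      hyper[[paste0("tau_", nm)]])
  }
  if (!is.null(frame$fused_levels)) {
    lp <- lp + iid_lp(unlist(lapply(effects$fused, as.numeric)),
                      hyper$tau_fused)
  }
  ll + lp
}

#' Analytic gradient of [log_posterior()]
#'
#' @inheritParams log_posterior
#' @return List of gradient blocks matching the layout of `effects`.
#' @export
log_posterior_grad <- function(effects, hyper, panel, spec = model_spec(),
                               fused = NULL, theta = NULL) {
  theta <- theta %||% compute_theta_tot(panel)
  if (inherits(theta, "baseline_rate")) theta <- theta$theta_tot
  frame <- build_frame(panel, spec, fused, theta)
  x <- flatten_effects(frame, effects)
  eta <- pmin(frame$offset + as.numeric(frame$X %*% x), spec$control$eta_clip)
  score <- as.numeric(Matrix::crossprod(frame$X, frame$y - exp(eta)))
  take <- function(name, k) score[frame$xoffs[[name]] + seq_len(k)]
  out <- list()
  out$intercept <- take("intercept", 1L) -
    (effects$intercept %||% 0) / spec$intercept_prior_sd^2
  if (!is.null(frame$zindex$temporal)) {
    xt <- as.numeric(effects$temporal)
    P <- ar1_precision(length(xt), hyper$rho)
    out$temporal <- take("temporal", length(xt)) -
      hyper$tau_temporal * as.numeric(P %*% xt)
  }
  if (!is.null(frame$zindex$spatial)) {
    xs <- as.numeric(effects$spatial)
    out$spatial <- take("spatial", length(xs)) - hyper$tau_spatial * xs
  }
  out$levels <- list()
  for (nm in names(frame$covariates)) {
    v <- as.numeric(effects$levels[[nm]])
    out$levels[[nm]] <- take(nm, length(v)) - hyper[[paste0("tau_", nm)]] * v
  }
  if (!is.null(frame$fused_levels)) {
    out$fused <- list()
    pos <- 0L
    gf <- take("fused", sum(vapply(frame$fused_levels, `[[`, integer(1), "m")))
    for (fl in frame$fused_levels) {
      v <- as.numeric(effects$fused[[fl$country]])
      out$fused[[fl$country]] <- gf[pos + seq_len(fl$m)] - hyper$tau_fused * v
      pos <- pos + fl$m
    }
  }
  out
}

#' Predicted relative-risk surface
#'
#' Computes the relative risk `RR(i,t)` from the exponentiated sum of
#' posterior-mean effects and the expected negative count
#' `mu = theta_tot * CT * RR` for every panel row.  Rows whose week,
#' region, level or fused interval was not seen during fitting raise an
#' error naming the offending index; rows with missing covariate levels
#' yield `NA` relative risk.
#'
#' @param fit an `rr_fit`.
#' @param panel an `st_panel` compatible with the fit.
#' @return data.frame with `region`, `week`, `rr`, `mu`.
#' @export
predict_rr <- function(fit, panel) {
  stopifnot(inherits(fit, "rr_fit"))
  validate_panel(panel)
  frame <- fit$internal$frame
  ef <- fit$effects
  eta_x <- rep(ef$intercept, nrow(panel))
  if (!is.null(ef$temporal)) {
    wi <- match(panel$week, frame$weeks)
    if (anyNA(wi)) {
      csx_stop("unseen week index: ", panel$week[which(is.na(wi))[1]])
    }
    eta_x <- eta_x + as.numeric(ef$temporal)[wi]
  }
  if (!is.null(ef$spatial)) {
    ri <- match(panel$region, frame$regions)
    if (anyNA(ri)) {
      csx_stop("unseen region: ", panel$region[which(is.na(ri))[1]])
    }
    eta_x <- eta_x + as.numeric(ef$spatial)[ri]
  }
  for (nm in names(frame$covariates)) {
    lev <- as.integer(panel[[paste0(nm, "_level")]])
    bad <- !is.na(lev) & (lev < 0 | lev >= frame$covariates[[nm]])
    if (any(bad)) {
      csx_stop("unseen level index ", lev[which(bad)[1]],
               " for covariate '", nm, "'")
    }
    eta_x <- eta_x + as.numeric(ef$levels[[nm]])[lev + 1L]
  }
  if (!is.null(frame$fused_levels)) {
    key <- paste(frame$fused_key$country, frame$fused_key$week, sep = "\r")
    pos <- match(paste(panel$country, panel$week, sep = "\r"), key)
    if (anyNA(pos)) {
      i <- which(is.na(pos))[1]
      csx_stop("no fused interval for country ", panel$country[i],
               ", week ", panel$week[i])
    }
    iv <- frame$fused_key$interval[pos]
    fv <- mapply(function(ctry, k) {
      v <- ef$fused[[ctry]]
      if (is.null(v) || k + 1L > length(v)) {
        csx_stop("unseen fused interval ", k, " for country ", ctry)
      }
      v[[k + 1L]]
    }, panel$country, iv)
    eta_x <- eta_x + as.numeric(fv)
  }
  rr <- exp(eta_x)
  data.frame(region = panel$region, week = panel$week, rr = rr,
             mu = fit$theta_tot * as.numeric(panel$total_count) * rr,
             stringsAsFactors = FALSE)
}

#' Pearson residual diagnostics
#'
#' Residuals `(Y - mu) / sqrt(mu)` for rows with `CT > 0`, with pooled
#' summary statistics (mean, variance) and the mean per-region lag-1
#' autocorrelation, for assessing model fit.
#'
#' @param fit a converged `rr_fit` (a warning is raised otherwise).
#' @param panel the fitted panel.
#' @return List with `residuals` (data.frame `region, week, residual`) and
#'   `summary` (list `mean`, `variance`, `lag1_autocorrelation`).
#' @export
pearson_residuals <- function(fit, panel) {
  if (!isTRUE(fit$converged)) {
    warning("residuals from a non-converged fit", call. = FALSE)
  }
  pred <- predict_rr(fit, panel)
  keep <- as.numeric(panel$total_count) > 0 & is.finite(pred$mu) & pred$mu > 0
  r <- (as.numeric(panel$negative_count)[keep] - pred$mu[keep]) /
    sqrt(pred$mu[keep])
  df <- data.frame(region = panel$region[keep], week = panel$week[keep],
                   residual = r, stringsAsFactors = FALSE)
  lag1 <- vapply(split(df, df$region), function(sub) {
    sub <- sub[order(sub$week), ]
    n <- nrow(sub)
    if (n < 3) return(NA_real_)
    suppressWarnings(stats::cor(sub$residual[-1], sub$residual[-n]))
  }, numeric(1))
  list(residuals = df,
       summary = list(mean = mean(r), variance = var(r),
                      lag1_autocorrelation = mean(lag1, na.rm = TRUE)))
}
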