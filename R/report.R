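#' Percent change in relative risk
#'
#' Converts a log-scale effect to the reporting scale:
#' `(exp(log_effect) - 1) * 100` percent.  For the small effects typical
#' of exposure-response estimates this is approximately `100 * log_effect`.
#'
#' @param log_effect numeric vector of log relative-risk effects.
#' @return Percent change(s), strictly increasing in the input and always
#'   greater than -100.
#' @export
percent_change <- function(log_effect) {
  stopifnot(all(is.finite(log_effect)))
  expm1(log_effect) * 100
}

#' Exposure-response summary of a fitted model
#'
#' One row per (covariate, level): the percent change in relative risk at
#' the posterior mean, a 95% interval obtained by transforming the
#' Gaussian (Laplace) interval `mean +/- 1.96 SD` endpoint-wise, and a
#' significance flag (interval excludes 0).  Rows are ordered by covariate
#' (spec order) then level index.
#'
#' @param fit an `rr_fit`.
#' @param ci_level credible level (default 0.95).
#' @param scale `"percent"` for `(e^b - 1) * 100` (default) or `"log100"`
#'   for `100 * b` directly.
#' @return data.frame with columns `covariate`, `level`, `level_label`,
#'   `percent_change`, `ci_low`, `ci_high`, `significant`.  If the fit did
#'   not converge a warning is raised and the attribute
#'   `"nonconverged_fit"` is set to TRUE.
#' @export
summarize_rr <- function(fit, ci_level = 0.95, scale = c("percent", "log100")) {
  stopifnot(inherits(fit, "rr_fit"))
  scale <- match.arg(scale)
  if (!isTRUE(fit$converged)) {
    warning("summaries from a NON-CONVERGED fit; interpret with caution",
            call. = FALSE)
  }
  zq <- qnorm(1 - (1 - ci_level) / 2)
  tr <- if (scale == "percent") percent_change else function(b) 100 * b
  rows <- list()
  for (nm in names(fit$effects$levels)) {
    m <- fit$effects$levels[[nm]]
    s <- fit$effect_sds$levels[[nm]]
    lo <- m - zq * s
    hi <- m + zq * s
    rows[[nm]] <- data.frame(
      covariate = nm,
      level = seq_along(m) - 1L,
      level_label = names(m),
      percent_change = tr(m),
      ci_low = tr(lo),
      ci_high = tr(hi),
      significant = lo > 0 | hi < 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "nonconverged_fit") <- !isTRUE(fit$converged)
  out
}
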