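#' Exposure level schemes
#'
#' A level scheme maps a continuous covariate to ordered discrete exposure
#' levels via strictly increasing cut points.  With `k` levels there are
#' `k - 1` cut points.  Intervals are left-closed/right-open by default
#' (`boundary_rule = "left_closed"`): a value exactly at a cut point is
#' assigned to the upper level; `"right_closed"` flips this.
#'
#' @param covariate covariate name.
#' @param cut_points strictly increasing numeric vector.
#' @param labels character vector of level names, one more than cut points.
#' @param boundary_rule `"left_closed"` (default) or `"right_closed"`.
#' @return A `level_scheme` object.
#' @export
level_scheme <- function(covariate, cut_points, labels = NULL,
                         boundary_rule = c("left_closed", "right_closed")) {
  boundary_rule <- match.arg(boundary_rule)
  cut_points <- as.numeric(cut_points)
  if (length(cut_points) < 1 || any(!is.finite(cut_points))) {
    csx_stop("cut_points must be a non-empty finite numeric vector")
  }
  if (any(diff(cut_points) <= 0)) {
    csx_stop("cut_points must be strictly increasing",
             class = "climsent_scheme_error")
  }
  k <- length(cut_points) + 1L
  if (is.null(labels)) labels <- paste0("L", seq_len(k) - 1L)
  if (length(labels) != k) {
    csx_stop("need ", k, " labels for ", length(cut_points), " cut points",
             class = "climsent_scheme_error")
  }
  structure(list(covariate = covariate, cut_points = cut_points,
                 labels = as.character(labels), boundary_rule = boundary_rule),
            class = "level_scheme")
}

#' @export
print.level_scheme <- function(x, ...) {
  cat(sprintf("Level scheme for '%s' (%s): %d levels\n", x$covariate,
              x$boundary_rule, length(x$labels)))
  cat("  cuts:", paste(format(x$cut_points), collapse = ", "), "\n")
  cat("  labels:", paste(x$labels, collapse = " < "), "\n")
  invisible(x)
}

#' Default exposure level schemes
#'
#' The shipped categorisation of each climate-health covariate into the
#' ordered levels used by the relative-risk model: four temperature levels
#' (cuts 2.96, 14.9, 26.9 degrees C), four levels per pollen taxon
#' (alder cuts 0.000512, 0.262, 135 grains/m3; birch 0.000530, 0.281, 149;
#' olive 0.000393, 0.155, 61.0), three heat-attributable mortality levels
#' (cuts 1.68e-6, 0.382), three drought levels on the standardized
#' precipitation index (extreme drought below -3.72, moderate up to 1.22,
#' rainfall above), and a zero-versus-at-least-one-case split for West
#' Nile virus (cut 0.5 on the count scale).
#'
#' @return Named list of [level_scheme()] objects keyed by covariate name.
#' @export
default_schemes <- function() {
  list(
    max_temperature = level_scheme(
      "max_temperature", c(2.96, 14.9, 26.9),
      labels = c("low", "mid", "average", "high")),
    alder = level_scheme(
      "alder", c(0.000512, 0.262, 135),
      labels = c("low", "mid", "average", "high")),
    birch = level_scheme(
      "birch", c(0.000530, 0.281, 149),
      labels = c("low", "mid", "average", "high")),
    olive = level_scheme(
      "olive", c(0.000393, 0.155, 61.0),
      labels = c("low", "mid", "average", "high")),
    mortality = level_scheme(
      "mortality", c(0.00000168, 0.382),
      labels = c("low", "mid", "high")),
    spi = level_scheme(
      "spi", c(-3.72, 1.22),
      labels = c("extreme_drought", "moderate", "rainfall")),
    wnv = level_scheme(
      "wnv", 0.5,
      labels = c("zero_cases", "one_plus_cases"))
  )
}

#' Assign values to exposure levels
#'
#' Deterministic bin assignment under the scheme's boundary rule.  Missing
#' values map to `NA` (a missing-value signal, not a level).
#'
#' @param value numeric vector.
#' @param scheme a [level_scheme()].
#' @return Integer vector of 0-based ordered level indices.
#' @export
assign_level <- function(value, scheme) {
  stopifnot(inherits(scheme, "level_scheme"))
  value <- as.numeric(value)
  out <- rep(NA_integer_, length(value))
  ok <- is.finite(value)
  if (any(!is.finite(value) & !is.na(value))) {
    csx_stop("assign_level requires finite values (found Inf)")
  }
  left_open <- scheme$boundary_rule == "right_closed"
  out[ok] <- findInterval(value[ok], scheme$cut_points, left.open = left_open)
  out
}

#' Build a level scheme from sample quantiles
#'
#' Places the cut points at sample quantiles of the supplied values
#' (quantile type 7, R's default), for synthetic panels whose covariate
#' ranges do not match the shipped cut points.
#'
#' @param values numeric vector of observed covariate values.
#' @param k number of levels (>= 2).
#' @param probs optional quantile levels; default equally spaced
#'   `(1:(k-1))/k`.
#' @param covariate covariate name recorded in the scheme.
#' @return A [level_scheme()].
#' @export
quantile_scheme <- function(values, k, probs = NULL, covariate = "x") {
  if (k < 2) csx_stop("need k >= 2 levels")
  values <- values[is.finite(values)]
  if (length(unique(values)) < k) {
    csx_stop("too few distinct values for ", k, " levels",
             class = "climsent_degenerate_scheme_error")
  }
  probs <- probs %||% (seq_len(k - 1) / k)
  cuts <- unname(quantile(values, probs, type = 7))
  if (any(diff(cuts) <= 0)) {
    csx_stop("tied quantiles: cannot achieve ", k, " levels",
             class = "climsent_degenerate_scheme_error")
  }
  level_scheme(covariate, cuts)
}

#' Append level columns to a panel
#'
#' Adds one `<covariate>_level` integer column per scheme (0-based level
#' indices).  Rows with missing covariate values keep `NA` levels; the
#' count of such rows is logged.
#'
#' @param panel an `st_panel`.
#' @param schemes named list of [level_scheme()]s; default
#'   [default_schemes()] restricted to the panel's covariates.
#' @param verbose log the number of rows with missing levels.
#' @return The panel with level columns appended.
#' @export
apply_schemes <- function(panel, schemes = NULL, verbose = TRUE) {
  validate_panel(panel)
  schemes <- schemes %||% default_schemes()
  schemes <- schemes[intersect(names(schemes), panel_covariates(panel))]
  if (length(schemes) == 0) csx_stop("no scheme matches a panel covariate")
  for (nm in names(schemes)) {
    panel[[paste0(nm, "_level")]] <- assign_level(panel[[nm]], schemes[[nm]])
  }
  lev_cols <- paste0(names(schemes), "_level")
  n_missing <- sum(!stats::complete.cases(panel[, lev_cols, drop = FALSE]))
  if (n_missing > 0) {
    csx_log(n_missing, " row(s) have missing covariate levels and will be ",
            "dropped at model fit", verbose = verbose)
  }
  attr(panel, "schemes") <- schemes
  panel
}

#' Write level schemes to YAML
#' @param schemes named list of [level_scheme()]s.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_schemes <- function(schemes, path) {
  out <- lapply(schemes, function(s) {
    list(covariate = s$covariate, cut_points = as.numeric(s$cut_points),
         labels = as.list(s$labels), boundary_rule = s$boundary_rule)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read level schemes from YAML
#' @param path YAML path written by [write_schemes()].
#' @return Named list of [level_scheme()]s.
#' @export
read_schemes <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(s) {
    level_scheme(s$covariate, as.numeric(unlist(s$cut_points)),
                 labels = as.character(unlist(s$labels)),
                 boundary_rule = s$boundary_rule %||% "left_closed")
  })
  names(out) <- vapply(out, function(s) s$covariate, character(1))
  out
}
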