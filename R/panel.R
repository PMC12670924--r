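#' Spatio-temporal panels of tweet counts and exposures
#'
#' A spatio-temporal panel is a `data.frame` (class `st_panel`) with one row
#' per region-week, holding the total tweet count `total_count` (CT), the
#' negative-sentiment tweet count `negative_count` (Y), the region and
#' country labels, a consecutive integer week index, and one column per
#' exposure covariate (weekly maximum temperature in degrees C, pollen
#' concentrations in grains/m3, the standardized precipitation index,
#' heat-attributable mortality rate and West Nile virus case counts).
#'
#' Invariants enforced by [validate_panel()]:
#' * `negative_count <= total_count` on every row;
#' * counts are non-negative integers;
#' * `(region, week)` pairs are unique;
#' * every region belongs to exactly one country;
#' * week indices are contiguous within each region.
#'
#' @param x data.frame with columns `region`, `country`, `week`,
#'   `total_count`, `negative_count` plus covariate columns.
#' @param covariates character vector naming the covariate columns; by
#'   default every column that is not a reserved panel column and does not
#'   end in `_level`.
#' @return An `st_panel` data.frame.
#' @export
as_st_panel <- function(x, covariates = NULL) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x)
  reserved <- c("region", "country", "week", "total_count", "negative_count")
  missing_cols <- setdiff(reserved, names(x))
  if (length(missing_cols) > 0) {
    csx_stop("panel is missing required column(s): ",
             paste(missing_cols, collapse = ", "),
             class = "climsent_schema_error")
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(x), reserved)
    covariates <- covariates[!grepl("_level$", covariates)]
  }
  x$region <- as.character(x$region)
  x$country <- as.character(x$country)
  x$week <- as.integer(x$week)
  attr(x, "covariates") <- covariates
  class(x) <- unique(c("st_panel", class(x)))
  validate_panel(x)
}

#' Covariate columns of a panel
#' @param panel an `st_panel`.
#' @return Character vector of covariate column names.
#' @export
panel_covariates <- function(panel) {
  attr(panel, "covariates") %||% character(0)
}

#' Validate a spatio-temporal panel
#'
#' Checks every panel invariant and fails with an informative error naming
#' the offending rows or columns.
#'
#' @param panel an `st_panel` data.frame.
#' @return The panel, invisibly unchanged, if valid.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "st_panel"))
  bad <- !is_count(panel$total_count)
  if (any(bad)) {
    csx_stop("total_count must be a non-negative integer; offending row(s): ",
             paste(head(which(bad), 5), collapse = ", "),
             class = "climsent_validation_error")
  }
  bad <- !is_count(panel$negative_count)
  if (any(bad)) {
    csx_stop("negative_count must be a non-negative integer; offending row(s): ",
             paste(head(which(bad), 5), collapse = ", "),
             class = "climsent_validation_error")
  }
  bad <- panel$negative_count > panel$total_count
  if (any(bad)) {
    i <- which(bad)[1]
    csx_stop("negative_count exceeds total_count, e.g. row ", i,
             " (region ", panel$region[i], ", week ", panel$week[i], "): ",
             panel$negative_count[i], " > ", panel$total_count[i],
             class = "climsent_validation_error")
  }
  key <- paste(panel$region, panel$week, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    csx_stop("duplicated (region, week) pair: region ", panel$region[i],
             ", week ", panel$week[i],
             class = "climsent_validation_error")
  }
  n_country <- tapply(panel$country, panel$region, function(ctry) length(unique(ctry)))
  if (any(n_country > 1)) {
    csx_stop("region(s) mapped to more than one country: ",
             paste(names(n_country)[n_country > 1], collapse = ", "),
             class = "climsent_validation_error")
  }
  for (r in unique(panel$region)) {
    w <- sort(panel$week[panel$region == r])
    if (length(w) > 1 && any(diff(w) != 1L)) {
      csx_stop("week indices are not contiguous for region ", r,
               " (gap after week ", w[which(diff(w) != 1L)[1]], ")",
               class = "climsent_validation_error")
    }
  }
  invisible(panel)
}

#' Read a panel from CSV
#'
#' Reads a region-week panel from an UTF-8 CSV file with a header, applies
#' an optional schema map renaming file columns to the standard panel
#' columns, and validates all panel invariants.  Alternatively to a `week`
#' column the file may carry `iso_year` and `iso_week` columns, which are
#' converted to a consecutive integer week index (ISO-8601 weeks).
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping standard column
#'   names to file column names, e.g. `c(region = "nuts2")`.  May also be a
#'   path to a YAML file with a `columns:` map.
#' @param covariates optional character vector of covariate columns.
#' @return An `st_panel`.
#' @export
read_panel <- function(path, schema = NULL, covariates = NULL) {
  if (!file.exists(path)) csx_stop("no such file: ", path)
  x <- as.data.frame(data.table::fread(path, encoding = "UTF-8"))
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema <- unlist(yaml::read_yaml(schema)$columns)
  }
  if (!is.null(schema)) {
    for (std in names(schema)) {
      src <- schema[[std]]
      if (!src %in% names(x)) {
        csx_stop("schema column not found in file: ", src,
                 class = "climsent_schema_error")
      }
      names(x)[names(x) == src] <- std
    }
  }
  if (!"week" %in% names(x) && all(c("iso_year", "iso_week") %in% names(x))) {
    x$week <- iso_week_index(x$iso_year, x$iso_week)
    x$iso_year <- NULL
    x$iso_week <- NULL
  }
  as_st_panel(x, covariates = covariates)
}

#' Write a panel to CSV
#'
#' Writes the panel with full floating-point precision so that
#' `read_panel(write_panel(p))` reproduces `p` exactly.
#'
#' @param panel an `st_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  cols <- c("region", "country", "week", "total_count", "negative_count",
            panel_covariates(panel))
  extra <- setdiff(names(panel), cols)
  out <- as.data.frame(panel)[, c(cols, extra), drop = FALSE]
  ok <- tryCatch({
    data.table::fwrite(out, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) csx_stop("cannot write panel to ", path, ": ",
                            conditionMessage(ok))
  invisible(path)
}

#' Convert ISO year-week pairs to a consecutive week index
#'
#' Week indices are 0-based and count ISO-8601 weeks from the earliest
#' year-week present in the input.  ISO years have 52 or 53 weeks; the
#' week count of a year is derived from the ISO week number of 28 December.
#'
#' @param iso_year integer vector of ISO years.
#' @param iso_week integer vector of ISO week numbers (1-53).
#' @return Integer vector of consecutive 0-based week indices.
#' @export
iso_week_index <- function(iso_year, iso_week) {
  stopifnot(length(iso_year) == length(iso_week))
  if (any(iso_week < 1 | iso_week > 53, na.rm = TRUE)) {
    csx_stop("iso_week must be in 1..53")
  }
  years <- seq(min(iso_year), max(iso_year))
  weeks_in_year <- vapply(years, function(y) {
    # 28 December always falls in the last ISO week of its year
    as.integer(format(as.Date(sprintf("%d-12-28", y)), "%V"))
  }, integer(1))
  offset <- c(0L, cumsum(weeks_in_year))[match(iso_year, years)]
  idx <- offset + as.integer(iso_week) - 1L
  idx - min(idx)
}

#' Overall negative-sentiment baseline proportion
#'
#' Computes theta_tot, the ratio of negative-sentiment tweets to total
#' tweets pooled over the whole panel.  This is the global baseline rate
#' that multiplies the tweet-volume offset in the relative-risk model.
#'
#' @param panel an `st_panel`.
#' @return A list of class `baseline_rate` with element `theta_tot`.
#' @export
compute_theta_tot <- function(panel) {
  validate_panel(panel)
  ct <- sum(as.numeric(panel$total_count))
  if (ct <= 0) {
    csx_stop("degenerate panel: all total counts are zero",
             class = "climsent_degenerate_error")
  }
  structure(list(theta_tot = sum(as.numeric(panel$negative_count)) / ct),
            class = "baseline_rate")
}

#' @export
print.baseline_rate <- function(x, ...) {
  cat(sprintf("Baseline negative-sentiment proportion theta_tot = %.6g\n",
              x$theta_tot))
  invisible(x)
}

#' @export
print.st_panel <- function(x, ...) {
  cat(sprintf(
    "Spatio-temporal panel: %d rows, %d regions, %d countries, weeks %d..%d\n",
    nrow(x), length(unique(x$region)), length(unique(x$country)),
    min(x$week), max(x$week)))
  cat("Covariates:", paste(panel_covariates(x), collapse = ", "), "\n")
  NextMethod()
}
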