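#' Exact 1-D sparse fused lasso
#'
#' Solves
#' \deqn{\min_\beta \tfrac12 \sum_t w_t (y_t - \beta_t)^2
#'   + \lambda_{fuse} \sum_t |\beta_{t+1} - \beta_t|
#'   + \lambda_{sparse} \sum_t |\beta_t|}
#' exactly, by dynamic programming over piecewise-quadratic value
#' functions: the derivative of each Bellman message is a continuous
#' nondecreasing piecewise-linear function that is clipped at
#' `+/- lambda_fuse` at every step, and the solution is recovered by a
#' backward clamping pass.  The magnitude penalty is applied through the
#' exact soft-threshold reduction (valid for uniform weights): the sparse
#' solution is the pure-fusion solution soft-thresholded by
#' `lambda_sparse / w`.
#'
#' @param y numeric vector (one country's weekly signal).
#' @param lambda_fuse non-negative penalty on successive differences.
#' @param lambda_sparse non-negative penalty on coefficient magnitudes.
#' @param weights optional non-negative per-week precision weights
#'   (default 1).  Must be uniform when `lambda_sparse > 0`.
#' @param tol tolerance used to declare adjacent coefficients equal when
#'   extracting intervals.
#' @return A `fused_lasso_fit`: list with `beta` (piecewise constant),
#'   `intervals` (0-based interval index per week), `objective`,
#'   `lambda_fuse`, `lambda_sparse`, `weights`.
#' @export
solve_fused_lasso_1d <- function(y, lambda_fuse, lambda_sparse = 0,
                                 weights = NULL, tol = 1e-8) {
  n <- length(y)
  if (n == 0) csx_stop("empty input series", class = "climsent_empty_fit_error")
  if (any(!is.finite(y))) csx_stop("y must be finite")
  if (lambda_fuse < 0 || lambda_sparse < 0) csx_stop("penalties must be >= 0")
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(!is.finite(w)) || any(w < 0)) {
    csx_stop("weights must be non-negative, finite, length(y)")
  }
  if (lambda_sparse > 0 && diff(range(w)) > 1e-12 * max(w, 1)) {
    csx_stop("the sparse penalty requires uniform weights ",
             "(soft-threshold reduction)")
  }

  beta <- fused_dp(y, w, lambda_fuse)
  if (lambda_sparse > 0) {
    w0 <- w[1]
    beta <- if (w0 > 0) {
      sign(beta) * pmax(abs(beta) - lambda_sparse / w0, 0)
    } else {
      rep(0, n)
    }
  }
  obj <- 0.5 * sum(w * (y - beta)^2) +
    lambda_fuse * sum(abs(diff(beta))) + lambda_sparse * sum(abs(beta))
  structure(list(beta = beta,
                 intervals = extract_intervals(beta, tol),
                 objective = obj,
                 lambda_fuse = lambda_fuse, lambda_sparse = lambda_sparse,
                 weights = w),
            class = "fused_lasso_fit")
}

# first b with f'(b) == level for a nondecreasing piecewise-linear
# derivative given by knots x, values d, slopes s (length(x) + 1)
pwl_crossing <- function(x, d, s, level) {
  m <- length(x)
  if (d[1] >= level) {
    if (s[1] > 0) return(x[1] - (d[1] - level) / s[1])
    return(-Inf)
  }
  j <- which(d >= level)
  if (length(j) == 0) {
    if (s[m + 1] > 0) return(x[m] + (level - d[m]) / s[m + 1])
    return(Inf)
  }
  j <- j[1]  # crossing in (x[j-1], x[j]]
  sj <- s[j]
  if (sj <= 0) return(x[j])
  x[j - 1] + (level - d[j - 1]) / sj
}

# slope of the segment containing point b (b not a knot)
pwl_slope_at <- function(x, s, b) s[findInterval(b, x) + 1L]

fused_dp <- function(y, w, lam) {
  n <- length(y)
  if (n == 1) {
    # single point: derivative w (b - y); root y (or 0 if w == 0)
    return(if (w[1] > 0) y[1] else 0)
  }
  lo <- numeric(n - 1)
  hi <- numeric(n - 1)
  # seed message with the first quadratic
  x <- y[1]; d <- 0; s <- c(w[1], w[1])
  for (t in seq_len(n - 1)) {
    if (lam == 0) {
      r <- pwl_crossing(x, d, s, 0)
      if (!is.finite(r)) r <- x[1]
      lo[t] <- r; hi[t] <- r
      x <- r; d <- 0; s <- c(0, 0)
    } else {
      lo_t <- pwl_crossing(x, d, s, -lam)
      hi_t <- pwl_crossing(x, d, s, lam)
      if (!is.finite(lo_t) && !is.finite(hi_t)) {
        # flat derivative strictly inside (-lam, lam): no clipping
        lo[t] <- -Inf; hi[t] <- Inf
      } else {
        keep <- which(x > lo_t & x < hi_t)
        new_x <- c(if (is.finite(lo_t)) lo_t, x[keep], if (is.finite(hi_t)) hi_t)
        new_d <- c(if (is.finite(lo_t)) -lam, d[keep], if (is.finite(hi_t)) lam)
        k <- length(new_x)
        new_s <- numeric(k + 1)
        new_s[1] <- if (is.finite(lo_t)) 0 else s[1]
        new_s[k + 1] <- if (is.finite(hi_t)) 0 else s[length(s)]
        if (k > 1) {
          mids <- (new_x[-k] + new_x[-1]) / 2
          new_s[2:k] <- vapply(mids, function(b) pwl_slope_at(x, s, b),
                               numeric(1))
        }
        lo[t] <- lo_t; hi[t] <- hi_t
        x <- new_x; d <- new_d; s <- new_s
      }
    }
    # add the next quadratic w[t+1] * (b - y[t+1])
    d <- d + w[t + 1] * (x - y[t + 1])
    s <- s + w[t + 1]
  }
  beta <- numeric(n)
  r <- pwl_crossing(x, d, s, 0)
  if (!is.finite(r)) r <- if (is.finite(x[1])) x[1] else 0
  beta[n] <- r
  for (t in (n - 1):1) beta[t] <- min(max(beta[t + 1], lo[t]), hi[t])
  beta
}

#' Interval index of a piecewise-constant series
#'
#' Maps each week to the index of the constant segment containing it:
#' the index starts at 0 and increments by one exactly where the absolute
#' successive difference of `beta` exceeds `tol`.
#'
#' @param beta numeric vector (typically a fused lasso solution).
#' @param tol positive tolerance on the coefficient scale.
#' @return Integer vector of 0-based, nondecreasing interval indices.
#' @export
extract_intervals <- function(beta, tol = 1e-8) {
  if (any(!is.finite(beta))) csx_stop("beta must be finite")
  stopifnot(tol > 0)
  if (length(beta) == 0) return(integer(0))
  as.integer(cumsum(c(0, abs(diff(beta)) > tol)))
}

#' Default penalty grid for [select_penalties()]
#'
#' A log-spaced grid of fusion penalties scaled by the SD of the signal
#' (`sd(y) * 2^(-4..6)` in half-power steps) with no magnitude penalty.
#'
#' @param y the signal the grid will be applied to.
#' @return List with components `lambda_fuse` and `lambda_sparse`.
#' @export
default_penalty_grid <- function(y) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) s <- 1
  list(lambda_fuse = s * 2^seq(-4, 6, by = 0.5), lambda_sparse = 0)
}

#' Select fused lasso penalties by BIC
#'
#' Scores every grid point with
#' `BIC = RSS / sigma^2 + log(T) * df`, where `df` is the number of
#' distinct non-zero coefficient levels of the solution and `sigma` is a
#' robust difference-based noise scale, `MAD(diff(y)) / sqrt(2)`
#' (insensitive to the jumps the fused lasso is meant to find), and
#' returns the minimiser; ties are broken toward the larger fusion
#' penalty (the smoother solution).  The known-variance form keeps the
#' criterion well-behaved near interpolating solutions, where the
#' profiled-variance form `T log(RSS/T)` degenerates.  A constant input
#' signal returns the largest grid point with a logged note.
#'
#' @param y numeric signal.
#' @param grid list with `lambda_fuse` and `lambda_sparse` vectors;
#'   default [default_penalty_grid()].
#' @param weights optional precision weights passed to the solver.
#' @param tol interval-extraction tolerance.
#' @param verbose log notes.
#' @return List with `lambda_fuse`, `lambda_sparse` and the full `bic`
#'   table (data.frame).
#' @export
select_penalties <- function(y, grid = NULL, weights = NULL, tol = 1e-8,
                             verbose = FALSE) {
  grid <- grid %||% default_penalty_grid(y)
  if (length(grid$lambda_fuse) == 0) csx_stop("empty penalty grid")
  grid$lambda_sparse <- grid$lambda_sparse %||% 0
  n <- length(y)
  combos <- expand.grid(lambda_fuse = sort(grid$lambda_fuse),
                        lambda_sparse = sort(grid$lambda_sparse))
  if (sd(y) == 0 || !is.finite(sd(y))) {
    csx_log("constant signal: returning largest penalty grid point",
            verbose = verbose)
    i <- nrow(combos)
    return(list(lambda_fuse = combos$lambda_fuse[i],
                lambda_sparse = combos$lambda_sparse[i], bic = NULL))
  }
  w <- weights %||% rep(1, n)
  sigma2 <- (stats::mad(diff(y)) / sqrt(2))^2
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- var(y)
  bic <- numeric(nrow(combos))
  df <- integer(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    fit <- solve_fused_lasso_1d(y, combos$lambda_fuse[i],
                                combos$lambda_sparse[i], weights = weights,
                                tol = tol)
    rss <- sum(w * (y - fit$beta)^2)
    seg_vals <- fit$beta[!duplicated(fit$intervals)]
    df[i] <- sum(abs(seg_vals) > tol)
    bic[i] <- rss / sigma2 + log(n) * df[i]
  }
  best <- which(bic <= min(bic) + 1e-9)
  # among ties prefer the largest fusion penalty, then largest sparse
  best <- best[order(combos$lambda_fuse[best], combos$lambda_sparse[best],
                     decreasing = TRUE)][1]
  list(lambda_fuse = combos$lambda_fuse[best],
       lambda_sparse = combos$lambda_sparse[best],
       bic = cbind(combos, df = df, bic = bic))
}

#' Refine and merge a fused lasso segmentation
#'
#' Post-selection pruning for fused lasso segmentations.  The L1 fusion
#' penalty shrinks large jumps and tends to staircase them into several
#' intermediate levels, occasionally with boundaries displaced by a week;
#' this step alternates two exact operations until a fixed point:
#' boundary refinement — each change point is moved to the weighted
#' two-mean least-squares optimum within its two adjacent segments — and
#' merging of the adjacent pair whose standardized refitted mean
#' difference `|m1 - m2| / (sigma * sqrt(1/n1 + 1/n2))` is smallest,
#' while it falls below the universal threshold `sqrt(2 log T)`.
#' Segment means are refitted exactly, so the returned levels are
#' unbiased, unlike the shrunk fused-lasso coefficients.
#'
#' @param y the signal that was segmented.
#' @param intervals 0-based interval index (from [extract_intervals()]).
#' @param weights optional weights for refit and boundary placement; the
#'   noise model of the merge test is unweighted.
#' @param sigma noise scale; default the robust difference-based estimate
#'   `MAD(diff(y)) / sqrt(2)`.
#' @param crit merge threshold on the standardized difference; default
#'   the interval-scan threshold `sqrt(2 * log(T * (T + 1) / 2))`
#'   (the segments being compared are data-selected intervals, so the
#'   relevant null maximum is over all O(T^2) intervals, not T points).
#' @return List with `intervals` (pruned, consecutive from 0) and `beta`
#'   (refitted piecewise-constant means).
#' @export
prune_segments <- function(y, intervals, weights = NULL, sigma = NULL,
                           crit = NULL) {
  n <- length(y)
  stopifnot(length(intervals) == n)
  if (n == 0) return(list(intervals = integer(0), beta = numeric(0)))
  w <- weights %||% rep(1, n)
  sigma <- sigma %||% (stats::mad(diff(y)) / sqrt(2))
  if (!is.finite(sigma) || sigma <= 0) sigma <- max(sd(y), .Machine$double.eps)
  crit <- crit %||% sqrt(2 * log(max(n, 2) * (max(n, 2) + 1) / 2))
  iv <- as.integer(intervals)

  refine_once <- function(iv) {
    ids <- sort(unique(iv))
    changed <- FALSE
    for (j in seq_len(length(ids) - 1)) {
      sel <- which(iv == ids[j] | iv == ids[j + 1])
      m <- length(sel)
      yy <- y[sel]; ww <- pmax(w[sel], 1e-12)
      cw <- cumsum(ww); cwy <- cumsum(ww * yy)
      p <- seq_len(m - 1)
      # weighted RSS of a two-mean fit split after position p (constant
      # total sum of squares dropped)
      score <- -(cwy[p]^2 / cw[p]) -
        ((cwy[m] - cwy[p])^2 / (cw[m] - cw[p]))
      best <- which.min(score)
      cur <- sum(iv[sel] == ids[j])
      if (best != cur) {
        iv[sel] <- ids[j]
        iv[sel[(best + 1):m]] <- ids[j + 1]
        changed <- TRUE
      }
    }
    list(iv = iv, changed = changed)
  }

  for (pass in 1:50) {
    r <- refine_once(iv)
    iv <- r$iv
    ids <- sort(unique(iv))
    k <- length(ids)
    merged <- FALSE
    if (k > 1) {
      m <- vapply(ids, function(id) {
        sel <- iv == id
        sum(w[sel] * y[sel]) / sum(w[sel])
      }, numeric(1))
      len <- vapply(ids, function(id) sum(iv == id), numeric(1))
      z <- abs(diff(m)) / (sigma * sqrt(1 / len[-k] + 1 / len[-1]))
      j <- which.min(z)
      if (z[j] < crit) {
        iv[iv >= ids[j + 1]] <- iv[iv >= ids[j + 1]] - 1L
        merged <- TRUE
      }
    }
    if (!r$changed && !merged) break
  }
  ids <- sort(unique(iv))
  beta <- numeric(n)
  for (id in ids) {
    sel <- iv == id
    beta[sel] <- sum(w[sel] * y[sel]) / sum(w[sel])
  }
  list(intervals = match(iv, ids) - 1L, beta = beta)
}

#' Country-week log relative-rate anomaly
#'
#' The per-country weekly signal the fused lasso stage is fitted to:
#' for country c and week t,
#' `log((sum_Y + 0.5) / (theta_tot * sum_CT + 0.5))`, the log of the
#' observed negative-count total against its baseline expectation, with
#' +0.5 continuity corrections guarding zero counts.  Weekly total tweet
#' counts are returned as optional precision weights.
#'
#' @param panel an `st_panel`.
#' @param theta a `baseline_rate`, a plain number, or NULL to compute
#'   [compute_theta_tot()] from the panel.
#' @return Named list (one entry per country) of lists with `week`,
#'   `signal`, `weight`.  Countries with zero tweet volume in every week
#'   are excluded with a warning.
#' @export
country_signal <- function(panel, theta = NULL) {
  validate_panel(panel)
  theta <- theta %||% compute_theta_tot(panel)
  if (inherits(theta, "baseline_rate")) theta <- theta$theta_tot
  stopifnot(is.numeric(theta), theta > 0)
  out <- list()
  for (ctry in sort(unique(panel$country))) {
    sub <- panel[panel$country == ctry, ]
    ag_y <- tapply(as.numeric(sub$negative_count), sub$week, sum)
    ag_ct <- tapply(as.numeric(sub$total_count), sub$week, sum)
    wk <- as.integer(names(ag_y))
    ord <- order(wk)
    wk <- wk[ord]; ag_y <- as.numeric(ag_y[ord]); ag_ct <- as.numeric(ag_ct[ord])
    if (all(ag_ct == 0)) {
      warning("country ", ctry, " has zero tweet volume in every week; excluded")
      next
    }
    out[[ctry]] <- list(week = wk,
                        signal = log((ag_y + 0.5) / (theta * ag_ct + 0.5)),
                        weight = ag_ct)
  }
  out
}

#' Per-country fused lasso change-point stage
#'
#' Runs the full first inference stage: computes each country's weekly log
#' relative-rate anomaly, selects penalties by BIC, solves the fused lasso
#' exactly and extracts the piecewise-constant interval index `I(t)` that
#' the relative-risk model uses to index its per-country random effects.
#'
#' @param panel an `st_panel`.
#' @param theta baseline rate (see [country_signal()]).
#' @param grid penalty grid; default [default_penalty_grid()] per country.
#' @param weighted use weekly tweet totals as precision weights (default
#'   FALSE: unweighted signal smoothing).
#' @param center `"median"` (default) subtracts the cross-country weekly
#'   median anomaly before fusing, so change points reflect
#'   country-specific shocks rather than the shared temporal field (which
#'   the relative-risk model's AR(1) component is meant to capture); with
#'   few countries the median leaves a single country's shock intact.
#'   `"none"` fuses the raw anomaly.
#' @param prune merge statistically indistinguishable adjacent segments
#'   and refit exact segment means afterwards (default TRUE; see
#'   [prune_segments()]), removing the staircase artifact that L1 fusion
#'   leaves around large shocks.
#' @param tol interval-extraction tolerance.
#' @return data.frame with columns `country`, `week`, `signal` (the series
#'   actually fused), `beta` (refitted when pruning), `interval`, plus a
#'   `penalties` attribute (per-country list).
#' @export
country_fused_intervals <- function(panel, theta = NULL, grid = NULL,
                                    weighted = FALSE,
                                    center = c("median", "none"),
                                    prune = TRUE,
                                    tol = 1e-8) {
  center <- match.arg(center)
  sigs <- country_signal(panel, theta)
  if (center == "median" && length(sigs) > 1) {
    wk_all <- sort(unique(unlist(lapply(sigs, `[[`, "week"))))
    smat <- vapply(sigs, function(s) {
      s$signal[match(wk_all, s$week)]
    }, numeric(length(wk_all)))
    med <- apply(smat, 1, stats::median, na.rm = TRUE)
    for (ctry in names(sigs)) {
      sigs[[ctry]]$signal <- sigs[[ctry]]$signal -
        med[match(sigs[[ctry]]$week, wk_all)]
    }
  }
  rows <- list()
  pens <- list()
  for (ctry in names(sigs)) {
    s <- sigs[[ctry]]
    w <- if (weighted) s$weight else NULL
    pen <- select_penalties(s$signal, grid = grid, weights = w, tol = tol)
    fit <- solve_fused_lasso_1d(s$signal, pen$lambda_fuse, pen$lambda_sparse,
                                weights = w, tol = tol)
    seg <- if (prune) {
      prune_segments(s$signal, fit$intervals, weights = w)
    } else {
      list(intervals = fit$intervals, beta = fit$beta)
    }
    pens[[ctry]] <- pen[c("lambda_fuse", "lambda_sparse")]
    rows[[ctry]] <- data.frame(country = ctry, week = s$week,
                               signal = s$signal, beta = seg$beta,
                               interval = seg$intervals,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "penalties") <- pens
  out
}
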