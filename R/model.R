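#' Model specification for the hierarchical Poisson relative-risk model
#'
#' Describes the latent-effect layout of the model
#' `Y(i,t) ~ Poisson(theta_tot * CT(i,t) * RR(i,t))` with
#' `log RR = intercept + temporal AR(1) field (shared across regions) +
#' iid spatial effect + per-covariate exposure-level effects + per-country
#' fused-interval effects`.  All random-effect blocks carry iid Gaussian
#' priors with block-specific precisions except the temporal block, which
#' carries a stationary AR(1) prior with unit-marginal-variance
#' parameterisation (precision `tau_temporal`, lag-1 correlation `rho`).
#' Sum-to-zero constraints are imposed on the temporal, spatial and
#' exposure-level blocks and on the fused block within each country; the
#' overall level is carried by a weakly penalised global intercept.
#'
#' @param covariates named integer vector mapping covariate names to their
#'   number of levels, or NULL to infer from the panel's `_level` columns
#'   and attached schemes at fit time.
#' @param include_temporal_ar1 include the shared weekly AR(1) field.
#' @param include_spatial_iid include the iid per-region effect.
#' @param include_fused include per-country fused-interval effects (needs
#'   a `fused` table at fit time).
#' @param hyper_prior_mean,hyper_prior_sd log-normal hyperprior on each
#'   block precision, on the log-precision scale (defaults 0 and 2: wide).
#' @param rho_prior_sd SD of the Gaussian prior on `atanh(rho)`.
#' @param intercept_prior_sd SD of the Gaussian prior on the intercept.
#' @param fixed_precisions named list of block precisions to hold fixed
#'   (names: covariate names, `"temporal"`, `"spatial"`, `"fused"`);
#'   fixed blocks are excluded from empirical-Bayes optimisation.
#' @param control a [model_control()] list.
#' @return A `model_spec` object.
#' @export
model_spec <- function(covariates = NULL,
                       include_temporal_ar1 = TRUE,
                       include_spatial_iid = TRUE,
                       include_fused = TRUE,
                       hyper_prior_mean = 0,
                       hyper_prior_sd = 2,
                       rho_prior_sd = 1.5,
                       intercept_prior_sd = 10,
                       fixed_precisions = list(),
                       control = model_control()) {
  structure(list(covariates = covariates,
                 include_temporal_ar1 = include_temporal_ar1,
                 include_spatial_iid = include_spatial_iid,
                 include_fused = include_fused,
                 hyper_prior_mean = hyper_prior_mean,
                 hyper_prior_sd = hyper_prior_sd,
                 rho_prior_sd = rho_prior_sd,
                 intercept_prior_sd = intercept_prior_sd,
                 fixed_precisions = fixed_precisions,
                 control = control),
            class = "model_spec")
}

#' Numerical control parameters for [fit_rr_model()]
#'
#' @param inner_tol inf-norm gradient tolerance of the inner Newton loop.
#' @param inner_maxit maximum inner Newton iterations per evaluation.
#' @param outer_maxit maximum outer quasi-Newton iterations.
#' @param outer_factr L-BFGS-B `factr` (relative-improvement stop).
#' @param outer_pgtol L-BFGS-B projected-gradient tolerance.
#' @param eta_clip upper clip on the linear predictor guarding overflow.
#' @return A list of control values.
#' @export
model_control <- function(inner_tol = 1e-6, inner_maxit = 100,
                          outer_maxit = 50, outer_factr = 1e9,
                          outer_pgtol = 0.05, eta_clip = 30) {
  list(inner_tol = inner_tol, inner_maxit = inner_maxit,
       outer_maxit = outer_maxit, outer_factr = outer_factr,
       outer_pgtol = outer_pgtol, eta_clip = eta_clip)
}

# AR(1) precision matrix with unit marginal variance, sparse tridiagonal
ar1_precision <- function(n, rho) {
  if (n == 1) return(Matrix::Matrix(1, 1, 1, sparse = TRUE))
  d <- c(1, rep(1 + rho^2, n - 2), 1) / (1 - rho^2)
  od <- rep(-rho / (1 - rho^2), n - 1)
  Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                     diagonals = list(od, d, od), symmetric = FALSE)
}

infer_covariates <- function(panel, spec) {
  if (!is.null(spec$covariates)) {
    covs <- spec$covariates
    if (is.null(names(covs)) || any(names(covs) == "")) {
      csx_stop("spec$covariates must be a named integer vector")
    }
    return(covs)
  }
  schemes <- attr(panel, "schemes")
  lev_cols <- grep("_level$", names(panel), value = TRUE)
  nms <- sub("_level$", "", lev_cols)
  k <- vapply(seq_along(nms), function(i) {
    if (!is.null(schemes[[nms[i]]])) {
      length(schemes[[nms[i]]]$labels)
    } else {
      as.integer(max(panel[[lev_cols[i]]], na.rm = TRUE)) + 1L
    }
  }, integer(1))
  stats::setNames(k, nms)
}

# builds observation vectors, the sparse indicator design in the full
# (unconstrained) effect parameterisation, and the constraint bases
build_frame <- function(panel, spec, fused, theta) {
  validate_panel(panel)
  covs <- infer_covariates(panel, spec)
  lev_cols <- if (length(covs)) paste0(names(covs), "_level") else character(0)
  miss <- setdiff(lev_cols, names(panel))
  if (length(miss) > 0) {
    csx_stop("panel lacks level column(s): ", paste(miss, collapse = ", "),
             " (run apply_schemes first)")
  }
  weeks <- sort(unique(panel$week))
  regions <- sort(unique(panel$region))
  region_country <- vapply(regions, function(r) {
    panel$country[match(r, panel$region)]
  }, character(1))

  lev_ok <- stats::complete.cases(panel[, lev_cols, drop = FALSE])
  n_missing <- sum(!lev_ok)
  obs <- which(panel$total_count > 0 & lev_ok)
  if (length(obs) == 0) csx_stop("no usable observations (CT>0, levels present)")

  y <- as.numeric(panel$negative_count[obs])
  ct <- as.numeric(panel$total_count[obs])
  offset <- log(theta) + log(ct)
  widx <- match(panel$week[obs], weeks)
  ridx <- match(panel$region[obs], regions)

  # x-parameterisation column layout
  blocks <- list(intercept = 1L)
  if (spec$include_temporal_ar1) blocks$temporal <- length(weeks)
  if (spec$include_spatial_iid) blocks$spatial <- length(regions)
  for (nm in names(covs)) blocks[[nm]] <- as.integer(covs[[nm]])

  fused_levels <- NULL
  fused_key <- NULL
  if (spec$include_fused && !is.null(fused)) {
    stopifnot(all(c("country", "week", "interval") %in% names(fused)))
    fused_key <- fused
    m_c <- tapply(fused$interval, fused$country, function(v) max(v) + 1L)
    fused_levels <- lapply(sort(names(m_c)), function(ctry) {
      list(country = ctry, m = as.integer(m_c[[ctry]]))
    })
    blocks$fused <- sum(vapply(fused_levels, `[[`, integer(1), "m"))
  }

  offs <- cumsum(c(0L, unlist(blocks)))
  names(offs) <- c(names(blocks), "END")
  p_x <- offs[["END"]]

  n <- length(obs)
  tri_i <- list(); tri_j <- list()
  add <- function(jcol) {
    tri_i[[length(tri_i) + 1]] <<- seq_len(n)
    tri_j[[length(tri_j) + 1]] <<- jcol
  }
  add(rep(1L, n))                                        # intercept
  if (spec$include_temporal_ar1) add(offs[["temporal"]] + widx)
  if (spec$include_spatial_iid) add(offs[["spatial"]] + ridx)
  for (nm in names(covs)) {
    lev <- as.integer(panel[[paste0(nm, "_level")]][obs])
    if (any(lev < 0 | lev >= covs[[nm]])) {
      csx_stop("level index out of range for covariate '", nm, "'")
    }
    cnt <- tabulate(lev + 1L, nbins = covs[[nm]])
    if (any(cnt == 0)) {
      warning("covariate '", nm, "' has empty level(s) ",
              paste(which(cnt == 0) - 1L, collapse = ", "),
              "; their effects are prior-dominated", call. = FALSE)
    }
    add(offs[[nm]] + lev + 1L)
  }
  if (!is.null(fused_levels)) {
    key <- paste(fused$country, fused$week, sep = "\r")
    row_key <- paste(panel$country[obs], panel$week[obs], sep = "\r")
    pos <- match(row_key, key)
    if (anyNA(pos)) {
      i <- which(is.na(pos))[1]
      csx_stop("no fused interval for country ", panel$country[obs][i],
               ", week ", panel$week[obs][i])
    }
    ctries <- vapply(fused_levels, `[[`, character(1), "country")
    m_vec <- vapply(fused_levels, `[[`, integer(1), "m")
    c_off <- cumsum(c(0L, m_vec))
    cidx <- match(fused$country[pos], ctries)
    add(offs[["fused"]] + c_off[cidx] + fused$interval[pos] + 1L)
  }
  X <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j), x = 1,
                            dims = c(n, p_x))

  # constraint bases: sum-to-zero for every block except the intercept
  zblocks <- list(intercept = matrix(1, 1, 1))
  if (spec$include_temporal_ar1) zblocks$temporal <- sum_zero_basis(length(weeks))
  if (spec$include_spatial_iid) zblocks$spatial <- sum_zero_basis(length(regions))
  for (nm in names(covs)) zblocks[[nm]] <- sum_zero_basis(covs[[nm]])
  if (!is.null(fused_levels)) {
    m_vec <- vapply(fused_levels, `[[`, integer(1), "m")
    zb <- lapply(m_vec, sum_zero_basis)
    zf <- matrix(0, sum(m_vec), sum(pmax(m_vec - 1L, 0L)))
    ro <- 0L; co <- 0L
    for (b in zb) {
      if (ncol(b) > 0) zf[ro + seq_len(nrow(b)), co + seq_len(ncol(b))] <- b
      ro <- ro + nrow(b); co <- co + ncol(b)
    }
    zblocks$fused <- zf
  }
  Z <- Matrix::bdiag(lapply(zblocks, Matrix::Matrix, sparse = TRUE))
  Z <- methods::as(Z, "CsparseMatrix")

  zdims <- vapply(zblocks, ncol, integer(1))
  zoffs <- cumsum(c(0L, zdims))
  names(zoffs) <- c(names(zblocks), "END")
  zindex <- lapply(seq_along(zdims), function(i) {
    if (zdims[i] == 0) integer(0) else zoffs[i] + seq_len(zdims[i])
  })
  names(zindex) <- names(zblocks)

  list(y = y, ct = ct, offset = offset, obs = obs, n_missing = n_missing,
       weeks = weeks, regions = regions, region_country = region_country,
       covariates = covs, X = X, Z = Z, zblocks = zblocks, zindex = zindex,
       xoffs = offs, fused_levels = fused_levels, fused_key = fused_key,
       p_z = sum(zdims))
}

# sum-to-zero projection of the AR(1) precision: Zt' P(rho) Zt
temporal_M <- function(frame, rho) {
  P <- ar1_precision(length(frame$weeks), rho)
  Zt <- frame$zblocks$temporal
  M <- crossprod(Zt, as.matrix(P %*% Zt))
  (M + t(M)) / 2
}

# prior precision of the constrained parameter vector z, plus its logdet;
# temporal projection is memoised on rho within one fit
make_Q_builder <- function(frame, spec) {
  cache <- new.env(parent = emptyenv())
  cache$rho <- NA_real_
  function(hp) {
    p <- frame$p_z
    Q <- matrix(0, p, p)
    logdet <- 0
    M <- NULL
    idx <- frame$zindex
    Q[idx$intercept, idx$intercept] <- 1 / spec$intercept_prior_sd^2
    logdet <- logdet - 2 * log(spec$intercept_prior_sd)
    if (!is.null(idx$temporal) && length(idx$temporal) > 0) {
      if (!identical(cache$rho, hp$rho)) {
        cache$M <- temporal_M(frame, hp$rho)
        cache$rho <- hp$rho
        cache$logdetM <- 2 * sum(log(diag(chol(cache$M))))
      }
      M <- cache$M
      Q[idx$temporal, idx$temporal] <- hp$tau_temporal * M
      logdet <- logdet + length(idx$temporal) * log(hp$tau_temporal) +
        cache$logdetM
    }
    for (nm in setdiff(names(idx), c("intercept", "temporal"))) {
      ii <- idx[[nm]]
      if (length(ii) == 0) next
      tau <- hp[[paste0("tau_", nm)]]
      Q[cbind(ii, ii)] <- tau
      logdet <- logdet + length(ii) * log(tau)
    }
    list(Q = Q, logdet = logdet, M = M)
  }
}

# maximise loglik(eta(z)) - z'Qz/2 by damped Newton; Hessian assembled in
# the sparse indicator basis then projected through the constraint bases
inner_newton <- function(frame, Q, z0, control) {
  X <- frame$X; Z <- frame$Z; y <- frame$y; off <- frame$offset
  clip <- control$eta_clip
  eta_of <- function(z) {
    e <- off + as.numeric(X %*% (Z %*% z))
    pmin(e, clip)
  }
  Fval <- function(z, eta) sum(y * eta - exp(eta)) - 0.5 * sum(z * (Q %*% z))
  z <- z0
  eta <- eta_of(z)
  f <- Fval(z, eta)
  f_trace <- f
  iters <- 0L
  gnorm <- Inf
  clipped <- FALSE
  stalled <- FALSE
  repeat {
    mu <- exp(eta)
    g <- as.numeric(Matrix::crossprod(Z, Matrix::crossprod(X, y - mu))) -
      as.numeric(Q %*% z)
    gnorm <- max(abs(g))
    if (gnorm < control$inner_tol || iters >= control$inner_maxit) break
    Xw <- X
    Xw@x <- Xw@x * sqrt(mu)[Xw@i + 1L]
    Mx <- Matrix::crossprod(Xw)
    H <- as.matrix(Matrix::crossprod(Z, Mx %*% Z)) + Q
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) {
      H <- H + diag(1e-8 * max(diag(H)), nrow(H))
      ch <- chol(H)
    }
    step <- backsolve(ch, forwardsolve(t(ch), g))
    s <- 1
    for (h in 1:30) {
      z_new <- z + s * step
      eta_new <- eta_of(z_new)
      f_new <- Fval(z_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      s <- s / 2
    }
    if (max(abs(z_new - z)) < 1e-12) {
      z <- z_new; eta <- eta_new; f <- f_new; f_trace <- c(f_trace, f)
      stalled <- TRUE
      break
    }
    z <- z_new; eta <- eta_new; f <- f_new
    f_trace <- c(f_trace, f)
    iters <- iters + 1L
  }
  if (any((off + as.numeric(X %*% (Z %*% z))) > clip)) clipped <- TRUE
  mu <- exp(eta)
  Xw <- X
  Xw@x <- Xw@x * sqrt(mu)[Xw@i + 1L]
  H <- as.matrix(Matrix::crossprod(Z, Matrix::crossprod(Xw) %*% Z)) + Q
  ch <- chol(H)
  if (stalled) {
    mu0 <- exp(eta)
    gnorm <- max(abs(
      as.numeric(Matrix::crossprod(Z, Matrix::crossprod(X, y - mu0))) -
        as.numeric(Q %*% z)))
  }
  # a stalled step with a near-threshold gradient is converged for all
  # practical purposes (parameter error ~ grad / Hessian scale)
  conv <- gnorm < control$inner_tol ||
    (stalled && gnorm < 1e3 * control$inner_tol)
  list(z = z, f = f, f_trace = f_trace, eta = eta, mu = mu, chol_H = ch,
       logdet_H = 2 * sum(log(diag(ch))), iterations = iters,
       grad_norm = gnorm, converged = conv,
       clipped = clipped)
}

hyper_layout <- function(frame, spec) {
  free <- character(0)
  fixed <- list()
  fx <- spec$fixed_precisions
  want <- function(block, label = block) {
    if (!is.null(fx[[block]])) {
      fixed[[paste0("tau_", label)]] <<- fx[[block]]
    } else {
      free <<- c(free, paste0("log_tau_", label))
    }
  }
  if (!is.null(frame$zindex$temporal) && length(frame$zindex$temporal) > 0) {
    want("temporal")
    free <- c(free, "atanh_rho")
  }
  if (!is.null(frame$zindex$spatial) && length(frame$zindex$spatial) > 0) {
    want("spatial")
  }
  for (nm in names(frame$covariates)) want(nm)
  if (!is.null(frame$zindex$fused) && length(frame$zindex$fused) > 0) {
    want("fused")
  }
  list(free = free, fixed = fixed)
}

hyper_from_par <- function(par, layout) {
  hp <- list()
  for (nm in names(par)) {
    if (nm == "atanh_rho") {
      hp$rho <- tanh(par[[nm]])
    } else {
      hp[[sub("^log_", "", nm)]] <- exp(par[[nm]])
    }
  }
  for (nm in names(layout$fixed)) hp[[nm]] <- layout$fixed[[nm]]
  hp
}

default_hyper_init <- function(layout) {
  init <- numeric(length(layout$free))
  names(init) <- layout$free
  for (nm in layout$free) {
    init[nm] <- switch(nm,
      log_tau_temporal = 6, log_tau_spatial = 6, atanh_rho = atanh(0.5),
      log_tau_fused = 2, 8)  # exposure blocks: prior sd ~ exp(-4) = 0.018
  }
  init
}

#' Fit the hierarchical Poisson relative-risk model
#'
#' Two nested loops: the inner loop maximises the log posterior of the
#' latent effects at fixed hyperparameters by damped Newton iterations
#' (the latent field is log-concave, so this converges), yielding the
#' Laplace (Gaussian) approximation at the mode with covariance from the
#' inverse negative Hessian; the outer loop maximises the
#' Laplace-approximate marginal likelihood, plus wide log-normal
#' hyperpriors, over the block precisions and the AR(1) correlation by
#' bounded quasi-Newton (`L-BFGS-B`) on transformed scales (log precision,
#' atanh rho).  Sum-to-zero constraints are enforced by optimising in
#' orthonormal constraint bases.  Deterministic given its inputs.
#'
#' @param panel an `st_panel` with `_level` columns (see [apply_schemes()]).
#' @param spec a [model_spec()].
#' @param fused optional data.frame `country, week, interval` from
#'   [country_fused_intervals()].
#' @param theta a `baseline_rate` or number; default computed from `panel`.
#' @param verbose log progress.
#' @return An `rr_fit` with posterior means (`effects`) and SDs
#'   (`effect_sds`) per latent block, estimated `hyper`parameters
#'   (precisions and rho), `log_marginal`, `converged` flag and
#'   `diagnostics`.
#' @export
fit_rr_model <- function(panel, spec = model_spec(), fused = NULL,
                         theta = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  theta <- theta %||% compute_theta_tot(panel)
  if (inherits(theta, "baseline_rate")) theta <- theta$theta_tot
  frame <- build_frame(panel, spec, fused, theta)
  if (frame$n_missing > 0) {
    csx_log("dropping ", frame$n_missing,
            " row(s) with missing covariate levels", verbose = verbose)
  }
  control <- spec$control
  buildQ <- make_Q_builder(frame, spec)
  layout <- hyper_layout(frame, spec)
  lfact <- sum(lfactorial(frame$y))

  state <- new.env(parent = emptyenv())
  state$z <- numeric(frame$p_z)
  state$inner_total <- 0L
  state$key <- NULL

  # one Laplace evaluation per distinct hyperparameter point (memoised so
  # optim's separate fn/gr calls at the same point reuse the inner solve)
  evaluate <- function(par) {
    key <- paste(sprintf("%.17g", par), collapse = ",")
    if (identical(state$key, key)) return(state$res)
    hp <- hyper_from_par(as.list(par), layout)
    qq <- buildQ(hp)
    nw <- inner_newton(frame, qq$Q, state$z, control)
    state$z <- nw$z
    state$inner_total <- state$inner_total + nw$iterations
    logml <- nw$f - lfact + 0.5 * qq$logdet - 0.5 * nw$logdet_H
    lp <- 0
    for (nm in names(par)) {
      lp <- lp + if (nm == "atanh_rho") {
        dnorm(par[[nm]], 0, spec$rho_prior_sd, log = TRUE)
      } else {
        dnorm(par[[nm]], spec$hyper_prior_mean, spec$hyper_prior_sd, log = TRUE)
      }
    }
    state$key <- key
    state$res <- list(hp = hp, qq = qq, nw = nw, logml = logml,
                      obj = -(logml + lp))
    state$res
  }

  # empirical-Bayes gradient of the Laplace marginal likelihood, holding
  # the mode and the Poisson weights fixed (envelope approximation):
  # d logML / d theta_j = -z'(dQ)z/2 + tr(Q^-1 dQ)/2 - tr(H^-1 dQ)/2
  gradient <- function(par) {
    r <- evaluate(par)
    Sigma <- chol2inv(r$nw$chol_H)
    z <- r$nw$z
    idx <- frame$zindex
    g <- numeric(length(par))
    names(g) <- names(par)
    for (nm in names(par)) {
      if (nm == "atanh_rho") {
        rho <- r$hp$rho
        tau <- r$hp$tau_temporal
        ii <- idx$temporal
        h <- 1e-4
        dM <- (temporal_M(frame, rho + h) - temporal_M(frame, rho - h)) / (2 * h)
        Minv <- chol2inv(chol(r$qq$M))
        zt <- z[ii]
        g[nm] <- (1 - rho^2) *
          (-0.5 * tau * sum(zt * (dM %*% zt)) + 0.5 * sum(Minv * dM) -
             0.5 * tau * sum(Sigma[ii, ii] * dM)) -
          par[[nm]] / spec$rho_prior_sd^2
      } else {
        block <- sub("^log_tau_", "", nm)
        ii <- idx[[block]]
        tau <- r$hp[[paste0("tau_", block)]]
        zb <- z[ii]
        if (block == "temporal") {
          M <- r$qq$M
          g[nm] <- -0.5 * tau * sum(zb * (M %*% zb)) + 0.5 * length(ii) -
            0.5 * tau * sum(Sigma[ii, ii] * M)
        } else {
          g[nm] <- -0.5 * tau * sum(zb^2) + 0.5 * length(ii) -
            0.5 * tau * sum(diag(Sigma)[ii])
        }
        g[nm] <- g[nm] -
          (par[[nm]] - spec$hyper_prior_mean) / spec$hyper_prior_sd^2
      }
    }
    -g
  }

  par0 <- default_hyper_init(layout)
  if (length(par0) > 0) {
    lower <- ifelse(names(par0) == "atanh_rho", -4, -12)
    upper <- ifelse(names(par0) == "atanh_rho", 4, 16)
    opt <- optim(par0, fn = function(p) evaluate(p)$obj, gr = gradient,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = control$outer_maxit,
                                factr = control$outer_factr,
                                pgtol = control$outer_pgtol))
    par_hat <- opt$par
    outer_conv <- opt$convergence
    outer_counts <- opt$counts
    outer_message <- opt$message %||% ""
  } else {
    par_hat <- par0
    outer_conv <- 0L
    outer_counts <- c(`function` = 1L, gradient = 0L)
    outer_message <- "no free hyperparameters"
  }
  final <- evaluate(par_hat)
  nw <- final$nw
  hp <- hyper_from_par(as.list(par_hat), layout)
  qq <- buildQ(hp)

  Sigma <- chol2inv(nw$chol_H)
  idx <- frame$zindex
  effects <- list()
  effect_sds <- list()
  grab <- function(name) {
    ii <- idx[[name]]
    Zb <- frame$zblocks[[name]]
    if (length(ii) == 0) {
      return(list(mean = rep(0, nrow(Zb)), sd = rep(0, nrow(Zb))))
    }
    m <- as.numeric(Zb %*% nw$z[ii])
    V <- Zb %*% Sigma[ii, ii, drop = FALSE]
    list(mean = m, sd = sqrt(pmax(rowSums(V * Zb), 0)))
  }
  gi <- grab("intercept")
  effects$intercept <- gi$mean; effect_sds$intercept <- gi$sd
  if (!is.null(idx$temporal)) {
    gt <- grab("temporal")
    effects$temporal <- stats::setNames(gt$mean, frame$weeks)
    effect_sds$temporal <- stats::setNames(gt$sd, frame$weeks)
  }
  if (!is.null(idx$spatial)) {
    gs <- grab("spatial")
    effects$spatial <- stats::setNames(gs$mean, frame$regions)
    effect_sds$spatial <- stats::setNames(gs$sd, frame$regions)
  }
  effects$levels <- list(); effect_sds$levels <- list()
  schemes <- attr(panel, "schemes")
  for (nm in names(frame$covariates)) {
    gc_ <- grab(nm)
    labs <- if (!is.null(schemes[[nm]])) schemes[[nm]]$labels else
      paste0("L", seq_len(frame$covariates[[nm]]) - 1L)
    effects$levels[[nm]] <- stats::setNames(gc_$mean, labs)
    effect_sds$levels[[nm]] <- stats::setNames(gc_$sd, labs)
  }
  if (!is.null(frame$fused_levels)) {
    gf <- grab("fused")
    effects$fused <- list(); effect_sds$fused <- list()
    pos <- 0L
    for (fl in frame$fused_levels) {
      sel <- pos + seq_len(fl$m)
      effects$fused[[fl$country]] <-
        stats::setNames(gf$mean[sel], seq_len(fl$m) - 1L)
      effect_sds$fused[[fl$country]] <-
        stats::setNames(gf$sd[sel], seq_len(fl$m) - 1L)
      pos <- pos + fl$m
    }
  }

  converged <- nw$converged && outer_conv == 0L
  if (!converged) {
    warning("fit did not fully converge (outer code ", outer_conv,
            ", inner grad norm ", format(nw$grad_norm, digits = 3), ")",
            call. = FALSE)
  }
  if (nw$clipped) {
    warning("linear predictor clipped at ", control$eta_clip,
            " to avoid overflow", call. = FALSE)
  }

  structure(list(
    theta_tot = theta,
    effects = effects,
    effect_sds = effect_sds,
    hyper = hp,
    log_marginal = final$logml,
    converged = converged,
    diagnostics = list(outer_convergence = outer_conv,
                       outer_counts = outer_counts,
                       outer_message = outer_message,
                       inner_iterations_total = state$inner_total,
                       final_grad_norm = nw$grad_norm,
                       eta_clipped = nw$clipped),
    internal = list(spec = spec, frame = frame, z = nw$z, Sigma = Sigma,
                    Q = qq$Q, chol_H = nw$chol_H, lfact = lfact)),
    class = "rr_fit")
}

#' @export
print.rr_fit <- function(x, ...) {
  cat("Hierarchical Poisson relative-risk fit\n")
  cat(sprintf("  theta_tot = %.5g, log marginal = %.4f, converged: %s\n",
              x$theta_tot, x$log_marginal, x$converged))
  hp <- x$hyper
  if (!is.null(hp$rho)) {
    cat(sprintf("  AR(1): rho = %.3f, marginal sd = %.4g\n",
                hp$rho, 1 / sqrt(hp$tau_temporal)))
  }
  for (nm in names(x$effects$levels)) {
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s=%.4f", names(x$effects$levels[[nm]]),
                              x$effects$levels[[nm]]), collapse = " ")))
  }
  invisible(x)
}
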