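#' MCMC cross-check of the Laplace fit
#'
#' Samples the latent effects of the relative-risk model by
#' Metropolis-within-Gibbs (one multivariate random-walk update per latent
#' block per sweep, proposal covariance taken from the Laplace posterior
#' scaled by `2.4 / sqrt(d)`), with the hyperparameters held at their
#' empirical-Bayes estimates.  Intended as an independent check of the
#' Gaussian approximation on small panels; refuses panels above 5000 rows.
#'
#' @param panel an `st_panel` with level columns.
#' @param spec a [model_spec()].
#' @param draws number of post-burnin sweeps (>= 1).
#' @param seed integer seed; identical seeds give identical chains.
#' @param fused optional fused-interval table.
#' @param theta baseline rate; default computed from the panel.
#' @param burnin burn-in sweeps (default `draws`, i.e. half the chain).
#' @param verbose log progress.
#' @return List with posterior `effects` means and `effect_sds` from the
#'   chain (same block layout as an `rr_fit`), per-block `acceptance`
#'   rates, `draws`, and the `laplace` fit used for comparison.
#' @export
mcmc_check <- function(panel, spec = model_spec(), draws = 2000L,
                       seed = 1L, fused = NULL, theta = NULL,
                       burnin = NULL, verbose = FALSE) {
  if (nrow(panel) > 5000) {
    csx_stop("mcmc_check is a desk-scale verification tool; panel has ",
             nrow(panel), " rows (> 5000). Subset the panel first.",
             class = "climsent_guard_error")
  }
  draws <- as.integer(draws)
  if (is.na(draws) || draws < 1) csx_stop("draws must be >= 1")
  burnin <- as.integer(burnin %||% draws)
  set.seed(seed)

  fit <- fit_rr_model(panel, spec, fused = fused, theta = theta,
                      verbose = verbose)
  frame <- fit$internal$frame
  Q <- fit$internal$Q
  Sigma <- fit$internal$Sigma
  X <- frame$X; Z <- frame$Z; y <- frame$y; off <- frame$offset
  clip <- spec$control$eta_clip

  blocks <- Filter(function(ii) length(ii) > 0, frame$zindex)
  B <- lapply(blocks, function(ii) as.matrix(X %*% Z[, ii, drop = FALSE]))
  # block proposals from the Laplace full conditional
  # N(m_b(z_rest), H_bb^-1), Metropolis-Hastings corrected: near-Gibbs
  # mixing wherever the Gaussian approximation is accurate
  H <- crossprod(fit$internal$chol_H)
  zhat <- fit$internal$z
  prop <- lapply(names(blocks), function(nm) {
    ii <- blocks[[nm]]
    Hbb <- H[ii, ii, drop = FALSE]
    ch <- chol((Hbb + t(Hbb)) / 2)
    list(ii = ii, Hbb = Hbb, chol_Hbb = ch,
         # A with A A' = Hbb^-1: A = R^-1 for upper Cholesky R of Hbb
         L = backsolve(ch, diag(length(ii))),
         Hrow = H[ii, , drop = FALSE])
  })
  names(prop) <- names(blocks)

  z <- fit$internal$z
  eta <- pmin(off + as.numeric(X %*% (Z %*% z)), clip)
  ll <- sum(y * eta - exp(eta))
  qf <- function(nm, zb) {
    ii <- blocks[[nm]]
    0.5 * sum(zb * (Q[ii, ii, drop = FALSE] %*% zb))
  }
  acc <- stats::setNames(numeric(length(blocks) + 1),
                         c(names(blocks), "joint"))
  chol_H_full <- chol((H + t(H)) / 2)
  Lfull <- backsolve(chol_H_full, diag(nrow(H)))
  Qfull <- Q
  total <- burnin + draws
  keep <- matrix(NA_real_, draws, length(z))
  for (it in seq_len(total)) {
    # joint independence proposal from the Laplace posterior N(zhat, H^-1):
    # breaks the cross-block correlation that block updates mix slowly over
    z_new <- zhat + as.numeric(Lfull %*% rnorm(length(z)))
    eta_new <- pmin(off + as.numeric(X %*% (Z %*% z_new)), clip)
    ll_new <- sum(y * eta_new - exp(eta_new))
    lqj <- function(v) -0.5 * sum((v - zhat) * (H %*% (v - zhat)))
    dpost <- (ll_new - 0.5 * sum(z_new * (Qfull %*% z_new))) -
      (ll - 0.5 * sum(z * (Qfull %*% z))) + lqj(z) - lqj(z_new)
    if (is.finite(dpost) && log(runif(1)) < dpost) {
      z <- z_new
      eta <- eta_new
      ll <- ll_new
      if (it > burnin) acc["joint"] <- acc["joint"] + 1
    }
    for (nm in names(blocks)) {
      pr <- prop[[nm]]
      ii <- pr$ii
      zb <- z[ii]
      # Laplace full-conditional mean given the other blocks
      m <- zhat[ii] - as.numeric(
        backsolve(pr$chol_Hbb,
                  forwardsolve(t(pr$chol_Hbb),
                               as.numeric(pr$Hrow %*% (z - zhat)) -
                                 as.numeric(pr$Hbb %*% (zb - zhat[ii])))))
      zb_new <- m + as.numeric(pr$L %*% rnorm(length(ii)))
      eta_new <- pmin(eta + as.numeric(B[[nm]] %*% (zb_new - zb)), clip)
      ll_new <- sum(y * eta_new - exp(eta_new))
      lq <- function(v) -0.5 * sum((v - m) * (pr$Hbb %*% (v - m)))
      dpost <- (ll_new - qf(nm, zb_new)) - (ll - qf(nm, zb)) +
        lq(zb) - lq(zb_new)
      if (is.finite(dpost) && log(runif(1)) < dpost) {
        z[ii] <- zb_new
        eta <- eta_new
        ll <- ll_new
        if (it > burnin) acc[nm] <- acc[nm] + 1
      }
    }
    if (it > burnin) keep[it - burnin, ] <- z
  }
  acc <- acc / draws

  summarize_block <- function(name, stat) {
    ii <- frame$zindex[[name]]
    Zb <- frame$zblocks[[name]]
    if (length(ii) == 0) return(rep(0, nrow(Zb)))
    xs <- keep[, ii, drop = FALSE] %*% t(as.matrix(Zb))
    apply(xs, 2, stat)
  }
  effects <- list(intercept = summarize_block("intercept", mean))
  effect_sds <- list(intercept = summarize_block("intercept", sd))
  if (!is.null(frame$zindex$temporal)) {
    effects$temporal <- stats::setNames(summarize_block("temporal", mean),
                                        frame$weeks)
    effect_sds$temporal <- stats::setNames(summarize_block("temporal", sd),
                                           frame$weeks)
  }
  if (!is.null(frame$zindex$spatial)) {
    effects$spatial <- stats::setNames(summarize_block("spatial", mean),
                                       frame$regions)
    effect_sds$spatial <- stats::setNames(summarize_block("spatial", sd),
                                          frame$regions)
  }
  effects$levels <- list(); effect_sds$levels <- list()
  for (nm in names(frame$covariates)) {
    labs <- names(fit$effects$levels[[nm]])
    effects$levels[[nm]] <- stats::setNames(summarize_block(nm, mean), labs)
    effect_sds$levels[[nm]] <- stats::setNames(summarize_block(nm, sd), labs)
  }
  list(effects = effects, effect_sds = effect_sds, acceptance = acc,
       draws = draws, laplace = list(effects = fit$effects,
                                     effect_sds = fit$effect_sds),
       fit = fit)
}
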