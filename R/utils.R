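#' @importFrom stats rnorm rpois runif optim qnorm quantile sd var coef glm
#'   poisson dnorm acf na.omit lag
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
csx_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[climsent] ", ...)
  invisible(NULL)
}

csx_stop <- function(..., class = "climsent_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 0 & (abs(x - round(x)) < 1e-8)
}

# orthonormal basis of the sum-to-zero subspace of R^k (k x (k-1));
# columns are orthonormal and orthogonal to the ones vector
sum_zero_basis <- function(k) {
  if (k < 1) csx_stop("block size must be >= 1")
  if (k == 1) return(matrix(numeric(0), nrow = 1, ncol = 0))
  qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
}
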