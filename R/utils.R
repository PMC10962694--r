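## Small numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable softplus link
#'
#' Maps an unconstrained real to a strictly positive scale parameter,
#' `log(1 + exp(x))` plus a small floor that keeps gradients finite when the
#' pre-link value is very negative.
#'
#' @param x numeric vector of pre-link values.
#' @param floor additive lower bound on the linked value.
#' @return positive numeric vector.
#' @export
softplus <- function(x, floor = 1e-4) {
  # log1p(exp(x)) overflows for large x; switch to the asymptote there
  out <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  out + floor
}

#' Inverse of [softplus()] (ignoring the floor)
#' @param y positive numeric vector.
#' @param floor floor used in the forward link.
#' @return numeric vector x with softplus(x, floor) ~= y.
#' @export
softplus_inv <- function(y, floor = 1e-4) {
  y <- pmax(y - floor, 1e-12)
  ifelse(y > 30, y, log(expm1(y)))
}

## derivative of softplus wrt its pre-link argument (the floor is additive)
softplus_grad <- function(x) {
  1 / (1 + exp(-pmin(pmax(x, -30), 30)))
}

#' Log-mean-exp of a matrix across columns
#'
#' Combines per-member log densities into the log density of the equal-weight
#' predictive mixture, row-wise and without underflow.
#'
#' @param ll numeric matrix, rows = observations, columns = mixture members.
#' @return numeric vector of length `nrow(ll)`.
#' @export
log_mean_exp <- function(ll) {
  ll <- as.matrix(ll)
  m <- apply(ll, 1L, max)
  m + log(rowMeans(exp(ll - m)))
}

## sd that never returns 0/NA so standardization is always invertible
safe_sd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) 1 else s
}

stop_missing_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

## deterministic child seeds derived from a user seed, kept inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}
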