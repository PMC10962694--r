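## Convolutional read-out, response-distribution likelihood, and prediction.

#' Convolve impulses with their response weights
#'
#' Computes `s = s0 + sum_n G_n diag(b) [1; x'_n]`: each event's impulse
#' vector, with the rate bias 1 prepended, is scaled by the coefficient vector
#' and mapped through that event's convolution weight matrix; contributions
#' across events are strictly additive.
#'
#' @param s0 S-dimensional intercept of the response-distribution parameters.
#' @param b coefficient vector of length J+1 (index 1 is the rate slot).
#' @param G list of N matrices, each S x (J+1).
#' @param Xp N x J impulse matrix (may have zero rows).
#' @return numeric vector s of length S.
#' @export
cdrnn_convolve <- function(s0, b, G, Xp) {
  Xp <- as.matrix(Xp)
  N <- length(G)
  if (N > 0 && nrow(Xp) != N) stop("Xp must have one row per weight matrix")
  J <- ncol(Xp)
  if (length(b) != J + 1L) {
    stop(sprintf("b must have length J+1 = %d, got %d", J + 1L, length(b)))
  }
  s <- s0
  for (n in seq_len(N)) {
    Gn <- G[[n]]
    if (!all(dim(Gn) == c(length(s0), J + 1L))) {
      stop(sprintf("G[[%d]] must be %d x %d", n, length(s0), J + 1L))
    }
    s <- s + Gn %*% (b * c(1, Xp[n, ]))
  }
  drop(s)
}

#' Log density of responses under the response distribution
#'
#' @param y numeric response vector.
#' @param mu location parameter (vectorized).
#' @param sigma scale parameter, already linked (strictly positive).
#' @param family response family; only `"normal"` is implemented (other
#'   families are a deliberate extension point).
#' @return numeric vector of pointwise log densities; the dataset log
#'   likelihood is their sum.
#' @export
cdrnn_loglik <- function(y, mu, sigma, family = "normal") {
  if (!identical(family, "normal")) {
    stop("only the normal response family is implemented")
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("scale parameter must be strictly positive after the link")
  }
  stats::dnorm(y, mu, sigma, log = TRUE)
}

#' Predict response-distribution parameters and log likelihoods
#'
#' Runs the full deconvolutional pipeline for each response sample: delays,
#' impulses, convolution weights, convolution, link, and pointwise log
#' density. Deterministic given the fitted model and inputs (dropout off);
#' pass `draws > 0` for Monte Carlo dropout draws instead. Unknown
#' random-effects levels fall back to the population prediction (z = 0) with
#' a warning.
#'
#' @param object a fitted model from [fit_cdrnn()].
#' @param events event table.
#' @param responses response table (must carry the response column for log
#'   likelihoods; otherwise only `mu`/`sigma` are returned).
#' @param draws number of Monte Carlo dropout draws (0 = deterministic
#'   expected-mask prediction).
#' @param seed seed for the dropout draws.
#' @param ... unused.
#' @return data.frame with the series id, timestamp, observed response (if
#'   present), linked parameters `mu` and `sigma` on the raw response scale,
#'   and pointwise `loglik`. With `draws > 0`, columns `mu`/`sigma`/`loglik`
#'   average the draws and a `"draws"` attribute holds the per-draw log
#'   likelihood matrix.
#' @export
predict.cdrnn_fit <- function(object, events, responses, draws = 0L,
                              seed = 1L, ...) {
  spec <- object$spec
  design <- .build_design(events, responses, spec, stats = object$stats,
                          levels = object$levels)
  y <- responses[[spec$response]]
  st <- object$stats
  as_raw <- function(fp) {
    sigma_s <- softplus(fp$eta)
    list(mu = fp$mu * st$y_sd + st$y_mean, sigma = sigma_s * st$y_sd)
  }
  if (draws <= 0 || object$control$dropout == 0) {
    fp <- .forward_params(spec, object$params, design)
    pr <- as_raw(fp)
    ll <- if (!is.null(y)) cdrnn_loglik(y, pr$mu, pr$sigma) else NULL
    out <- data.frame(series = responses[[spec$series_col]],
                      time = responses[[spec$time_col]])
    if (!is.null(y)) out$y <- y
    out$mu <- pr$mu
    out$sigma <- pr$sigma
    if (!is.null(ll)) out$loglik <- ll
    return(out)
  }
  ps <- posterior_sample(object, n_samples = draws, seed = seed)
  mu_acc <- 0; sg_acc <- 0
  llm <- if (!is.null(y)) matrix(NA_real_, length(y), draws) else NULL
  for (i in seq_len(draws)) {
    fp <- .forward_params(spec, object$params, design,
                          control_dropout = object$control$dropout,
                          masks = ps[[i]]$masks)
    pr <- as_raw(fp)
    mu_acc <- mu_acc + pr$mu
    sg_acc <- sg_acc + pr$sigma
    if (!is.null(llm)) llm[, i] <- cdrnn_loglik(y, pr$mu, pr$sigma)
  }
  out <- data.frame(series = responses[[spec$series_col]],
                    time = responses[[spec$time_col]])
  if (!is.null(y)) out$y <- y
  out$mu <- mu_acc / draws
  out$sigma <- sg_acc / draws
  if (!is.null(llm)) {
    out$loglik <- log_mean_exp(llm)
    attr(out, "draws") <- llm
  }
  out
}

#' Per-sample conditional log likelihoods of a model on a dataset
#'
#' Convenience accessor used by the model-comparison machinery; works for
#' single fits and ensembles (whose members' predictive densities are
#' mixed by [log_mean_exp()]).
#'
#' @param model a `cdrnn_fit` or `cdrnn_ensemble`.
#' @param events,responses data tables.
#' @return numeric vector of pointwise log likelihoods, named by
#'   `series:time`.
#' @export
loglik_vector <- function(model, events, responses) {
  pr <- predict(model, events, responses)
  stats::setNames(pr$loglik, paste(pr$series, format(pr$time, digits = 12),
                                   sep = ":"))
}
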