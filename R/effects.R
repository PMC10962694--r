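## Perturbation-based interpretation. Every query constructs a single
## synthetic event, evaluates the response-distribution parameters with the
## event's predictors at the queried value and at the reference point, and
## reports the (raw-scale) difference of the targeted parameter — by
## additivity of the convolution, unrelated context events cancel exactly in
## this difference, so queries need only the single event. Uncertainty comes
## from Monte Carlo dropout draws, pooled over ensemble members when present.

.model_members <- function(model) {
  if (inherits(model, "cdrnn_ensemble")) model$members else list(model)
}

.model_spec <- function(model) .model_members(model)[[1L]]$spec

## query matrix evaluation for one fit and one dropout draw:
## rows of (d, t, Xq) against rows of (d, t, Xr); returns the change in the
## target parameter on the raw response scale, one value per row.
.query_change_one <- function(fit, d, t_onset, Xq, Xr, target, masks = NULL,
                              rate = FALSE) {
  spec <- fit$spec
  st <- fit$stats
  S_net <- .spec_S_net(spec)
  J <- .spec_J(spec)
  npt <- length(d)
  std_x <- function(X) sweep(sweep(X, 2L, st$x_mean, `-`), 2L, st$x_sd, `/`)
  Xq_s <- std_x(Xq)
  Xr_s <- std_x(Xr)
  ds <- (d - st$d_mean) / st$d_sd
  ts <- (t_onset - st$t_mean) / st$t_sd
  keep <- match(setdiff(spec$predictors, spec$linear_predictors),
                spec$predictors)
  build_in <- function(Xs) cbind(ds, if (spec$nonstationary) ts,
                                 Xs[, keep, drop = FALSE])
  contrib <- function(Xs) {
    if (spec$irf == "dirac") {
      Out <- .dirac_out(npt, S_net, J)
      Out[d != 0, ] <- 0
    } else {
      Out <- ffn_forward(.spec_ffn(spec), fit$params$ffn, build_in(Xs),
                         dropout = if (is.null(masks)) 0 else
                           fit$control$dropout,
                         masks = masks)
    }
    if (spec$causal) Out[d < 0, ] <- 0
    U <- cbind(1, Xs)
    Wp <- sweep(U, 2L, fit$params$bvec, `*`)
    sapply(seq_len(S_net), function(s) {
      rowSums(Out[, s + S_net * (0:J), drop = FALSE] * Wp)
    })
  }
  cq <- matrix(contrib(Xq_s), npt, S_net)
  cr <- if (rate) matrix(0, npt, S_net) else matrix(contrib(Xr_s), npt, S_net)
  if (target == "mu") {
    (cq[, 1L] - cr[, 1L]) * st$y_sd
  } else {
    eta0 <- fit$params$s0[2L]
    if (!spec$heteroscedastic) return(numeric(npt)) # exactly flat
    (softplus(eta0 + cq[, 2L]) - softplus(eta0 + cr[, 2L])) * st$y_sd
  }
}

## draws x points matrix over ensemble members and dropout draws
.query_draws <- function(model, d, t_onset, Xq, Xr, target, n_mc, seed,
                         rate = FALSE) {
  members <- .model_members(model)
  rows <- list()
  for (m in seq_along(members)) {
    fit <- members[[m]]
    if (fit$control$dropout > 0 && fit$spec$irf == "nn" && n_mc > 1) {
      ps <- posterior_sample(fit, n_mc, seed = derive_seed(seed, m))
      for (i in seq_len(n_mc)) {
        rows[[length(rows) + 1L]] <-
          .query_change_one(fit, d, t_onset, Xq, Xr, target,
                            masks = ps[[i]]$masks, rate = rate)
      }
    } else {
      rows[[length(rows) + 1L]] <-
        .query_change_one(fit, d, t_onset, Xq, Xr, target, rate = rate)
    }
  }
  do.call(rbind, rows)
}

#' Pointwise credible band from draw-wise estimates
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` over
#' posterior draws (and ensemble members, which are stacked as extra rows).
#'
#' @param draws numeric matrix, rows = draws, columns = grid points (a vector
#'   is treated as draws of a single point).
#' @param level credible level in (0, 1).
#' @return list with vectors `lo` and `hi`.
#' @export
credible_band <- function(draws, level = 0.95) {
  stopifnot(level > 0, level < 1)
  draws <- if (is.null(dim(draws))) matrix(draws, ncol = 1L) else draws
  a <- (1 - level) / 2
  lo <- apply(draws, 2L, stats::quantile, probs = a, names = FALSE)
  hi <- apply(draws, 2L, stats::quantile, probs = 1 - a, names = FALSE)
  list(lo = lo, hi = hi)
}

.resolve_value <- function(model, predictor, value) {
  st <- .model_members(model)[[1L]]$stats
  k <- match(predictor, .model_spec(model)$predictors)
  if (identical(value, "+1sd")) st$x_mean[k] + st$x_sd[k] else value
}

.ref_row <- function(model) {
  st <- .model_members(model)[[1L]]$stats
  matrix(st$x_mean, 1L)  # training-set mean = 0 after standardization
}

.default_onset <- function(model) .model_members(model)[[1L]]$stats$t_mean

.effect_result <- function(coords, draws, level) {
  bands <- credible_band(draws, level)
  out <- cbind(coords,
               data.frame(est = colMeans(draws), lo = bands$lo,
                          hi = bands$hi))
  class(out) <- c("cdrnn_effect", class(out))
  out
}

#' Impulse response curve of a predictor
#'
#' The estimated change in a response-distribution parameter caused by a
#' single event whose queried predictor is perturbed from the reference point
#' (the training-set mean) to `value` (default one training standard
#' deviation above the mean), as a function of delay. `predictor = "rate"`
#' gives the baseline response to an event with all predictors at reference
#' (the deconvolutional intercept).
#'
#' @param model a `cdrnn_fit` or `cdrnn_ensemble`.
#' @param predictor predictor name, or `"rate"`.
#' @param delays numeric delay grid in seconds.
#' @param value queried raw predictor value, or `"+1sd"`.
#' @param onset event onset time (defaults to the training mean time).
#' @param target `"mu"` (location) or `"sigma"` (scale).
#' @param n_mc number of Monte Carlo dropout draws per ensemble member.
#' @param level credible level.
#' @param seed seed for the dropout draws.
#' @return data.frame of class `cdrnn_effect` with columns `delay`, `est`,
#'   `lo`, `hi`.
#' @export
irf_curve <- function(model, predictor, delays = seq(0, 1, length.out = 201),
                      value = "+1sd", onset = NULL, target = "mu",
                      n_mc = 100L, level = 0.95, seed = 1L) {
  spec <- .model_spec(model)
  rate <- identical(predictor, "rate")
  if (!rate && !(predictor %in% spec$predictors)) {
    stop(sprintf("unknown predictor '%s'", predictor))
  }
  onset <- onset %||% .default_onset(model)
  npt <- length(delays)
  Xr <- .ref_row(model)[rep(1L, npt), , drop = FALSE]
  Xq <- Xr
  if (!rate) {
    Xq[, match(predictor, spec$predictors)] <-
      .resolve_value(model, predictor, value)
  }
  draws <- .query_draws(model, delays, rep(onset, npt), Xq, Xr, target,
                        n_mc, seed, rate = rate)
  .effect_result(data.frame(delay = delays), draws, level)
}

#' Effect surface over predictor value and delay
#'
#' @inheritParams irf_curve
#' @param values raw predictor-value grid (defaults to +/- 2.5 training
#'   standard deviations, 21 points).
#' @return data.frame of class `cdrnn_effect` with columns `value`, `delay`,
#'   `est`, `lo`, `hi`.
#' @export
effect_surface <- function(model, predictor,
                           values = NULL,
                           delays = seq(0, 1, length.out = 21),
                           onset = NULL, target = "mu", n_mc = 100L,
                           level = 0.95, seed = 1L) {
  spec <- .model_spec(model)
  if (!(predictor %in% spec$predictors)) {
    stop(sprintf("unknown predictor '%s'", predictor))
  }
  st <- .model_members(model)[[1L]]$stats
  k <- match(predictor, spec$predictors)
  values <- values %||%
    seq(st$x_mean[k] - 2.5 * st$x_sd[k], st$x_mean[k] + 2.5 * st$x_sd[k],
        length.out = 21)
  onset <- onset %||% .default_onset(model)
  grid <- expand.grid(value = values, delay = delays,
                      KEEP.OUT.ATTRS = FALSE)
  npt <- nrow(grid)
  Xr <- .ref_row(model)[rep(1L, npt), , drop = FALSE]
  Xq <- Xr
  Xq[, k] <- grid$value
  draws <- .query_draws(model, grid$delay, rep(onset, npt), Xq, Xr, target,
                        n_mc, seed)
  .effect_result(grid, draws, level)
}

#' Functional form of an effect at a fixed delay
#'
#' A slice of [effect_surface()] along the predictor dimension.
#'
#' @inheritParams effect_surface
#' @param delay fixed delay in seconds.
#' @return data.frame of class `cdrnn_effect` with columns `value`, `est`,
#'   `lo`, `hi`.
#' @export
functional_form_slice <- function(model, predictor, values = NULL, delay = 5,
                                  onset = NULL, target = "mu", n_mc = 100L,
                                  level = 0.95, seed = 1L) {
  out <- effect_surface(model, predictor, values = values, delays = delay,
                        onset = onset, target = target, n_mc = n_mc,
                        level = level, seed = seed)
  out$delay <- NULL
  out
}

#' Pairwise effect interaction surface at a fixed delay
#'
#' The joint change from perturbing two predictors together over their grid,
#' all other predictors held at the reference point. The additive part can be
#' removed downstream by subtracting the two marginal slices; a nonzero
#' residual indicates an interaction.
#'
#' @inheritParams effect_surface
#' @param predictor_a,predictor_b the two predictors.
#' @param values_a,values_b raw value grids (default +/- 2.5 training SDs, 11
#'   points each).
#' @param delay fixed delay in seconds.
#' @return data.frame of class `cdrnn_effect` with columns `value_a`,
#'   `value_b`, `est`, `lo`, `hi`.
#' @export
interaction_surface <- function(model, predictor_a, predictor_b,
                                values_a = NULL, values_b = NULL, delay = 5,
                                onset = NULL, target = "mu", n_mc = 100L,
                                level = 0.95, seed = 1L) {
  spec <- .model_spec(model)
  for (p in c(predictor_a, predictor_b)) {
    if (!(p %in% spec$predictors)) stop(sprintf("unknown predictor '%s'", p))
  }
  st <- .model_members(model)[[1L]]$stats
  ka <- match(predictor_a, spec$predictors)
  kb <- match(predictor_b, spec$predictors)
  gr <- function(k, v) v %||% seq(st$x_mean[k] - 2.5 * st$x_sd[k],
                                  st$x_mean[k] + 2.5 * st$x_sd[k],
                                  length.out = 11)
  grid <- expand.grid(value_a = gr(ka, values_a), value_b = gr(kb, values_b),
                      KEEP.OUT.ATTRS = FALSE)
  npt <- nrow(grid)
  onset <- onset %||% .default_onset(model)
  Xr <- .ref_row(model)[rep(1L, npt), , drop = FALSE]
  Xq <- Xr
  Xq[, ka] <- grid$value_a
  Xq[, kb] <- grid$value_b
  draws <- .query_draws(model, rep(delay, npt), rep(onset, npt), Xq, Xr,
                        target, n_mc, seed)
  .effect_result(grid, draws, level)
}

#' Impulse response of the scale parameter
#'
#' [irf_curve()] with `target = "sigma"`: the change in the predictive
#' standard deviation caused by a single event, as a function of delay.
#' Identically zero for homoscedasticity-constrained models.
#'
#' @inheritParams irf_curve
#' @return data.frame of class `cdrnn_effect`.
#' @export
sigma_irf <- function(model, predictor, delays = seq(0, 1, length.out = 201),
                      value = "+1sd", onset = NULL, n_mc = 100L,
                      level = 0.95, seed = 1L) {
  irf_curve(model, predictor, delays = delays, value = value, onset = onset,
            target = "sigma", n_mc = n_mc, level = level, seed = seed)
}

#' Nonstationarity curve: effect size as a function of event onset
#'
#' The effect of a predictor at a fixed delay, evaluated at a grid of onset
#' timestamps. Flat (exactly) for stationarity-constrained models.
#'
#' @inheritParams irf_curve
#' @param delay fixed delay in seconds.
#' @param onsets grid of onset timestamps (defaults to 21 points spanning the
#'   training time range).
#' @return data.frame of class `cdrnn_effect` with columns `onset`, `est`,
#'   `lo`, `hi`.
#' @export
nonstationarity_curve <- function(model, predictor, delay = 5, onsets = NULL,
                                  value = "+1sd", target = "mu", n_mc = 100L,
                                  level = 0.95, seed = 1L) {
  spec <- .model_spec(model)
  if (!(predictor %in% spec$predictors)) {
    stop(sprintf("unknown predictor '%s'", predictor))
  }
  st <- .model_members(model)[[1L]]$stats
  onsets <- onsets %||% seq(st$t_min, st$t_max, length.out = 21)
  npt <- length(onsets)
  Xr <- .ref_row(model)[rep(1L, npt), , drop = FALSE]
  Xq <- Xr
  Xq[, match(predictor, spec$predictors)] <-
    .resolve_value(model, predictor, value)
  draws <- .query_draws(model, rep(delay, npt), onsets, Xq, Xr, target,
                        n_mc, seed)
  .effect_result(data.frame(onset = onsets), draws, level)
}

#' Plot an effect query result
#'
#' Line plots (with credible ribbon) for one-dimensional queries and tile
#' plots for surfaces. Requires ggplot2.
#'
#' @param result a `cdrnn_effect`.
#' @return a ggplot object.
#' @export
plot_effect <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  cols <- setdiff(names(result), c("est", "lo", "hi"))
  if (length(cols) == 1L) {
    ggplot2::ggplot(result, ggplot2::aes(.data[[cols[1L]]], .data$est)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           alpha = 0.25) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "estimated change")
  } else {
    ggplot2::ggplot(result, ggplot2::aes(.data[[cols[1L]]], .data[[cols[2L]]],
                                         fill = .data$est)) +
      ggplot2::geom_tile() +
      ggplot2::labs(fill = "change")
  }
}
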