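## Model specification and the shared design machinery: pairing responses
## with their in-horizon event histories, standardization, and the population
## forward pass used by fitting, prediction and effect queries.

#' Specify a continuous-time deconvolutional regression network
#'
#' The model maps each response sample's event history through a feedforward
#' impulse response network: for event n at delay `d_n = tau - t_n`, the
#' network input is the admitted subset of `(d_n, t_n, x'_n)` and the output
#' is an S x (J+1) convolution weight matrix `G_n`. Response-distribution
#' parameters are `s = s0 + sum_n G_n diag(b) [1; x'_n]`, with the leading
#' coefficient slot (`rate`) capturing the baseline response to any event.
#' Input processing `f_in` is identity, so impulses equal predictors (J = K).
#'
#' Constraint flags carve out interpretable special cases: dropping `t` from
#' the network inputs enforces stationarity, dropping a predictor enforces a
#' linear effect for it (it still enters the convolution product), restricting
#' the network to the location row enforces homoscedasticity, and the
#' `"dirac"` impulse response (an indicator on zero delay) reduces the model
#' to discrete-time regression.
#'
#' @param predictors character vector of predictor column names (K >= 1).
#' @param response response column name.
#' @param series_col,time_col series-identifier and timestamp columns shared
#'   by event and response tables.
#' @param groups character vector of random-effects grouping columns on the
#'   response table (e.g. participant), or NULL for a fixed-effects model.
#' @param ranef_blocks parameter blocks receiving per-level random deviations:
#'   any of `"s0"` (location intercept) and `"b"` (convolution coefficients).
#' @param heteroscedastic if TRUE the network parameterizes the scale of the
#'   response distribution as well as its location; if FALSE sigma is a single
#'   free constant.
#' @param nonstationary include the event timestamp among the network inputs.
#' @param linear_predictors predictors excluded from the network inputs (their
#'   effects stay linear); `"all"` excludes every predictor.
#' @param causal zero the impulse response at negative delays (d = 0 counts as
#'   past-and-present and is retained).
#' @param d_max history horizon in seconds: events with delay in `[0, d_max]`
#'   (or `[-d_max, d_max]` when `causal = FALSE`) enter the convolution.
#'   Truncation error is negligible provided fitted kernels carry little mass
#'   beyond `d_max`; see [kernel_mass_beyond()].
#' @param irf `"nn"` (feedforward impulse response) or `"dirac"` (fixed
#'   indicator on zero delay, the discrete-time reduction).
#' @param hidden hidden-layer widths of the impulse response network.
#' @param activation hidden activation function.
#' @param family response family; `"normal"` is implemented, other families
#'   are reserved for extension.
#' @return object of class `cdrnn_model_spec`.
#' @export
cdrnn_spec <- function(predictors, response = "y",
                       series_col = "series", time_col = "time",
                       groups = NULL, ranef_blocks = c("s0", "b"),
                       heteroscedastic = TRUE, nonstationary = TRUE,
                       linear_predictors = character(0),
                       causal = TRUE, d_max = 10,
                       irf = c("nn", "dirac"),
                       hidden = c(32L, 32L), activation = "tanh",
                       family = "normal") {
  irf <- match.arg(irf)
  stopifnot(length(predictors) >= 1, d_max > 0)
  if (!identical(family, "normal")) {
    stop("only the normal response family is implemented")
  }
  if (identical(linear_predictors, "all")) linear_predictors <- predictors
  if (length(setdiff(linear_predictors, predictors))) {
    stop(sprintf("linear constraint names unknown predictor(s): %s",
                 paste(setdiff(linear_predictors, predictors), collapse = ", ")))
  }
  ranef_blocks <- intersect(ranef_blocks, c("s0", "b"))
  structure(list(predictors = predictors, response = response,
                 series_col = series_col, time_col = time_col,
                 groups = groups, ranef_blocks = ranef_blocks,
                 heteroscedastic = isTRUE(heteroscedastic),
                 nonstationary = isTRUE(nonstationary),
                 linear_predictors = linear_predictors,
                 causal = isTRUE(causal), d_max = d_max, irf = irf,
                 hidden = as.integer(hidden), activation = activation,
                 family = family),
            class = "cdrnn_model_spec")
}

## number of response-distribution parameter rows produced by the network
.spec_S_net <- function(spec) if (spec$heteroscedastic) 2L else 1L

## impulse dimension (f_in identity)
.spec_J <- function(spec) length(spec$predictors)

## columns of the IRF network input, in order: d, (t), admitted impulses
.spec_input_dim <- function(spec) {
  1L + as.integer(spec$nonstationary) +
    length(setdiff(spec$predictors, spec$linear_predictors))
}

.spec_ffn <- function(spec) {
  ffn_spec(.spec_input_dim(spec), spec$hidden,
           .spec_S_net(spec) * (.spec_J(spec) + 1L), spec$activation)
}

#' Map predictors to impulses
#'
#' Input processing. In identity mode (the default model) the impulses are
#' the predictors unchanged. In feedforward mode an [ffn_spec()] network is
#' applied independently to each row of `[t_n; x_n]`.
#'
#' @param events event table (or a numeric predictor matrix).
#' @param spec a `cdrnn_model_spec` (identity mode) or NULL.
#' @param f_in_spec,f_in_params optional feedforward network and parameters
#'   for feedforward mode.
#' @param time_col timestamp column used in feedforward mode.
#' @return numeric impulse matrix, N x J.
#' @export
input_transform <- function(events, spec = NULL, f_in_spec = NULL,
                            f_in_params = NULL, time_col = "time") {
  if (is.null(f_in_spec)) {
    if (!is.null(spec)) {
      stop_missing_cols(events, spec$predictors, "event table")
      return(as.matrix(events[spec$predictors]))
    }
    return(as.matrix(events))
  }
  stop_missing_cols(events, time_col, "event table")
  pred_cols <- setdiff(names(events)[vapply(events, is.numeric, TRUE)],
                       time_col)
  X <- cbind(events[[time_col]], as.matrix(events[pred_cols]))
  ffn_apply(f_in_spec, f_in_params, X)
}

## Standardization statistics from training data. d statistics come from the
## realized training delays so the network sees O(1) inputs.
.compute_stats <- function(events, responses, spec, d_raw) {
  X <- as.matrix(events[spec$predictors])
  y <- responses[[spec$response]]
  t_all <- events[[spec$time_col]]
  list(x_mean = colMeans(X),
       x_sd = apply(X, 2L, safe_sd),
       t_mean = mean(t_all), t_sd = safe_sd(t_all),
       t_min = min(t_all), t_max = max(t_all),
       d_mean = if (length(d_raw)) mean(d_raw) else 0,
       d_sd = if (length(d_raw)) safe_sd(d_raw) else 1,
       y_mean = mean(y), y_sd = safe_sd(y))
}

## Pair every response sample with the events of its series inside the
## history horizon. Returns parallel vectors over pairs plus bookkeeping.
.build_pairs <- function(events, responses, spec) {
  stop_missing_cols(events, c(spec$series_col, spec$time_col, spec$predictors),
                    "event table")
  stop_missing_cols(responses, c(spec$series_col, spec$time_col),
                    "response table")
  eps <- 1e-9
  p_resp <- integer(0); p_event <- integer(0)
  ev_series <- as.character(events[[spec$series_col]])
  rs_series <- as.character(responses[[spec$series_col]])
  for (s in unique(rs_series)) {
    ei <- which(ev_series == s)
    ri <- which(rs_series == s)
    if (!length(ei)) next
    ord <- order(events[[spec$time_col]][ei])  # stable for tied timestamps
    ei <- ei[ord]
    et <- events[[spec$time_col]][ei]
    tau <- responses[[spec$time_col]][ri]
    if (spec$irf == "dirac") {
      lo <- findInterval(tau - eps, et) + 1L
      hi <- findInterval(tau + eps, et)
    } else if (spec$causal) {
      lo <- findInterval(tau - spec$d_max - eps, et) + 1L
      hi <- findInterval(tau + eps, et)
    } else {
      lo <- findInterval(tau - spec$d_max - eps, et) + 1L
      hi <- findInterval(tau + spec$d_max + eps, et)
    }
    npair <- pmax(hi - lo + 1L, 0L)
    if (!any(npair > 0)) next
    p_resp <- c(p_resp, ri[rep(seq_along(ri), npair)])
    p_event <- c(p_event, ei[sequence(npair) + rep(lo - 1L, npair)])
  }
  d_raw <- responses[[spec$time_col]][p_resp] - events[[spec$time_col]][p_event]
  list(p_resp = p_resp, p_event = p_event, d_raw = d_raw)
}

## Full design: standardized network inputs, convolution factors and
## random-effects level indices. `stats` defaults to statistics of the data
## supplied (training); pass a fitted model's stats for prediction.
.build_design <- function(events, responses, spec, stats = NULL,
                          levels = NULL, warn_unknown = TRUE) {
  pr <- .build_pairs(events, responses, spec)
  if (is.null(stats)) stats <- .compute_stats(events, responses, spec, pr$d_raw)
  K <- .spec_J(spec)
  Xs <- sweep(sweep(as.matrix(events[spec$predictors]), 2L, stats$x_mean, `-`),
              2L, stats$x_sd, `/`)
  Xp <- Xs[pr$p_event, , drop = FALSE]
  ds <- (pr$d_raw - stats$d_mean) / stats$d_sd
  ts <- (events[[spec$time_col]][pr$p_event] - stats$t_mean) / stats$t_sd
  keep <- setdiff(spec$predictors, spec$linear_predictors)
  Xin <- cbind(ds, if (spec$nonstationary) ts,
               Xp[, match(keep, spec$predictors), drop = FALSE])
  U <- cbind(1, Xp)  # rate bias prepended at index 1

  n_resp <- nrow(responses)
  # group pairs by response for minibatching
  fac <- factor(pr$p_resp, levels = seq_len(n_resp))
  pairs_by_resp <- split(seq_along(pr$p_resp), fac)

  lev_idx <- list()
  lev_names <- list()
  for (g in spec$groups %||% character(0)) {
    stop_missing_cols(responses, g, "response table")
    vals <- as.character(responses[[g]])
    if (is.null(levels)) {
      lv <- sort(unique(vals))
    } else {
      lv <- levels[[g]]
      unknown <- setdiff(unique(vals), lv)
      if (length(unknown) && warn_unknown) {
        warning(sprintf(
          "unknown level(s) of '%s' (%s): falling back to population-level prediction",
          g, paste(unknown, collapse = ", ")))
      }
    }
    idx <- match(vals, lv)
    idx[is.na(idx)] <- 0L  # 0 = population (z = 0)
    lev_idx[[g]] <- idx
    lev_names[[g]] <- lv
  }

  y <- responses[[spec$response]]
  ys <- if (!is.null(y)) (y - stats$y_mean) / stats$y_sd else NULL

  list(Xin = Xin, U = U, d_raw = pr$d_raw, p_resp = pr$p_resp,
       p_event = pr$p_event, pairs_by_resp = pairs_by_resp,
       n_resp = n_resp, ys = ys, stats = stats,
       lev_idx = lev_idx, lev_names = lev_names)
}

## Dirac-mode "network output": an all-ones weight block for every matched
## (zero-delay) pair.
.dirac_out <- function(np, S_net, J) matrix(1, np, S_net * (J + 1L))

## Population (z = 0) forward evaluation over a design, optionally under a
## fixed dropout draw (list of per-layer mask vectors). Returns the
## standardized-scale location vector and pre-link scale vector per response.
.forward_params <- function(spec, params, design, control_dropout = 0,
                            masks = NULL, use_ranef = TRUE) {
  S_net <- .spec_S_net(spec)
  J <- .spec_J(spec)
  np <- nrow(design$Xin)
  n <- design$n_resp
  if (np > 0) {
    Out <- if (spec$irf == "dirac") .dirac_out(np, S_net, J)
           else ffn_forward(.spec_ffn(spec), params$ffn, design$Xin,
                            dropout = control_dropout, masks = masks)
    if (spec$causal && any(design$d_raw < 0)) Out[design$d_raw < 0, ] <- 0
    bmat <- matrix(params$bvec, n, J + 1L, byrow = TRUE)
    if (use_ranef && "b" %in% spec$ranef_blocks) {
      for (g in names(design$lev_idx)) {
        idx <- design$lev_idx[[g]]
        ok <- idx > 0L
        if (!is.null(params$ranef[[g]]$b) && any(ok)) {
          bmat[ok, ] <- bmat[ok, ] + params$ranef[[g]]$b[idx[ok], , drop = FALSE]
        }
      }
    }
    Wp <- design$U * bmat[design$p_resp, , drop = FALSE]
    agg <- matrix(0, n, S_net)
    for (s in seq_len(S_net)) {
      Cs <- rowSums(Out[, s + S_net * (0:J), drop = FALSE] * Wp)
      rs <- rowsum(Cs, design$p_resp)
      agg[as.integer(rownames(rs)), s] <- rs[, 1L]
    }
  } else {
    agg <- matrix(0, n, S_net)
  }
  mu <- params$s0[1L] + agg[, 1L]
  if (use_ranef && "s0" %in% spec$ranef_blocks) {
    for (g in names(design$lev_idx)) {
      idx <- design$lev_idx[[g]]
      ok <- idx > 0L
      if (!is.null(params$ranef[[g]]$s0) && any(ok)) {
        mu[ok] <- mu[ok] + params$ranef[[g]]$s0[idx[ok]]
      }
    }
  }
  eta <- if (spec$heteroscedastic) params$s0[2L] + agg[, 2L]
         else rep(params$s0[2L], n)
  list(mu = mu, eta = eta)
}

#' Diagnostic: kernel mass beyond the history horizon
#'
#' Reports the fraction of the absolute area of a fitted univariate impulse
#' response curve that lies beyond `d_max`, by extrapolating the curve on an
#' extended delay grid. Large values mean the horizon truncates real response
#' mass and `d_max` should be increased.
#'
#' @param model fitted model (see [fit_cdrnn()]).
#' @param predictor predictor name (or `"rate"`).
#' @param d_max horizon to assess (defaults to the model's own).
#' @param d_far far end of the extended grid.
#' @param n_grid grid resolution.
#' @return fraction in `[0, 1]`.
#' @export
kernel_mass_beyond <- function(model, predictor, d_max = NULL, d_far = NULL,
                               n_grid = 401L) {
  spec <- if (inherits(model, "cdrnn_ensemble")) model$members[[1L]]$spec
          else model$spec
  d_max <- d_max %||% spec$d_max
  d_far <- d_far %||% (3 * d_max)
  cur <- irf_curve(model, predictor, delays = seq(0, d_far, length.out = n_grid),
                   n_mc = 1L)
  a <- abs(cur$est)
  sum(a[cur$delay > d_max]) / max(sum(a), 1e-12)
}
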