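## Stochastic-gradient estimation of the deconvolutional network. The
## objective is the penalized negative mean log likelihood on the
## standardized scale; gradients are computed analytically (backpropagation
## through the impulse response network and the convolutional read-out) and
## applied with Adam. Monte Carlo dropout is active during training and
## serves as the approximate posterior over network weights; random effects
## and the distribution intercept are point estimates with L2 shrinkage and
## a hard zero-sum projection each epoch.

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size in response samples.
#' @param max_epochs maximum number of passes over the training data.
#' @param dropout Monte Carlo dropout probability on hidden units of the
#'   impulse response network (also the posterior-sampling mechanism).
#' @param weight_penalty L2 penalty strength on network weight matrices.
#' @param ranef_penalty L2 shrinkage strength on random-effect deviations.
#' @param alpha level of the correlation test in the time-loss convergence
#'   criterion.
#' @param window number of recent evaluations over which the criterion
#'   counts non-significant correlation tests.
#' @param eval_interval evaluate the convergence metric every this many
#'   epochs.
#' @param eval_metric convergence metric: `"train_loglik"` (the epoch's mean
#'   training log likelihood, free) or `"exploratory_loglik"` (out-of-sample
#'   mean log likelihood on the exploratory partition, one extra forward
#'   pass per evaluation; requires fitting with `partition` so that
#'   exploratory rows are identifiable).
#' @param refine_frac fraction of the epoch budget forming a final
#'   refinement phase in which dropout is switched off and the step size is
#'   multiplied by `refine_lr_factor`, so the point estimate and scale head
#'   converge to the deterministic-prediction limit used at evaluation
#'   (0 disables the phase).
#' @param refine_lr_factor learning-rate multiplier during refinement.
#' @param clip_norm global gradient-norm clipping threshold.
#' @param stop_on_convergence stop training when the time-loss criterion
#'   fires (otherwise run the full epoch budget and only record the firing
#'   epoch).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout; two runs with the same seed produce identical histories.
#' @param verbose print a line every 50 epochs.
#' @return list of class `cdrnn_control`.
#' @export
cdrnn_control <- function(learning_rate = 1e-3, batch_size = 1024L,
                          max_epochs = 2000L, dropout = 0.1,
                          weight_penalty = 0.01, ranef_penalty = 1.0,
                          alpha = 0.5, window = 100L, eval_interval = 1L,
                          eval_metric = c("train_loglik",
                                          "exploratory_loglik"),
                          refine_frac = 0.3, refine_lr_factor = 0.3,
                          clip_norm = 10, stop_on_convergence = TRUE,
                          seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            dropout >= 0, dropout < 1, weight_penalty >= 0,
            ranef_penalty >= 0, alpha > 0, alpha < 1, window >= 2,
            eval_interval >= 1, refine_frac >= 0, refine_frac < 1,
            refine_lr_factor > 0, clip_norm > 0)
  eval_metric <- match.arg(eval_metric)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), dropout = dropout,
                 weight_penalty = weight_penalty,
                 ranef_penalty = ranef_penalty, alpha = alpha,
                 window = as.integer(window),
                 eval_interval = as.integer(eval_interval),
                 eval_metric = eval_metric,
                 refine_frac = refine_frac,
                 refine_lr_factor = refine_lr_factor,
                 clip_norm = clip_norm,
                 stop_on_convergence = isTRUE(stop_on_convergence),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "cdrnn_control")
}

## p-value of the Pearson correlation between metric and time; ties /
## degenerate series count as failure to reject (p = 1)
.cor_pval <- function(metric, time) {
  n <- length(metric)
  if (n < 3L) return(1)
  if (stats::sd(metric) < 1e-300 || stats::sd(time) < 1e-300) return(1)
  stats::cor.test(metric, time)$p.value
}

#' Time-loss convergence criterion
#'
#' At each evaluation e, the Pearson correlation between the performance
#' metric and training time over the trailing `window` evaluations ending at
#' e is tested at level `alpha`. Training counts as converged at the first
#' evaluation where at least half of the most recent `window` such tests
#' fail to reject the null of no correlation — performance has stopped
#' changing with time. Convergence is never declared before `window`
#' evaluations exist; constant or too-short stretches count as failure to
#' reject.
#'
#' @param metric numeric vector of metric values (e.g. training log
#'   likelihood), one per evaluation; must be finite.
#' @param time training time per evaluation (defaults to the evaluation
#'   index).
#' @param alpha test level.
#' @param window number of recent evaluations considered, both as the
#'   correlation support and as the test-counting horizon.
#' @return list with `converged` (flag: the criterion fired at some
#'   evaluation), `convergence_epoch` (first firing evaluation, NA if none),
#'   `n_fail_to_reject` (count at the firing evaluation, or at the end) and
#'   `pvals` (one trailing-window test per evaluation).
#' @export
check_convergence <- function(metric, time = NULL, alpha = 0.5,
                              window = 100L) {
  if (any(!is.finite(metric))) stop("metric history contains non-finite values")
  stopifnot(alpha > 0, alpha < 1, window >= 2)
  time <- time %||% seq_along(metric)
  stopifnot(length(time) == length(metric))
  n <- length(metric)
  pvals <- vapply(seq_len(n), function(e) {
    lo <- max(1L, e - window + 1L)
    .cor_pval(metric[lo:e], time[lo:e])
  }, 0)
  if (n < window) {
    return(list(converged = FALSE, convergence_epoch = NA_integer_,
                n_fail_to_reject = NA_integer_, pvals = pvals))
  }
  nf_run <- vapply(seq.int(window, n), function(e) {
    sum(pvals[(e - window + 1L):e] > alpha)
  }, 0)
  fired <- which(nf_run >= window / 2)
  converged <- length(fired) > 0L
  list(converged = converged,
       convergence_epoch = if (converged) as.integer(window + fired[1L] - 1L)
                           else NA_integer_,
       n_fail_to_reject = if (converged) as.integer(nf_run[fired[1L]])
                          else as.integer(nf_run[length(nf_run)]),
       pvals = pvals)
}

## ---- Adam -----------------------------------------------------------------

.adam_init <- function(tensors) {
  list(m = lapply(tensors, function(x) x * 0),
       v = lapply(tensors, function(x) x * 0), t = 0L)
}

.adam_step <- function(state, tensors, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    tensors[[k]] <- tensors[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(state = state, tensors = tensors)
}

## flatten/unflatten model parameters to a named tensor list for the optimizer
.params_to_tensors <- function(params, spec) {
  tensors <- list()
  if (spec$irf == "nn") for (k in names(params$ffn)) {
    tensors[[paste0("ffn.", k)]] <- params$ffn[[k]]
  }
  tensors$bvec <- params$bvec
  tensors$s0 <- params$s0
  for (g in names(params$ranef)) {
    for (bl in names(params$ranef[[g]])) {
      tensors[[paste0("ranef.", g, ".", bl)]] <- params$ranef[[g]][[bl]]
    }
  }
  tensors
}

.tensors_to_params <- function(tensors, params, spec) {
  if (spec$irf == "nn") for (k in names(params$ffn)) {
    params$ffn[[k]] <- tensors[[paste0("ffn.", k)]]
  }
  params$bvec <- tensors$bvec
  params$s0 <- tensors$s0
  for (g in names(params$ranef)) {
    for (bl in names(params$ranef[[g]])) {
      params$ranef[[g]][[bl]] <- tensors[[paste0("ranef.", g, ".", bl)]]
    }
  }
  params
}

#' Fit a continuous-time deconvolutional regression network
#'
#' Maximizes the penalized log likelihood of the training responses by Adam
#' with Monte Carlo dropout, applying the zero-sum projection to random
#' effects after every epoch, and stops when the time-loss criterion of
#' [check_convergence()] fires (or at `max_epochs`). Deterministic given
#' `control$seed`.
#'
#' @param events event table.
#' @param responses response table; if `partition` is non-NULL, only rows
#'   whose `partition_label` matches are used.
#' @param spec a [cdrnn_spec()].
#' @param control a [cdrnn_control()].
#' @param partition optional partition label(s) selecting training rows.
#' @return object of class `cdrnn_fit`: parameters, standardization
#'   constants, random-effect level tables, the epochwise history
#'   (`epoch`, `time`, `loglik` on the raw response scale per sample,
#'   `objective`, `pval`), the convergence epoch, and the seed.
#' @export
fit_cdrnn <- function(events, responses, spec, control = cdrnn_control(),
                      partition = NULL) {
  stopifnot(inherits(spec, "cdrnn_model_spec"),
            inherits(control, "cdrnn_control"))
  eval_responses <- NULL
  if (!is.null(partition)) {
    stop_missing_cols(responses, "partition_label", "response table")
    if (control$eval_metric == "exploratory_loglik") {
      eval_responses <- responses[responses$partition_label == "exploratory",
                                  , drop = FALSE]
    }
    responses <- responses[responses$partition_label %in% partition, ,
                           drop = FALSE]
  }
  if (control$eval_metric == "exploratory_loglik" &&
      (is.null(eval_responses) || nrow(eval_responses) == 0L)) {
    stop("eval_metric = 'exploratory_loglik' needs fitting with `partition` ",
         "and a nonempty exploratory partition")
  }
  if (nrow(responses) == 0L) stop("training split is empty")
  stop_missing_cols(responses, spec$response, "response table")

  set.seed(derive_seed(control$seed, 0L))
  design <- .build_design(events, responses, spec)
  # exploratory metric is evaluated with the training standardization and
  # level tables
  design_eval <- if (!is.null(eval_responses)) {
    .build_design(events, eval_responses, spec, stats = design$stats,
                  levels = design$lev_names, warn_unknown = FALSE)
  }
  S_net <- .spec_S_net(spec)
  J <- .spec_J(spec)
  n <- design$n_resp

  ## initialization: random network, unit coefficients, intercept at the
  ## (standardized) response mean and unit scale
  params <- list(bvec = rep(1, J + 1L),
                 s0 = c(0, softplus_inv(1)),
                 ranef = list())
  if (spec$irf == "nn") params$ffn <- ffn_init(.spec_ffn(spec))
  for (g in spec$groups %||% character(0)) {
    L <- length(design$lev_names[[g]])
    params$ranef[[g]] <- list()
    if ("s0" %in% spec$ranef_blocks) params$ranef[[g]]$s0 <- numeric(L)
    if ("b" %in% spec$ranef_blocks) params$ranef[[g]]$b <- matrix(0, L, J + 1L)
  }

  tensors <- .params_to_tensors(params, spec)
  opt <- .adam_init(tensors)
  ffns <- if (spec$irf == "nn") .spec_ffn(spec)

  hist_loglik <- numeric(control$max_epochs)
  hist_time <- numeric(control$max_epochs)
  hist_obj <- numeric(control$max_epochs)
  hist_pval <- rep(NA_real_, control$max_epochs)
  pvals <- numeric(0)
  metrics <- numeric(0)
  times <- numeric(0)
  converged <- FALSE
  convergence_epoch <- NA_integer_
  t_start <- proc.time()[["elapsed"]]
  n_batches <- ceiling(n / control$batch_size)
  Scols <- lapply(seq_len(S_net), function(s) s + S_net * (0:J))

  refine_start <- if (control$refine_frac > 0) {
    as.integer(ceiling((1 - control$refine_frac) * control$max_epochs)) + 1L
  } else {
    control$max_epochs + 1L
  }

  for (epoch in seq_len(control$max_epochs)) {
    refining <- epoch >= refine_start
    dropout_now <- if (refining) 0 else control$dropout
    lr_now <- if (refining) {
      control$learning_rate * control$refine_lr_factor
    } else {
      control$learning_rate
    }
    perm <- sample.int(n)
    ll_total <- 0
    for (bi in seq_len(n_batches)) {
      ids <- perm[seq.int((bi - 1L) * control$batch_size + 1L,
                          min(bi * control$batch_size, n))]
      nb <- length(ids)
      sel <- unlist(design$pairs_by_resp[ids], use.names = FALSE)
      nloc <- rep(seq_along(ids), lengths(design$pairs_by_resp[ids]))
      np <- length(sel)

      ## ---- forward ----
      if (np > 0) {
        Xb <- design$Xin[sel, , drop = FALSE]
        if (spec$irf == "nn") {
          fw <- ffn_forward(ffns, params$ffn, Xb, dropout = dropout_now,
                            masks = "row", keep_cache = TRUE)
          Out <- fw$out
        } else {
          Out <- .dirac_out(np, S_net, J)
        }
        if (spec$causal) {
          neg <- design$d_raw[sel] < 0
          if (any(neg)) Out[neg, ] <- 0
        }
        bmat <- matrix(params$bvec, nb, J + 1L, byrow = TRUE)
        lev_b <- list()
        for (g in names(design$lev_idx)) {
          if (!is.null(params$ranef[[g]]$b)) {
            lv <- design$lev_idx[[g]][ids]
            lev_b[[g]] <- lv
            ok <- lv > 0L
            if (any(ok)) bmat[ok, ] <- bmat[ok, ] +
                params$ranef[[g]]$b[lv[ok], , drop = FALSE]
          }
        }
        Ub <- design$U[sel, , drop = FALSE]
        Wp <- Ub * bmat[nloc, , drop = FALSE]
        agg <- matrix(0, nb, S_net)
        for (s in seq_len(S_net)) {
          rs <- rowsum(rowSums(Out[, Scols[[s]], drop = FALSE] * Wp), nloc)
          agg[as.integer(rownames(rs)), s] <- rs[, 1L]
        }
      } else {
        agg <- matrix(0, nb, S_net)
        Out <- NULL
      }

      mu <- params$s0[1L] + agg[, 1L]
      lev_s0 <- list()
      for (g in names(design$lev_idx)) {
        if (!is.null(params$ranef[[g]]$s0)) {
          lv <- design$lev_idx[[g]][ids]
          lev_s0[[g]] <- lv
          ok <- lv > 0L
          if (any(ok)) mu[ok] <- mu[ok] + params$ranef[[g]]$s0[lv[ok]]
        }
      }
      eta <- if (spec$heteroscedastic) params$s0[2L] + agg[, 2L]
             else rep(params$s0[2L], nb)
      sigma <- softplus(eta)
      yb <- design$ys[ids]
      r <- yb - mu
      ll <- -0.918938533204672742 - log(sigma) - 0.5 * (r / sigma)^2
      ll_total <- ll_total + sum(ll)
      if (any(!is.finite(ll))) {
        stop(sprintf(paste0("non-finite objective at epoch %d ",
                            "(batch %d); try a smaller learning rate"),
                     epoch, bi))
      }

      ## ---- backward ----
      g_mu <- -(r / sigma^2) / nb
      g_sig <- (1 / sigma - r^2 / sigma^3) / nb
      g_eta <- g_sig * softplus_grad(eta)

      grads <- list()
      grads$s0 <- c(sum(g_mu), sum(g_eta))
      for (g in names(lev_s0)) {
        gv <- numeric(length(design$lev_names[[g]]))
        lv <- lev_s0[[g]]
        ok <- lv > 0L
        if (any(ok)) {
          rs <- rowsum(g_mu[ok], lv[ok])
          gv[as.integer(rownames(rs))] <- rs[, 1L]
        }
        grads[[paste0("ranef.", g, ".s0")]] <- gv +
          2 * control$ranef_penalty * params$ranef[[g]]$s0
      }

      if (np > 0) {
        gsp <- cbind(g_mu, if (spec$heteroscedastic) g_eta)
        gm <- gsp[nloc, , drop = FALSE]
        ## gradient flowing into the convolution-weight outputs
        dOut <- matrix(0, np, S_net * (J + 1L))
        GW <- matrix(0, np, J + 1L)
        for (s in seq_len(S_net)) {
          dOut[, Scols[[s]]] <- gm[, s] * Wp
          GW <- GW + gm[, s] * Out[, Scols[[s]], drop = FALSE]
        }
        GU <- GW * Ub
        grads$bvec <- colSums(GU)
        for (g in names(lev_b)) {
          gmat <- matrix(0, length(design$lev_names[[g]]), J + 1L)
          lv <- lev_b[[g]][nloc]
          ok <- lv > 0L
          if (any(ok)) {
            rs <- rowsum(GU[ok, , drop = FALSE], lv[ok])
            gmat[as.integer(rownames(rs)), ] <- rs
          }
          grads[[paste0("ranef.", g, ".b")]] <- gmat +
            2 * control$ranef_penalty * params$ranef[[g]]$b
        }
        if (spec$irf == "nn") {
          if (spec$causal && any(neg)) dOut[neg, ] <- 0
          bw <- ffn_backward(ffns, params$ffn, fw, dOut,
                             dropout = dropout_now)
          for (k in names(params$ffn)) {
            gk <- bw[[k]]
            if (grepl("^W", k)) {
              gk <- gk + 2 * control$weight_penalty * params$ffn[[k]]
            }
            grads[[paste0("ffn.", k)]] <- gk
          }
        }
      } else {
        grads$bvec <- numeric(J + 1L)
      }

      # global gradient-norm clipping guards occasional unstable steps
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
      if (is.finite(gnorm) && gnorm > control$clip_norm) {
        grads <- lapply(grads, function(g) g * (control$clip_norm / gnorm))
      }
      upd <- .adam_step(opt, tensors, grads, lr_now)
      opt <- upd$state
      tensors <- upd$tensors
      params <- .tensors_to_params(tensors, params, spec)
    }

    ## zero-sum projection of random effects across each factor's levels
    for (g in names(params$ranef)) {
      if (!is.null(params$ranef[[g]]$s0)) {
        params$ranef[[g]]$s0 <- params$ranef[[g]]$s0 -
          mean(params$ranef[[g]]$s0)
      }
      if (!is.null(params$ranef[[g]]$b)) {
        params$ranef[[g]]$b <- sweep(params$ranef[[g]]$b, 2L,
                                     colMeans(params$ranef[[g]]$b))
      }
    }
    tensors <- .params_to_tensors(params, spec)

    ## epochwise metric and time-loss convergence test
    elapsed <- proc.time()[["elapsed"]] - t_start
    metric <- ll_total / n  # standardized-scale mean train log likelihood
    if (epoch %% control$eval_interval == 0L) {
      if (!is.null(design_eval)) {
        fp <- .forward_params(spec, params, design_eval)
        metric <- mean(-0.918938533204672742 - log(softplus(fp$eta)) -
                         0.5 * ((design_eval$ys - fp$mu) /
                                  softplus(fp$eta))^2)
      }
      metrics <- c(metrics, metric)
      times <- c(times, elapsed)
      lo <- max(1L, length(metrics) - control$window + 1L)
      pvals <- c(pvals, .cor_pval(metrics[lo:length(metrics)],
                                  times[lo:length(times)]))
      n_eval <- length(metrics)
      if (!converged && n_eval >= control$window) {
        nf <- sum(pvals[(n_eval - control$window + 1L):n_eval] > control$alpha)
        if (nf >= control$window / 2) {
          converged <- TRUE
          convergence_epoch <- epoch
        }
      }
    }
    pen <- 0
    if (spec$irf == "nn") {
      pen <- pen + control$weight_penalty *
        sum(vapply(grep("^W", names(params$ffn), value = TRUE),
                   function(k) sum(params$ffn[[k]]^2), 0))
    }
    for (g in names(params$ranef)) {
      pen <- pen + control$ranef_penalty *
        sum(vapply(params$ranef[[g]], function(m) sum(m^2), 0))
    }
    hist_time[epoch] <- elapsed
    hist_loglik[epoch] <- metric - log(design$stats$y_sd) # raw-scale mean
    hist_obj[epoch] <- -metric + pen
    if (epoch %% control$eval_interval == 0L) {
      hist_pval[epoch] <- pvals[length(pvals)]
    }
    if (control$verbose && epoch %% 50L == 0L) {
      message(sprintf("epoch %d: loglik %.4f", epoch, metric))
    }
    if (converged && control$stop_on_convergence) break
  }

  n_done <- if (converged && control$stop_on_convergence) convergence_epoch
            else min(epoch, control$max_epochs)
  history <- data.frame(epoch = seq_len(n_done),
                        time = hist_time[seq_len(n_done)],
                        loglik = hist_loglik[seq_len(n_done)],
                        objective = hist_obj[seq_len(n_done)],
                        pval = hist_pval[seq_len(n_done)])

  structure(list(spec = spec, control = control, params = params,
                 stats = design$stats, levels = design$lev_names,
                 history = history, converged = converged,
                 convergence_epoch = convergence_epoch,
                 seed = control$seed, version = 1L),
            class = "cdrnn_fit")
}

#' Draw approximate posterior samples from a fitted model
#'
#' Each draw is a stochastic forward parameterization obtained by resampling
#' the Monte Carlo dropout masks of the impulse response network (one mask
#' vector per hidden layer, shared across evaluation rows within a draw).
#' With dropout 0 the posterior is degenerate and all draws coincide.
#'
#' @param fit a `cdrnn_fit`.
#' @param n_samples number of draws (>= 1).
#' @param seed integer seed; the same seed reproduces the same draws.
#' @return list of length `n_samples`; each element holds `masks`.
#' @export
posterior_sample <- function(fit, n_samples, seed = 1L) {
  if (n_samples < 1) stop("n_samples must be at least 1")
  p <- fit$control$dropout
  hidden <- fit$spec$hidden
  set.seed(derive_seed(seed, 3L))
  lapply(seq_len(n_samples), function(i) {
    masks <- lapply(hidden, function(w) {
      if (p > 0 && fit$spec$irf == "nn") stats::rbinom(w, 1L, 1 - p)
      else rep(1L, w)
    })
    list(masks = masks)
  })
}

#' Implied raw-scale regression coefficients of a discrete-time reduction
#'
#' For a model with the `"dirac"` impulse response (and `f_in` identity), the
#' location model collapses to ordinary linear regression; this accessor
#' undoes the internal standardization and returns the implied intercept and
#' slopes on the raw data scale, comparable to `coef(lm(...))`.
#'
#' @param object a `cdrnn_fit` with `spec$irf == "dirac"`.
#' @param ... unused.
#' @return named numeric vector: `(Intercept)` then one slope per predictor.
#' @export
coef.cdrnn_fit <- function(object, ...) {
  spec <- object$spec
  if (spec$irf != "dirac") {
    stop("raw-scale coefficients are defined for the dirac reduction only")
  }
  st <- object$stats
  b <- object$params$bvec
  slopes <- b[-1L] * st$y_sd / st$x_sd
  intercept <- st$y_mean + st$y_sd * (object$params$s0[1L] + b[1L]) -
    sum(slopes * st$x_mean)
  stats::setNames(c(intercept, slopes),
                  c("(Intercept)", spec$predictors))
}
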