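## Generalization-based hypothesis testing: constraint-defined null models,
## ensembles of independently seeded fits, and paired permutation tests on
## out-of-sample conditional log likelihood.

#' Derive a constrained (null) model specification
#'
#' Any null hypothesis expressible as a model constraint becomes a fittable
#' specification: ablation removes a predictor from both the network inputs
#' and the convolution; linearity removes predictors from the network inputs
#' only (their effect stays linear through the convolution product);
#' stationarity removes the event timestamp from the network inputs;
#' homoscedasticity fixes the scale to a single free constant. Constraints
#' compose.
#'
#' @param spec a [cdrnn_spec()].
#' @param constraints list with any of: `ablate` (predictor names),
#'   `linear` (`TRUE`/`"all"` or predictor names), `stationary` (flag),
#'   `homoscedastic` (flag), `causal` (flag, to force causal masking).
#' @return the constrained `cdrnn_model_spec`.
#' @export
build_null <- function(spec, constraints = list()) {
  stopifnot(inherits(spec, "cdrnn_model_spec"))
  known <- c("ablate", "linear", "stationary", "homoscedastic", "causal")
  if (length(setdiff(names(constraints), known))) {
    stop(sprintf("unknown constraint(s): %s",
                 paste(setdiff(names(constraints), known), collapse = ", ")))
  }
  if (!is.null(constraints$ablate)) {
    bad <- setdiff(constraints$ablate, spec$predictors)
    if (length(bad)) {
      stop(sprintf("cannot ablate unknown predictor(s): %s",
                   paste(bad, collapse = ", ")))
    }
    spec$predictors <- setdiff(spec$predictors, constraints$ablate)
    spec$linear_predictors <- setdiff(spec$linear_predictors,
                                      constraints$ablate)
    if (!length(spec$predictors)) {
      stop("ablation removed every predictor; at least one must remain")
    }
  }
  if (!is.null(constraints$linear)) {
    lin <- constraints$linear
    if (isTRUE(lin) || identical(lin, "all")) lin <- spec$predictors
    bad <- setdiff(lin, spec$predictors)
    if (length(bad)) {
      stop(sprintf("cannot linearize unknown predictor(s): %s",
                   paste(bad, collapse = ", ")))
    }
    spec$linear_predictors <- union(spec$linear_predictors, lin)
  }
  if (isTRUE(constraints$stationary)) spec$nonstationary <- FALSE
  if (isTRUE(constraints$homoscedastic)) spec$heteroscedastic <- FALSE
  if (!is.null(constraints$causal)) spec$causal <- isTRUE(constraints$causal)
  spec
}

#' Fit an ensemble of independently seeded models
#'
#' Members differ only in their random seed (initialization, shuffling and
#' dropout). The ensemble's predictive density for a sample is the
#' equal-weight mixture of the members' densities, i.e. the log-mean-exp of
#' their pointwise log likelihoods.
#'
#' @param events,responses data tables.
#' @param spec a [cdrnn_spec()].
#' @param n_members ensemble size.
#' @param control a [cdrnn_control()]; each member gets a seed derived from
#'   `control$seed` unless `seeds` is given.
#' @param seeds optional integer vector of member seeds.
#' @param partition optional partition label(s) selecting training rows.
#' @return object of class `cdrnn_ensemble` with elements `members`, `spec`
#'   and `seeds`.
#' @export
ensemble_fit <- function(events, responses, spec, n_members = 10L,
                         control = cdrnn_control(), seeds = NULL,
                         partition = NULL) {
  stopifnot(n_members >= 1)
  seeds <- seeds %||% vapply(seq_len(n_members),
                             function(i) derive_seed(control$seed, 100L + i),
                             integer(1))
  stopifnot(length(seeds) == n_members)
  members <- lapply(seeds, function(s) {
    ctl <- control
    ctl$seed <- as.integer(s)
    fit_cdrnn(events, responses, spec, ctl, partition = partition)
  })
  structure(list(members = members, spec = spec, seeds = seeds),
            class = "cdrnn_ensemble")
}

#' @export
predict.cdrnn_ensemble <- function(object, events, responses, ...) {
  prs <- lapply(object$members, predict, events = events,
                responses = responses, ...)
  out <- prs[[1L]][, c("series", "time", intersect("y", names(prs[[1L]])))]
  mu_m <- sapply(prs, `[[`, "mu")
  sg_m <- sapply(prs, `[[`, "sigma")
  out$mu <- rowMeans(mu_m)
  # scale of the equal-weight mixture of member normals
  out$sigma <- sqrt(rowMeans(sg_m^2 + mu_m^2) - out$mu^2)
  if (!is.null(prs[[1L]]$loglik)) {
    llm <- sapply(prs, `[[`, "loglik")
    llm <- matrix(llm, ncol = length(prs))
    out$loglik <- log_mean_exp(llm)
    attr(out, "member_loglik") <- llm
  }
  out
}

#' Paired permutation test on pointwise log likelihoods
#'
#' Tests whether two models assign systematically different conditional log
#' likelihoods to the same out-of-sample responses. The observed statistic is
#' the absolute total difference `|sum(lla - llb)|`; the null distribution is
#' built by independently swapping each pair's labels with probability 1/2,
#' and the p-value uses add-one smoothing,
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param lla,llb aligned numeric vectors of per-sample log likelihoods; if
#'   both carry names, the names must agree elementwise.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param cluster optional vector of cluster ids (e.g. participant): labels
#'   are then swapped per cluster rather than per sample.
#' @return list with `p`, `statistic` (observed absolute total difference),
#'   `delta` (signed total difference, model a minus model b) and `n_perm`.
#' @export
paired_permutation_test <- function(lla, llb, n_perm = 10000L, seed = 1L,
                                    cluster = NULL) {
  if (length(lla) != length(llb)) stop("likelihood vectors differ in length")
  if (!is.null(names(lla)) && !is.null(names(llb)) &&
      !identical(names(lla), names(llb))) {
    stop("likelihood vectors are not aligned: sample identifiers differ")
  }
  if (any(!is.finite(lla)) || any(!is.finite(llb))) {
    stop("likelihood vectors must be finite")
  }
  if (n_perm < 1) stop("n_perm must be at least 1")
  d <- lla - llb
  if (!is.null(cluster)) {
    d <- as.numeric(rowsum(d, cluster))  # swap whole clusters together
  }
  delta <- sum(d)
  obs <- abs(delta)
  set.seed(derive_seed(seed, 4L))
  n <- length(d)
  exceed <- 0L
  chunk <- max(1L, min(n_perm, floor(2e7 / max(n, 1L))))
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    signs <- matrix(sample(c(-1, 1), n * k, replace = TRUE), n, k)
    null_stats <- abs(colSums(d * signs))
    exceed <- exceed + sum(null_stats >= obs - 1e-12)
    done <- done + k
  }
  list(p = (1 + exceed) / (1 + n_perm), statistic = obs, delta = delta,
       n_perm = as.integer(n_perm))
}

#' Compare a full model against a constraint-defined null
#'
#' Fits ensembles of the full and the constrained specification on the
#' training partition, evaluates both on a held-out partition, and runs the
#' paired permutation test on the pointwise ensemble log likelihoods.
#'
#' @param events,responses data tables; `responses` must carry
#'   `partition_label`.
#' @param spec full-model [cdrnn_spec()].
#' @param constraints constraint list for [build_null()]; an empty list
#'   compares the model with itself (delta 0, p 1).
#' @param n_members ensemble size for both models.
#' @param n_perm permutations.
#' @param partition held-out partition label to evaluate on.
#' @param control training control.
#' @param seed seed for the permutation test.
#' @return list of class `cdrnn_comparison`: `delta` (full minus null total
#'   held-out log likelihood), `p`, `loglik_full`, `loglik_null` (totals),
#'   `member_loglik` (per-member totals), `constraints`, and the two
#'   ensembles.
#' @export
compare <- function(events, responses, spec, constraints = list(),
                    n_members = 10L, n_perm = 10000L, partition = "test",
                    control = cdrnn_control(), seed = 1L) {
  stop_missing_cols(responses, "partition_label", "response table")
  held <- responses[responses$partition_label %in% partition, , drop = FALSE]
  if (!nrow(held)) stop(sprintf("no rows in partition '%s'", partition))
  ens_full <- ensemble_fit(events, responses, spec, n_members, control,
                           partition = "train")
  null_spec <- build_null(spec, constraints)
  ens_null <- if (length(constraints)) {
    ensemble_fit(events, responses, null_spec, n_members, control,
                 partition = "train")
  } else {
    ens_full
  }
  lla <- loglik_vector(ens_full, events, held)
  llb <- loglik_vector(ens_null, events, held)
  pt <- paired_permutation_test(lla, llb, n_perm = n_perm, seed = seed)
  member_ll <- data.frame(
    member = seq_along(ens_full$members),
    full = vapply(ens_full$members, function(m)
      sum(loglik_vector(m, events, held)), 0),
    null = vapply(ens_null$members, function(m)
      sum(loglik_vector(m, events, held)), 0))
  structure(list(delta = pt$delta, p = pt$p, statistic = pt$statistic,
                 loglik_full = sum(lla), loglik_null = sum(llb),
                 member_loglik = member_ll, constraints = constraints,
                 ensemble_full = ens_full, ensemble_null = ens_null,
                 partition = partition, n_perm = n_perm, seed = seed),
            class = "cdrnn_comparison")
}

#' @export
print.cdrnn_comparison <- function(x, ...) {
  cat("Out-of-sample model comparison (paired permutation test)\n")
  cat(sprintf("  held-out partition: %s\n",
              paste(x$partition, collapse = ", ")))
  cat(sprintf("  constraints on null: %s\n",
              if (length(x$constraints))
                paste(names(x$constraints), collapse = ", ") else "none"))
  cat(sprintf("  total log likelihood, full: %.3f  null: %.3f\n",
              x$loglik_full, x$loglik_null))
  cat(sprintf("  delta: %.3f   p = %.5g (%d permutations)\n",
              x$delta, x$p, x$n_perm))
  invisible(x)
}
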