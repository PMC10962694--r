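# Shared fixtures, built in code. The quickstart is memoised per test run
# because several files use it.

.qs_cache <- new.env(parent = emptyenv())

get_quickstart <- function(seed = 1L) {
  key <- paste0("qs", seed)
  if (is.null(.qs_cache[[key]])) .qs_cache[[key]] <- quickstart_fixture(seed)
  .qs_cache[[key]]
}

# a tiny hand-checkable model object: known weights, no fitting
make_toy_fit <- function(predictors = c("x1", "x2"), hidden = c(4L, 3L),
                         heteroscedastic = TRUE, causal = TRUE,
                         nonstationary = TRUE, linear_predictors = character(0),
                         dropout = 0, seed = 42L, zero_weights = FALSE,
                         groups = NULL, irf = "nn", d_max = 5) {
  spec <- cdrnn_spec(predictors, groups = groups, d_max = d_max,
                     heteroscedastic = heteroscedastic, causal = causal,
                     nonstationary = nonstationary,
                     linear_predictors = linear_predictors,
                     irf = irf, hidden = hidden)
  set.seed(seed)
  params <- list(bvec = rep(1, length(predictors) + 1L),
                 s0 = c(0, softplus_inv(1)), ranef = list())
  if (irf == "nn") {
    params$ffn <- ffn_init(cdrnn:::.spec_ffn(spec))
    if (zero_weights) {
      params$ffn <- lapply(params$ffn, function(x) x * 0)
    }
  }
  stats <- list(x_mean = stats::setNames(rep(0, length(predictors)), predictors),
                x_sd = stats::setNames(rep(1, length(predictors)), predictors),
                t_mean = 0, t_sd = 1, t_min = 0, t_max = 100,
                d_mean = 0, d_sd = 1, y_mean = 0, y_sd = 1)
  structure(list(spec = spec,
                 control = cdrnn_control(dropout = dropout),
                 params = params, stats = stats,
                 levels = stats::setNames(list(), character(0)),
                 history = data.frame(), converged = TRUE,
                 convergence_epoch = NA_integer_, seed = seed, version = 1L),
            class = "cdrnn_fit")
}

# small event/response tables for prediction tests
make_toy_data <- function(n_events = 12L, seed = 5L, series = "s1") {
  set.seed(seed)
  events <- data.frame(series = series,
                       time = cumsum(runif(n_events, 0.2, 0.6)))
  events$x1 <- rnorm(n_events)
  events$x2 <- rnorm(n_events)
  responses <- data.frame(series = series, time = events$time,
                          y = rnorm(n_events))
  list(events = events, responses = responses)
}
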