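test_that("zero-weight networks give identically zero effect curves", {
  fit <- make_toy_fit(zero_weights = TRUE)
  cur <- irf_curve(fit, "x1", delays = seq(0, 2, length.out = 11), n_mc = 1)
  expect_equal(cur$est, rep(0, 11))
  expect_equal(cur$lo, rep(0, 11))
  expect_equal(cur$hi, rep(0, 11))
})

test_that("causal models have exactly zero effects at negative delays", {
  fit <- make_toy_fit(causal = TRUE)
  cur <- irf_curve(fit, "x1", delays = c(-1, -0.1, 0, 0.5), n_mc = 1)
  expect_equal(cur$est[1:2], c(0, 0))
  expect_false(cur$est[4] == 0)
})

test_that("effect estimates vanish at the reference point", {
  fit <- make_toy_fit()
  # querying the reference value itself gives a zero self-difference
  cur <- irf_curve(fit, "x1", delays = c(0.2, 0.7), value = 0, n_mc = 1)
  expect_equal(cur$est, c(0, 0))
  sur <- effect_surface(fit, "x1", values = 0, delays = c(0.2, 0.7), n_mc = 1)
  expect_equal(sur$est, c(0, 0))
  int <- interaction_surface(fit, "x1", "x2", values_a = 0, values_b = 0,
                             delay = 0.5, n_mc = 1)
  expect_equal(int$est, 0)
})

test_that("surfaces slice consistently into curves", {
  fit <- make_toy_fit(seed = 77)
  delays <- seq(0, 1, length.out = 7)
  sur <- effect_surface(fit, "x1", values = 1, delays = delays, n_mc = 1)
  cur <- irf_curve(fit, "x1", delays = delays, value = 1, n_mc = 1)
  expect_equal(sur$est, cur$est, tolerance = 1e-12)
  sl <- functional_form_slice(fit, "x1", values = c(-1, 0, 1), delay = 0.5,
                              n_mc = 1)
  su2 <- effect_surface(fit, "x1", values = c(-1, 0, 1), delays = 0.5,
                        n_mc = 1)
  expect_equal(sl$est, su2$est)
})

test_that("linearity constraint makes the effect linear in the predictor", {
  fit <- make_toy_fit(linear_predictors = "x1", seed = 31)
  vals <- c(-2, -1, 0, 1, 2)
  sl <- functional_form_slice(fit, "x1", values = vals, delay = 0.4, n_mc = 1)
  # second differences vanish for a linear function
  expect_equal(diff(diff(sl$est)), rep(0, 3), tolerance = 1e-10)
})

test_that("stationarity constraint flattens the nonstationarity curve", {
  fit <- make_toy_fit(nonstationary = FALSE, seed = 55)
  ns <- nonstationarity_curve(fit, "x1", delay = 0.5,
                              onsets = c(0, 50, 100), n_mc = 1)
  expect_equal(ns$est, rep(ns$est[1], 3))
  # a single onset equals the curve evaluated at that onset
  cur <- irf_curve(fit, "x1", delays = 0.5, onset = 50, n_mc = 1)
  expect_equal(ns$est[2], cur$est)
})

test_that("sigma effects index the scale parameter and respect constraints", {
  fit_hom <- make_toy_fit(heteroscedastic = FALSE, seed = 9)
  s <- sigma_irf(fit_hom, "x1", delays = c(0.1, 0.5), n_mc = 1)
  expect_equal(s$est, c(0, 0))
  fit_het <- make_toy_fit(heteroscedastic = TRUE, seed = 9)
  s2 <- sigma_irf(fit_het, "x1", delays = c(0.1, 0.5), n_mc = 1)
  c2 <- irf_curve(fit_het, "x1", delays = c(0.1, 0.5), target = "sigma",
                  n_mc = 1)
  expect_identical(s2$est, c2$est)
})

test_that("queries are invariant to unrelated context events", {
  # a query is built from a single synthetic event; verify against the
  # prediction-difference route with extra context present
  fit <- make_toy_fit(seed = 100)
  delay <- 0.6
  onset <- 2
  context <- data.frame(series = "q", time = c(0.3, 1.1),
                        x1 = c(0.7, -0.2), x2 = c(0.1, 0.4))
  ev_q <- rbind(context, data.frame(series = "q", time = onset, x1 = 1,
                                    x2 = 0))
  ev_r <- rbind(context, data.frame(series = "q", time = onset, x1 = 0,
                                    x2 = 0))
  resp <- data.frame(series = "q", time = onset + delay, y = 0)
  pq <- predict(fit, ev_q, resp)
  pr <- predict(fit, ev_r, resp)
  cur <- irf_curve(fit, "x1", delays = delay, value = 1, onset = onset,
                   n_mc = 1)
  expect_equal(pq$mu - pr$mu, cur$est, tolerance = 1e-10)
})

test_that("credible bands are empirical quantiles with sane degeneracies", {
  # all draws identical: zero-width band at the estimate
  draws <- matrix(2, nrow = 10, ncol = 3)
  b <- credible_band(draws)
  expect_equal(b$lo, rep(2, 3))
  expect_equal(b$hi, rep(2, 3))
  # draws 1..100 at level 0.95: the 2.5 and 97.5 empirical percentiles
  b2 <- credible_band(matrix(1:100, ncol = 1), level = 0.95)
  expect_equal(b2$lo, unname(quantile(1:100, 0.025)))
  expect_equal(b2$hi, unname(quantile(1:100, 0.975)))
  # bands bracket the mean estimate pointwise
  set.seed(3)
  dr <- matrix(rnorm(500), 50, 10)
  bb <- credible_band(dr)
  expect_true(all(bb$lo <= colMeans(dr) & colMeans(dr) <= bb$hi))
})

test_that("interaction residual is zero for additive surfaces", {
  # a linear-constrained model is additive by construction: the joint
  # change equals the sum of the marginal changes
  fit <- make_toy_fit(linear_predictors = c("x1", "x2"), seed = 13)
  joint <- interaction_surface(fit, "x1", "x2", values_a = c(0, 1),
                               values_b = c(0, 1), delay = 0.5, n_mc = 1)
  g <- function(a, b) joint$est[joint$value_a == a & joint$value_b == b]
  resid <- g(1, 1) - g(1, 0) - g(0, 1) + g(0, 0)
  expect_equal(resid, 0, tolerance = 1e-10)
})

test_that("unknown predictors are rejected", {
  fit <- make_toy_fit()
  expect_error(irf_curve(fit, "nope"), "unknown predictor")
  expect_error(effect_surface(fit, "nope"), "unknown predictor")
  expect_error(nonstationarity_curve(fit, "nope"), "unknown predictor")
})
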