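test_that("feedforward recursion matches affine arithmetic and a hand oracle", {
  s1 <- ffn_spec(1, integer(0), 1, "tanh")
  expect_equal(ffn_apply(s1, list(W1 = matrix(1), b1 = 0), 3), 3)
  expect_equal(ffn_apply(s1, list(W1 = matrix(2), b1 = 1), 3), 7)
  # two-layer random net vs an independent recursion written longhand
  set.seed(31)
  s2 <- ffn_spec(3, c(4L, 5L), 2, "tanh")
  p <- ffn_init(s2)
  x <- rnorm(3)
  h1 <- tanh(drop(x %*% p$W1) + p$b1)
  h2 <- tanh(drop(h1 %*% p$W2) + p$b2)
  manual <- drop(h2 %*% p$W3) + p$b3
  expect_equal(ffn_apply(s2, p, x), manual, tolerance = 1e-12)
  # shape mismatch is rejected naming the layer
  expect_error(ffn_apply(s2, p, rnorm(4)), "layer 1")
  bad <- p; bad$W2 <- matrix(0, 2, 2)
  expect_error(ffn_apply(s2, bad, x), "layer 2")
})

test_that("identity activations collapse to a single affine map", {
  set.seed(8)
  s <- ffn_spec(3, c(4L, 4L), 2, "identity")
  p <- ffn_init(s)
  X <- matrix(rnorm(15), 5, 3)
  combined_W <- p$W1 %*% p$W2 %*% p$W3
  combined_b <- drop((p$b1 %*% p$W2 + p$b2) %*% p$W3) + p$b3
  expect_equal(ffn_apply(s, p, X),
               sweep(X %*% combined_W, 2, combined_b, "+"),
               tolerance = 1e-12)
})

test_that("backpropagation matches finite differences", {
  set.seed(2)
  fs <- ffn_spec(3, c(5L, 4L), 4)
  pp <- ffn_init(fs)
  X <- matrix(rnorm(18), 6, 3)
  dOut <- matrix(rnorm(24), 6, 4)
  fw <- cdrnn:::ffn_forward(fs, pp, X, keep_cache = TRUE)
  bw <- cdrnn:::ffn_backward(fs, pp, fw, dOut)
  f0 <- sum(cdrnn:::ffn_forward(fs, pp, X) * dOut)
  eps <- 1e-6
  for (k in names(pp)) {
    g_num <- pp[[k]] * 0
    for (j in seq_along(pp[[k]])) {
      p2 <- pp
      p2[[k]][j] <- p2[[k]][j] + eps
      g_num[j] <- (sum(cdrnn:::ffn_forward(fs, p2, X) * dOut) - f0) / eps
    }
    expect_equal(as.numeric(bw[[k]]), as.numeric(g_num), tolerance = 1e-4)
  }
})

test_that("impulse response map honors causality and constraints", {
  set.seed(12)
  S <- 2L; J <- 2L
  spec <- ffn_spec(J + 2L, c(4L), S * (J + 1L))
  p <- ffn_init(spec)
  # causal mask: negative delay gives the zero matrix
  expect_equal(irf_apply(-2, 1, c(0.5, 1), spec, p, S, J, causal = TRUE),
               matrix(0, S, J + 1L))
  # delay zero is retained (past-and-present convention)
  expect_false(all(irf_apply(0, 1, c(0.5, 1), spec, p, S, J) == 0))
  # unconstrained output equals ffn_apply on the concatenated input, reshaped
  G <- irf_apply(1.5, 2, c(0.5, 1), spec, p, S, J)
  expect_equal(G, matrix(ffn_apply(spec, p, c(1.5, 2, 0.5, 1)), S, J + 1L))
  # stationarity constraint: invariant to the onset timestamp
  spec_s <- ffn_spec(J + 1L, c(4L), S * (J + 1L))
  ps <- ffn_init(spec_s)
  g1 <- irf_apply(1, 5, c(0.5, 1), spec_s, ps, S, J, stationary = TRUE)
  g2 <- irf_apply(1, 5000, c(0.5, 1), spec_s, ps, S, J, stationary = TRUE)
  expect_identical(g1, g2)
  # linearity constraint: bit-identical under perturbation of the excluded
  # impulse dimension
  spec_l <- ffn_spec(J + 1L, c(4L), S * (J + 1L))
  pl <- ffn_init(spec_l)
  gl1 <- irf_apply(1, 2, c(0.5, 1), spec_l, pl, S, J, linear_idx = 2L)
  gl2 <- irf_apply(1, 2, c(0.5, 99), spec_l, pl, S, J, linear_idx = 2L)
  expect_identical(gl1, gl2)
  # homoscedasticity: rows beyond the location row are zero
  spec_h <- ffn_spec(J + 2L, c(4L), 1L * (J + 1L))
  ph <- ffn_init(spec_h)
  gh <- irf_apply(1, 2, c(0.5, 1), spec_h, ph, S, J, homoscedastic = TRUE)
  expect_equal(gh[2L, ], rep(0, J + 1L))
  expect_error(irf_apply(1, 2, c(0.5, 1), spec, p, S, J, linear_idx = 5L),
               "not present")
})

test_that("parameter composition sums fixed and indexed random deviations", {
  st <- parameter_store(c(1, 2), matrix(c(0.5, -0.5, -1, 1), 2, 2,
                                        byrow = TRUE),
                        grouping_map = list(g = 1:2))
  expect_equal(compose_params(st, c(0, 0)), c(1, 2))
  expect_equal(compose_params(st, c(1, 0)), c(1.5, 1.0))
  expect_error(compose_params(st, c(1)), "length")
  expect_error(compose_params(st, c(1, 1)), "more than one active level")
  # two factors: both active columns contribute, equal to index-and-sum
  V <- cbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
  st2 <- parameter_store(c(0, 0), V, grouping_map = list(a = 1:2, b = 3:4))
  z <- c(1, 0, 0, 1)
  expect_equal(compose_params(st2, z), V[, 1] + V[, 4])
  # averaging over the levels of one factor recovers the fixed part
  lvl_means <- rowMeans(sapply(1:2, function(i) {
    z <- numeric(4); z[i] <- 1
    compose_params(st2, z)
  }))
  expect_equal(lvl_means, st2$v0)
})

test_that("zero-sum centering removes row means per block and is idempotent", {
  expect_equal(center_ranef(matrix(c(1, 3), 1)), matrix(c(-1, 1), 1))
  ctr <- center_ranef(matrix(c(-1, 1), 1))
  expect_equal(ctr, matrix(c(-1, 1), 1))
  set.seed(4)
  V <- matrix(rnorm(12), 3, 4)
  gm <- list(a = 1:2, b = 3:4)
  C <- center_ranef(V, gm)
  expect_lt(max(abs(rowSums(C[, 1:2]))), 1e-10)
  expect_lt(max(abs(rowSums(C[, 3:4]))), 1e-10)
  expect_equal(center_ranef(C, gm), C)
})

test_that("input processing defaults to identity and applies nets row-wise", {
  d <- make_toy_data()
  spec <- cdrnn_spec(c("x1", "x2"))
  expect_equal(input_transform(d$events, spec),
               as.matrix(d$events[c("x1", "x2")]))
  set.seed(3)
  fs <- ffn_spec(3, c(4L), 2)
  fp <- ffn_init(fs)
  out <- input_transform(d$events, f_in_spec = fs, f_in_params = fp)
  # row-wise equals per-row application
  row3 <- ffn_apply(fs, fp, c(d$events$time[3], d$events$x1[3],
                              d$events$x2[3]))
  expect_equal(out[3, ], row3)
  # zero weights give constant rows
  fp0 <- lapply(fp, function(x) x * 0)
  out0 <- input_transform(d$events, f_in_spec = fs, f_in_params = fp0)
  expect_equal(out0, matrix(0, nrow(d$events), 2))
})
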