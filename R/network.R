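## Feedforward stacks, the neural impulse response map, and mixed-effects
## parameter composition. The forward pass is written with plain matrix
## algebra so the training module can backpropagate through it analytically.

.activations <- list(
  tanh = list(f = tanh, grad = function(a) 1 - a^2),
  relu = list(f = function(z) pmax(z, 0), grad = function(a) as.numeric(a > 0)),
  identity = list(f = identity, grad = function(a) rep(1, length(a)))
)

#' Feedforward network specification
#'
#' @param input_dim width of the input vector.
#' @param hidden integer vector of hidden-layer widths (may be empty).
#' @param output_dim width of the output.
#' @param activation hidden-layer activation (`"tanh"`, `"relu"` or
#'   `"identity"`); the output activation is always identity so convolution
#'   weights are unbounded.
#' @return object of class `ffn_spec`.
#' @export
ffn_spec <- function(input_dim, hidden = c(32L, 32L), output_dim,
                     activation = "tanh") {
  stopifnot(input_dim >= 1, output_dim >= 1, all(hidden >= 1),
            activation %in% names(.activations))
  widths <- c(input_dim, as.integer(hidden), output_dim)
  acts <- c(rep(activation, length(hidden)), "identity")
  structure(list(widths = widths, activations = acts,
                 L = length(widths) - 1L), class = "ffn_spec")
}

#' Initialize feedforward parameters (Glorot-uniform weights, zero biases)
#'
#' @param spec an [ffn_spec()].
#' @return list with matrices `W1..WL` and vectors `b1..bL`.
#' @export
ffn_init <- function(spec) {
  stopifnot(inherits(spec, "ffn_spec"))
  params <- list()
  for (l in seq_len(spec$L)) {
    fan_in <- spec$widths[l]
    fan_out <- spec$widths[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    # the output layer starts small so that summing over long event
    # histories yields near-zero convolution weights at initialization
    if (l == spec$L) lim <- lim / 10
    params[[paste0("W", l)]] <-
      matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    params[[paste0("b", l)]] <- numeric(fan_out)
  }
  params
}

## Internal vectorized forward pass over rows of X.
## dropout masks: NULL (off), "row" (fresh Bernoulli per row, training),
## or a list of per-layer mask VECTORS shared across rows (one posterior draw).
## Returns list(out, cache) where cache holds post-activation layers for
## backprop.
ffn_forward <- function(spec, params, X, dropout = 0, masks = NULL,
                        keep_cache = FALSE) {
  A <- X
  cache <- if (keep_cache) list(A0 = X) else NULL
  mask_list <- if (keep_cache) list() else NULL
  for (l in seq_len(spec$L)) {
    Z <- A %*% params[[paste0("W", l)]]
    Z <- sweep(Z, 2L, params[[paste0("b", l)]], `+`)
    A <- .activations[[spec$activations[l]]]$f(Z)
    if (keep_cache) cache[[paste0("P", l)]] <- A # pre-dropout activation
    if (l < spec$L && dropout > 0) {
      M <- NULL
      if (is.character(masks) && masks == "row") {
        M <- matrix(stats::rbinom(length(A), 1L, 1 - dropout),
                    nrow(A), ncol(A))
      } else if (is.list(masks)) {
        M <- matrix(masks[[l]], nrow(A), ncol(A), byrow = TRUE)
      }
      if (!is.null(M)) A <- A * M / (1 - dropout)
      if (keep_cache) mask_list[[l]] <- M
    }
    if (keep_cache) cache[[paste0("A", l)]] <- A # layer output as fed onward
  }
  if (keep_cache) list(out = A, cache = cache, masks = mask_list) else A
}

## Backward pass matching ffn_forward(keep_cache = TRUE). dOut is the
## upstream gradient on the output rows. Returns gradients for every W/b
## plus dX (gradient on the input rows).
ffn_backward <- function(spec, params, fw, dOut, dropout = 0) {
  grads <- list()
  dA <- dOut
  for (l in rev(seq_len(spec$L))) {
    A_prev <- fw$cache[[if (l == 1L) "A0" else paste0("A", l - 1L)]]
    act <- spec$activations[l]
    if (l < spec$L && dropout > 0 && !is.null(fw$masks[[l]])) {
      dA <- dA * fw$masks[[l]] / (1 - dropout)
    }
    dZ <- if (act == "identity") dA
          else dA * .activations[[act]]$grad(fw$cache[[paste0("P", l)]])
    grads[[paste0("W", l)]] <- crossprod(A_prev, dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    dA <- dZ %*% t(params[[paste0("W", l)]])
  }
  grads$dX <- dA
  grads
}

#' Apply a feedforward network to an input
#'
#' The recursion is `f_l(x) = act_l(W_l f_(l-1)(x) + b_l)` with `f_0(x) = x`.
#' Accepts a single input vector or a matrix of row vectors.
#'
#' @param spec an [ffn_spec()].
#' @param params parameter list as produced by [ffn_init()].
#' @param x input vector of length `input_dim`, or a matrix with that many
#'   columns.
#' @return output vector (or matrix of row outputs).
#' @export
ffn_apply <- function(spec, params, x) {
  stopifnot(inherits(spec, "ffn_spec"))
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != spec$widths[1L]) {
    stop(sprintf("layer 1 expects input width %d, got %d",
                 spec$widths[1L], ncol(X)))
  }
  for (l in seq_len(spec$L)) {
    W <- params[[paste0("W", l)]]
    if (is.null(W) || nrow(W) != spec$widths[l] ||
        ncol(W) != spec$widths[l + 1L]) {
      stop(sprintf("weight matrix for layer %d has the wrong shape", l))
    }
  }
  out <- ffn_forward(spec, params, X)
  if (vec_in) drop(out) else out
}

#' Evaluate the neural impulse response for one event
#'
#' Concatenates the inputs the constraint set admits (delay `d`, onset time
#' `t`, impulse vector `xp`) and maps them through the IRF network to an
#' S x (J+1) matrix of convolution weights. Under causal masking the zero
#' matrix is returned whenever `d < 0`; delay 0 counts as past-and-present
#' and is retained. Under the homoscedasticity constraint only the location
#' row is produced by the network and the remaining rows are 0.
#'
#' @param d signed delay in seconds.
#' @param t event onset time in seconds (ignored when `stationary`).
#' @param xp impulse vector of length J (ignored entries per
#'   `linear_predictors`).
#' @param spec an [ffn_spec()] whose input width matches the admitted inputs
#'   and whose output width is `S_net * (J+1)`.
#' @param params network parameters.
#' @param S number of response-distribution parameters.
#' @param J impulse dimension.
#' @param causal logical; zero the output for negative delays.
#' @param stationary logical; exclude `t` from the inputs.
#' @param linear_idx integer indices of impulse dimensions excluded from the
#'   network inputs (their effect stays linear through the convolution).
#' @param homoscedastic logical; only the location row is free.
#' @return numeric S x (J+1) matrix.
#' @export
irf_apply <- function(d, t, xp, spec, params, S, J, causal = TRUE,
                      stationary = FALSE, linear_idx = integer(0),
                      homoscedastic = FALSE) {
  stopifnot(length(xp) == J)
  if (any(linear_idx > J | linear_idx < 1)) {
    stop("linear constraint names an impulse dimension that is not present")
  }
  S_net <- if (homoscedastic) 1L else S
  if (causal && d < 0) return(matrix(0, S, J + 1L))
  x_in <- c(d, if (!stationary) t, if (J) xp[setdiff(seq_len(J), linear_idx)])
  out <- ffn_apply(spec, params, x_in)
  if (length(out) != S_net * (J + 1L)) {
    stop("IRF network output width does not match S x (J+1)")
  }
  G <- matrix(0, S, J + 1L)
  G[seq_len(S_net), ] <- matrix(out, S_net, J + 1L)
  G
}

#' Mixed-effects parameter store
#'
#' Holds the fixed parameter vector `v0` and the random-effects matrix
#' `V_mat` realizing `v = v0 + V_mat z` for an indicator vector `z` over
#' random-effect levels. Columns are organized in blocks per grouping factor
#' (`grouping_map`), and only blocks named in `ranef_scope` may be nonzero.
#'
#' @param v0 numeric fixed parameter vector of length V.
#' @param V_mat V x Z random-effects matrix (defaults to all zeros with
#'   `Z = sum of mapped levels`).
#' @param grouping_map named list: for each grouping factor, the integer
#'   column indices of `V_mat` belonging to its levels.
#' @param ranef_scope character vector of parameter blocks admitting random
#'   variation (informational; rows outside it must be 0).
#' @return object of class `parameter_store`.
#' @export
parameter_store <- function(v0, V_mat = NULL, grouping_map = list(),
                            ranef_scope = c("s0", "b")) {
  Z <- sum(lengths(grouping_map))
  if (is.null(V_mat)) V_mat <- matrix(0, length(v0), Z)
  stopifnot(nrow(V_mat) == length(v0))
  cols <- sort(unlist(grouping_map, use.names = FALSE))
  if (length(cols) && !identical(cols, seq_len(ncol(V_mat)))) {
    stop("grouping_map must partition the columns of V_mat")
  }
  structure(list(v0 = v0, V_mat = V_mat, grouping_map = grouping_map,
                 ranef_scope = ranef_scope),
            class = "parameter_store")
}

#' Compose effective parameters from fixed and random parts
#'
#' `v = v0 + V_mat %*% z`, equivalent to indexing and summing the random
#' deviations of every level active in `z`.
#'
#' @param store a [parameter_store()] (or a plain list with `v0`, `V_mat`).
#' @param z binary indicator vector over random-effect levels, at most one
#'   active level per grouping factor.
#' @return effective parameter vector.
#' @export
compose_params <- function(store, z) {
  if (length(z) != ncol(store$V_mat)) {
    stop(sprintf("z has length %d but V_mat has %d columns",
                 length(z), ncol(store$V_mat)))
  }
  for (f in names(store$grouping_map)) {
    if (sum(z[store$grouping_map[[f]]] != 0) > 1L) {
      stop(sprintf("more than one active level for grouping factor '%s'", f))
    }
  }
  drop(store$v0 + store$V_mat %*% z)
}

#' Zero-sum projection of random effects
#'
#' Within each grouping factor's column block, removes the row mean so the
#' deviations across the factor's levels sum to 0 in every parameter row.
#' The projection is idempotent.
#'
#' @param V_mat V x Z random-effects matrix.
#' @param grouping_map named list of column-index blocks (defaults to one
#'   block spanning all columns).
#' @return centered matrix of the same shape.
#' @export
center_ranef <- function(V_mat, grouping_map = list(all = seq_len(ncol(V_mat)))) {
  for (cols in grouping_map) {
    if (length(cols) < 1L) next
    V_mat[, cols] <- V_mat[, cols, drop = FALSE] -
      rowMeans(V_mat[, cols, drop = FALSE])
  }
  V_mat
}
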