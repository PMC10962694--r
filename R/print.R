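#' @export
print.cdrnn_fit <- function(x, ...) {
  spec <- x$spec
  cat("Continuous-time deconvolutional regression network\n")
  cat(sprintf("  predictors: %s\n", paste(spec$predictors, collapse = ", ")))
  cat(sprintf("  impulse response: %s%s, horizon %g s%s\n",
              if (spec$irf == "dirac") "dirac (discrete-time reduction)"
              else paste0("feedforward [", paste(spec$hidden, collapse = "x"),
                          "]"),
              if (spec$causal) ", causal" else "",
              spec$d_max,
              if (spec$nonstationary) "" else ", stationary"))
  cat(sprintf("  response: %s ~ %s(%s)\n", spec$response, spec$family,
              if (spec$heteroscedastic) "mu, sigma" else "mu; constant sigma"))
  if (length(spec$linear_predictors)) {
    cat(sprintf("  linear effects: %s\n",
                paste(spec$linear_predictors, collapse = ", ")))
  }
  if (length(spec$groups)) {
    cat(sprintf("  random effects by: %s (%s)\n",
                paste(spec$groups, collapse = ", "),
                paste(spec$ranef_blocks, collapse = ", ")))
  }
  n_ep <- nrow(x$history)
  cat(sprintf("  trained %d epochs; final mean log likelihood %.4f%s\n",
              n_ep, x$history$loglik[n_ep],
              if (x$converged) sprintf(" (time-loss criterion fired at %d)",
                                       x$convergence_epoch)
              else " (criterion did not fire)"))
  invisible(x)
}

#' @export
print.cdrnn_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d deconvolutional regression networks\n",
              length(x$members)))
  cat(sprintf("  member seeds: %s\n", paste(x$seeds, collapse = ", ")))
  print(x$members[[1L]])
  invisible(x)
}
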