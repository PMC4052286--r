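# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the caller's
#' RNG state, so seeded package internals never perturb user-level randomness.
#' With `seed = NULL` the code runs under the current RNG state.
#' @noRd
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  ge <- globalenv()
  old <- if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
    get(".Random.seed", envir = ge)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
        rm(".Random.seed", envir = ge)
      }
    } else {
      assign(".Random.seed", old, envir = ge)
    }
  })
  set.seed(seed)
  force(code)
}

# Central-difference Hessian from an analytic gradient function.
# Accuracy O(h^2); adequate for observed-information SEs at these scales.
hessian_from_grad <- function(gr, theta, h = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    step <- h * max(1, abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- tp[j] + step
    tm[j] <- tm[j] - step
    H[, j] <- (gr(tp) - gr(tm)) / (2 * step)
  }
  (H + t(H)) / 2
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
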