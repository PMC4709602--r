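#' Random-walk-with-restart parameters
#'
#' Bundles the tunable parameters of the heterogeneous-network walk.
#'
#' @param delta Restart probability in (0, 1]: at every step the walker
#'   returns to the initial distribution with probability `delta`.
#'   Default 0.3.
#' @param beta Layer weight in (0, 1): fraction of initial probability
#'   mass placed on the query lncRNA; `1 - beta` is spread over its known
#'   partner proteins. `beta = 0.5` weights the two layers equally.
#' @param gamma Jump probability in (0, 1): probability of crossing
#'   between the protein and lncRNA layers along a known interaction
#'   edge, for nodes that have such an edge. Default 0.5.
#' @param tol Convergence tolerance on the L1 change between successive
#'   probability vectors. Default `1e-10`.
#' @param max_iter Iteration cap. Default 10000, far above the
#'   contraction bound `log(tol) / log(1 - delta)` for the defaults.
#'
#' @return An object of class `rwr_params` (a named list).
#' @examples
#' rwr_params()
#' rwr_params(delta = 0.5)
#' @export
rwr_params <- function(delta = 0.3, beta = 0.5, gamma = 0.5,
                       tol = 1e-10, max_iter = 10000L) {
  .check_prob(delta, "delta", hi_open = FALSE)
  .check_prob(beta, "beta")
  .check_prob(gamma, "gamma")
  .check_scalar_number(tol, "tol")
  if (tol <= 0) abort("`tol` must be > 0")
  .check_scalar_number(max_iter, "max_iter")
  if (max_iter < 1) abort("`max_iter` must be >= 1")
  structure(
    list(delta = delta, beta = beta, gamma = gamma,
         tol = tol, max_iter = as.integer(max_iter)),
    class = "rwr_params"
  )
}

#' @export
print.rwr_params <- function(x, ...) {
  cat("Random walk with restart parameters\n")
  cat(sprintf("  restart probability (delta): %g\n", x$delta))
  cat(sprintf("  layer weight (beta):         %g\n", x$beta))
  cat(sprintf("  jump probability (gamma):    %g\n", x$gamma))
  cat(sprintf("  tolerance: %g, max iterations: %d\n", x$tol, x$max_iter))
  invisible(x)
}
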