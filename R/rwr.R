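# Random walk with restart: power iteration of
#   Y_{t+1} = (1 - delta) W' Y_t + delta Y_0
# to its fixed point, and ranking of candidate proteins.

# Core iteration shared by the single-query and batched paths. Y0 is a
# column matrix of start distributions; all columns are iterated together
# (the map is linear, so this equals iterating each column separately).
.propagate_core <- function(Wt, Y0, delta, tol, max_iter) {
  Y <- Y0
  d <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Y_new <- (1 - delta) * (Wt %*% Y) + delta * Y0
    d <- max(colSums(abs(Y_new - Y)))
    Y <- Y_new
    if (d < tol) break
  }
  list(Y = Y, iterations = it, converged = d < tol, final_delta = d)
}

#' Propagate a start distribution to its fixed point
#'
#' Iterates `Y_{t+1} = (1 - delta) t(W) Y_t + delta Y_0` from `Y_0` until
#' the L1 change between successive iterates drops below `params$tol`
#' (default `1e-10`) or `params$max_iter` is reached. For
#' `delta` in (0, 1] the map is a contraction with factor `1 - delta`, so
#' convergence is guaranteed; with `delta = 1` the walk collapses to the
#' restart distribution after one step. Non-convergence at the iteration
#' cap is reported via the `converged` flag, not an error.
#'
#' @param transition A `transition_matrix` from
#'   [build_transition_matrix()], or a plain row-stochastic matrix.
#' @param y0 A `probability_vector` from [build_initial_vector()], or a
#'   numeric vector of matching length.
#' @param params [rwr_params()].
#' @return An object of class `rwr_propagation`: list with the stationary
#'   vector `y`, its protein/lncRNA partitions `u` and `v` (when the
#'   partition is known), `iterations`, `converged` and `final_delta`.
#' @export
propagate <- function(transition, y0, params = rwr_params()) {
  stopifnot(inherits(params, "rwr_params"))
  if (inherits(transition, "transition_matrix")) {
    W <- transition$W
    m <- transition$m
  } else {
    W <- as.matrix(transition)
    m <- NA_integer_
  }
  if (inherits(y0, "probability_vector")) {
    y0v <- c(y0$u, y0$v)
    m <- length(y0$u)
  } else {
    y0v <- as.numeric(y0)
  }
  if (length(y0v) != nrow(W)) {
    abort(sprintf("y0 has length %d but W is %dx%d",
                  length(y0v), nrow(W), ncol(W)))
  }
  res <- .propagate_core(t(W), matrix(y0v, ncol = 1L),
                         params$delta, params$tol, params$max_iter)
  y <- setNames(as.numeric(res$Y), rownames(W))
  structure(
    list(y = y,
         u = if (!is.na(m)) y[seq_len(m)] else NULL,
         v = if (!is.na(m)) y[-seq_len(m)] else NULL,
         iterations = res$iterations,
         converged = res$converged,
         final_delta = res$final_delta,
         params = params),
    class = "rwr_propagation"
  )
}

#' @export
print.rwr_propagation <- function(x, ...) {
  cat(sprintf("RWR propagation: %d iterations, %s (final L1 change %.3g)\n",
              x$iterations,
              if (x$converged) "converged" else "NOT converged",
              x$final_delta))
  invisible(x)
}

#' Rank candidate proteins for a query lncRNA
#'
#' Candidates are all proteins not already known to interact with the
#' query (`I(. , query) = 0`); they are scored by their entries in the
#' protein partition of the stationary vector and sorted by descending
#' score, ties broken by lexicographic protein id so output is
#' deterministic.
#'
#' @param propagation An `rwr_propagation` computed from the query's
#'   initial vector.
#' @param interaction_matrix The binary matrix the walk was built from.
#' @param query lncRNA id or 1-based column index.
#' @return A tibble with columns `query`, `protein`, `score`, `rank`
#'   (1-based, consecutive).
#' @export
rank_candidates <- function(propagation, interaction_matrix, query) {
  stopifnot(inherits(propagation, "rwr_propagation"))
  I <- interaction_matrix
  if (is.null(propagation$u)) {
    abort("propagation does not carry a protein partition; propagate a probability_vector")
  }
  q <- .resolve_query(query, I)
  cand <- which(I[, q] == 0)
  ids <- rownames(I)[cand]
  sc <- unname(propagation$u[cand])
  o <- .rank_order(sc, ids)
  tibble(query = colnames(I)[q],
         protein = ids[o],
         score = sc[o],
         rank = seq_along(o))
}

#' Protein-layer-only random walk with restart (comparison baseline)
#'
#' Standard RWR restricted to the PPI layer: the transition matrix is the
#' row-normalized SP' and the walker restarts to the uniform distribution
#' over the seed proteins. Used as a single-layer baseline against the
#' heterogeneous-network walk.
#'
#' @param sp Normalized PPI matrix from [normalize_ppi()].
#' @param seeds Protein ids or 1-based indices; at least one required.
#' @param delta Restart probability in (0, 1].
#' @param tol,max_iter Convergence controls as in [rwr_params()].
#' @return A named numeric vector of stationary scores over proteins.
#' @export
rwr_protein_baseline <- function(sp, seeds, delta = 0.3,
                                 tol = 1e-10, max_iter = 10000L) {
  .check_prob(delta, "delta", hi_open = FALSE)
  if (!length(seeds)) abort("at least one seed protein is required")
  if (is.character(seeds)) {
    idx <- match(seeds, rownames(sp))
    if (anyNA(idx)) {
      abort(sprintf("unknown seed protein: %s", seeds[which(is.na(idx))[1L]]))
    }
  } else {
    idx <- as.integer(seeds)
    if (any(idx < 1L | idx > nrow(sp))) abort("seed index out of range")
  }
  m <- nrow(sp)
  rs <- rowSums(sp)
  Tm <- matrix(0, m, m, dimnames = dimnames(sp))
  nz <- rs > 0
  Tm[nz, ] <- sp[nz, , drop = FALSE] / rs[nz]
  y0 <- numeric(m)
  y0[idx] <- 1 / length(idx)
  res <- .propagate_core(t(Tm), matrix(y0, ncol = 1L), delta, tol, max_iter)
  setNames(as.numeric(res$Y), rownames(sp))
}
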