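# Heterogeneous-network assembly: the binary interaction matrix I, the
# block transition matrix W and the initial probability vector Y0.

#' Binary lncRNA-protein interaction matrix
#'
#' Builds the `m x n` adjacency matrix I with `I(i, j) = 1` when protein
#' `i` is known to interact with lncRNA `j`. Rows follow
#' `registry$protein_ids`, columns `registry$lncrna_ids`.
#'
#' @param interactions A tibble from [read_interactions()].
#' @param registry A [node_registry()]; every id in `interactions` must
#'   be registered.
#' @return An integer matrix of 0/1 with protein/lncRNA dimnames.
#' @export
build_interaction_matrix <- function(interactions, registry) {
  stopifnot(inherits(registry, "node_registry"))
  bad_p <- setdiff(interactions$protein, registry$protein_ids)
  if (length(bad_p)) abort(sprintf("protein id not in registry: %s", bad_p[1L]))
  bad_l <- setdiff(interactions$lncrna, registry$lncrna_ids)
  if (length(bad_l)) abort(sprintf("lncRNA id not in registry: %s", bad_l[1L]))
  I <- matrix(0L, length(registry$protein_ids), length(registry$lncrna_ids),
              dimnames = list(registry$protein_ids, registry$lncrna_ids))
  if (nrow(interactions)) {
    I[cbind(interactions$protein, interactions$lncrna)] <- 1L
  }
  I
}

#' Block transition matrix of the heterogeneous network
#'
#' Assembles the `(m + n) x (m + n)` row-stochastic transition matrix
#' \deqn{W = \begin{pmatrix} W_P & W_{PL} \\ W_{LP} & W_L \end{pmatrix}}
#' with proteins indexed first. Within-layer rows are the row-normalized
#' similarity matrices; a node that also has a cross-layer interaction
#' edge keeps probability `1 - gamma` within its layer and sends `gamma`
#' across, spread uniformly over its interaction partners. A node with no
#' cross edge keeps all its mass within the layer; a node with a cross
#' edge but no within-layer neighbor sends its entire mass across (the
#' row stays stochastic). Nodes with no edges at all get an all-zero row:
#' the restart term of the walk still injects mass there, but they emit
#' none.
#'
#' @param sl lncRNA similarity matrix from [expression_similarity()]
#'   (`n x n`).
#' @param sp Normalized PPI matrix from [normalize_ppi()] (`m x m`).
#' @param interaction_matrix Binary `m x n` matrix from
#'   [build_interaction_matrix()].
#' @param gamma Jump probability in (0, 1).
#' @return An object of class `transition_matrix`: a list with the
#'   assembled matrix `W`, the blocks `W_P`, `W_L`, `W_PL`, `W_LP`, the
#'   `gamma` used, and the layer sizes `m`, `n`.
#' @export
build_transition_matrix <- function(sl, sp, interaction_matrix, gamma = 0.5) {
  I <- interaction_matrix
  m <- nrow(sp); n <- nrow(sl)
  if (ncol(sp) != m || ncol(sl) != n || nrow(I) != m || ncol(I) != n) {
    abort(sprintf(
      "dimension mismatch: SP' is %dx%d, SL is %dx%d, I is %dx%d",
      nrow(sp), ncol(sp), nrow(sl), ncol(sl), nrow(I), ncol(I)))
  }
  .check_prob(gamma, "gamma")

  p_deg <- rowSums(I)   # lncRNA partners per protein
  l_deg <- colSums(I)   # protein partners per lncRNA
  sp_rs <- rowSums(sp)
  sl_rs <- rowSums(sl)

  # protein -> protein: row-normalized SP', scaled by (1 - gamma) for
  # proteins that also have a cross edge
  W_P <- matrix(0, m, m, dimnames = dimnames(sp))
  nz <- sp_rs > 0
  W_P[nz, ] <- sp[nz, , drop = FALSE] / sp_rs[nz]
  W_P <- W_P * ifelse(p_deg > 0, 1 - gamma, 1)

  # protein -> lncRNA: gamma spread uniformly over the protein's lncRNA
  # partners; a protein with partners but no PPI neighbor sends all its
  # mass across
  W_PL <- matrix(0, m, n, dimnames = list(rownames(sp), rownames(sl)))
  cross_p <- p_deg > 0
  if (any(cross_p)) {
    g_p <- ifelse(sp_rs > 0, gamma, 1)
    W_PL[cross_p, ] <- (I[cross_p, , drop = FALSE] / p_deg[cross_p]) *
      g_p[cross_p]
  }

  # lncRNA -> lncRNA
  W_L <- matrix(0, n, n, dimnames = dimnames(sl))
  nzl <- sl_rs > 0
  W_L[nzl, ] <- sl[nzl, , drop = FALSE] / sl_rs[nzl]
  W_L <- W_L * ifelse(l_deg > 0, 1 - gamma, 1)

  # lncRNA -> protein: gamma spread uniformly over the lncRNA's protein
  # partners (the count of proteins interacting with the lncRNA)
  W_LP <- matrix(0, n, m, dimnames = list(rownames(sl), rownames(sp)))
  cross_l <- l_deg > 0
  if (any(cross_l)) {
    g_l <- ifelse(sl_rs > 0, gamma, 1)
    W_LP[cross_l, ] <- (t(I)[cross_l, , drop = FALSE] / l_deg[cross_l]) *
      g_l[cross_l]
  }

  W <- rbind(cbind(W_P, W_PL), cbind(W_LP, W_L))
  structure(
    list(W = W, W_P = W_P, W_L = W_L, W_PL = W_PL, W_LP = W_LP,
         gamma = gamma, m = m, n = n),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Transition matrix: %d proteins + %d lncRNAs (gamma = %g)\n",
              x$m, x$n, x$gamma))
  invisible(x)
}

#' Dump the assembled transition matrix in MatrixMarket format
#'
#' Debugging aid: writes `W` as a sparse MatrixMarket file for inspection
#' with external tools.
#'
#' @param transition A `transition_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(transition, path) {
  stopifnot(inherits(transition, "transition_matrix"))
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    abort("the Matrix package is required for write_transition_matrix()")
  }
  Matrix::writeMM(Matrix::Matrix(transition$W, sparse = TRUE, doDiag = FALSE),
                  path)
  invisible(path)
}

#' Initial probability vector for a query lncRNA
#'
#' The query lncRNA receives probability `beta` in the lncRNA partition;
#' its known partner proteins share `1 - beta` uniformly in the protein
#' partition, so the vector sums to 1. A query with no known partner
#' protein gets its full unit mass on the lncRNA entry.
#'
#' @param query lncRNA id (column name of `interaction_matrix`) or
#'   1-based column index.
#' @param interaction_matrix Binary `m x n` matrix from
#'   [build_interaction_matrix()].
#' @param beta Layer weight in (0, 1).
#' @return An object of class `probability_vector`: a list with named
#'   numeric vectors `u` (proteins) and `v` (lncRNAs).
#' @export
build_initial_vector <- function(query, interaction_matrix, beta = 0.5) {
  I <- interaction_matrix
  .check_prob(beta, "beta")
  q <- .resolve_query(query, I)
  m <- nrow(I); n <- ncol(I)
  u <- setNames(numeric(m), rownames(I))
  v <- setNames(numeric(n), colnames(I))
  seeds <- which(I[, q] == 1)
  if (length(seeds)) {
    u[seeds] <- (1 - beta) / length(seeds)
    v[q] <- beta
  } else {
    v[q] <- 1
  }
  structure(list(u = u, v = v), class = "probability_vector")
}

#' @export
print.probability_vector <- function(x, ...) {
  cat(sprintf(
    "Probability vector: %d proteins (sum %.4g) + %d lncRNAs (sum %.4g)\n",
    length(x$u), sum(x$u), length(x$v), sum(x$v)))
  invisible(x)
}

# resolve a query given as id or 1-based lncRNA index
.resolve_query <- function(query, I) {
  if (is.character(query)) {
    q <- match(query, colnames(I))
    if (is.na(q)) abort(sprintf("unknown query lncRNA: %s", query))
  } else {
    q <- as.integer(query)
    if (is.na(q) || q < 1L || q > ncol(I)) {
      abort(sprintf("query index %s out of range 1..%d", query, ncol(I)))
    }
  }
  q
}
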