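# The two intra-layer similarity matrices: |Pearson correlation| between
# lncRNA expression profiles, and symmetric square-root normalization of
# the weighted PPI matrix.

#' lncRNA expression-similarity matrix
#'
#' Computes the absolute Pearson correlation between every pair of lncRNA
#' expression profiles. The diagonal is set to 0: the walk has no
#' self-loops, an edge exists only between distinct lncRNAs with strictly
#' positive similarity. Profiles with zero variance have an undefined
#' correlation; such lncRNAs get similarity 0 to all others, with a
#' warning.
#'
#' @param expression A tibble from [read_expression()]: first column
#'   `lncrna`, remaining numeric columns one per condition (at least 2
#'   conditions required).
#' @param registry Optional [node_registry()]. When supplied, the result
#'   is expanded to cover `registry$lncrna_ids` in registry order;
#'   lncRNAs without an expression profile get all-zero rows (warned).
#' @return A symmetric numeric matrix with entries in `[0, 1]`, zero
#'   diagonal, and lncRNA ids as dimnames.
#' @examples
#' expr <- tibble::tibble(lncrna = c("L1", "L2"),
#'                        t1 = c(1, 3), t2 = c(2, 2), t3 = c(3, 1))
#' expression_similarity(expr)  # |PCC| = 1 despite opposite slopes
#' @export
expression_similarity <- function(expression, registry = NULL) {
  stopifnot(names(expression)[1L] == "lncrna")
  ids <- expression$lncrna
  x <- as.matrix(expression[-1L])
  if (ncol(x) < 2L) abort("expression profiles need at least 2 conditions")
  if (!is.numeric(x)) abort("expression values must be numeric")
  if (anyNA(x)) abort("expression values must not contain missing values")
  storage.mode(x) <- "double"
  rownames(x) <- ids

  sds <- apply(x, 1L, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warn(sprintf(
      "expression_similarity: %d zero-variance profile(s) set to similarity 0: %s",
      sum(flat), paste(ids[flat], collapse = ", ")))
  }
  sl <- matrix(0, nrow(x), nrow(x), dimnames = list(ids, ids))
  if (any(!flat)) {
    cc <- abs(cor(t(x[!flat, , drop = FALSE])))
    sl[!flat, !flat] <- cc
  }
  diag(sl) <- 0

  if (!is.null(registry)) {
    all_ids <- registry$lncrna_ids
    missing <- setdiff(ids, all_ids)
    if (length(missing)) {
      abort(sprintf("lncRNA id not in registry: %s", missing[1L]))
    }
    absent <- setdiff(all_ids, ids)
    if (length(absent)) {
      warn(sprintf(
        "expression_similarity: %d lncRNA(s) without expression profile get similarity 0: %s",
        length(absent), paste(absent, collapse = ", ")))
    }
    out <- matrix(0, length(all_ids), length(all_ids),
                  dimnames = list(all_ids, all_ids))
    out[ids, ids] <- sl
    sl <- out
  }
  sl
}

#' Symmetrically normalized PPI matrix
#'
#' Assembles the symmetric weighted adjacency matrix SP from the edge
#' table (zero diagonal) and normalizes it as
#' `SP'(i, j) = SP(i, j) / sqrt(M(i, i) * M(j, j))`, where `M(j, j)` is
#' the sum of row `j` of SP. Rows with zero weighted degree stay all
#' zero. For an unweighted graph this reduces to `1 / sqrt(d_i * d_j)`
#' with `d` the degree, so entries lie in `[0, 1]` and SP' is symmetric.
#'
#' @param ppi A tibble from [read_ppi()] (columns `protein_a`,
#'   `protein_b`, `score`).
#' @param registry A [node_registry()]; all proteins in `ppi` must be
#'   registered. The matrix covers every registered protein, so proteins
#'   without PPI edges contribute all-zero rows.
#' @return A symmetric numeric `m x m` matrix with protein ids as
#'   dimnames.
#' @export
normalize_ppi <- function(ppi, registry) {
  stopifnot(inherits(registry, "node_registry"))
  ids <- registry$protein_ids
  unknown <- setdiff(unique(c(ppi$protein_a, ppi$protein_b)), ids)
  if (length(unknown)) {
    abort(sprintf("protein id not in registry: %s", unknown[1L]))
  }
  m <- length(ids)
  sp <- matrix(0, m, m, dimnames = list(ids, ids))
  if (nrow(ppi)) {
    sp[cbind(ppi$protein_a, ppi$protein_b)] <- ppi$score
    sp[cbind(ppi$protein_b, ppi$protein_a)] <- ppi$score
  }
  diag(sp) <- 0
  rs <- rowSums(sp)
  denom <- sqrt(outer(rs, rs))
  out <- matrix(0, m, m, dimnames = list(ids, ids))
  nz <- denom > 0
  out[nz] <- sp[nz] / denom[nz]
  out
}
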