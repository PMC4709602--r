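# User-facing front end: assemble the heterogeneous network once, then
# score and rank candidate proteins for query lncRNAs.

#' Assemble the heterogeneous lncRNA-protein network
#'
#' Builds every static piece of the model from the three input tables:
#' the node registry, the expression-similarity matrix, the normalized
#' PPI matrix, the binary interaction matrix and the block transition
#' matrix.
#'
#' @param interactions Tibble of known interactions
#'   ([read_interactions()]).
#' @param expression Tibble of expression profiles ([read_expression()]).
#' @param ppi Tibble of weighted PPI edges ([read_ppi()]).
#' @param params [rwr_params()].
#' @param proteins,lncrnas Extra node ids to register (see
#'   [node_registry()]).
#' @return An object of class `lpihn_network` bundling `registry`, `sl`,
#'   `sp`, `I`, `transition` and `params`.
#' @examples
#' fx <- degenerate_fixtures()$tiny_2x2
#' net <- lpihn_network(fx$interactions, fx$expression, fx$ppi)
#' predict_partners(net, "L1")
#' @export
lpihn_network <- function(interactions, expression, ppi,
                          params = rwr_params(),
                          proteins = character(), lncrnas = character()) {
  stopifnot(inherits(params, "rwr_params"))
  registry <- node_registry(interactions, ppi, expression,
                            proteins = proteins, lncrnas = lncrnas)
  sl <- expression_similarity(expression, registry)
  sp <- normalize_ppi(ppi, registry)
  I <- build_interaction_matrix(interactions, registry)
  transition <- build_transition_matrix(sl, sp, I, params$gamma)
  structure(
    list(registry = registry, sl = sl, sp = sp, I = I,
         transition = transition, params = params),
    class = "lpihn_network"
  )
}

#' @export
print.lpihn_network <- function(x, ...) {
  cat(sprintf(
    "Heterogeneous lncRNA-protein network: %d proteins, %d lncRNAs, %d known interactions\n",
    nrow(x$I), ncol(x$I), sum(x$I)))
  print(x$params)
  invisible(x)
}

#' Rank candidate proteins for query lncRNAs
#'
#' Runs the random walk with restart once per query and returns the
#' ranked candidate proteins (known partners excluded). Each query is
#' scored independently: the walker restarts to the query lncRNA (weight
#' `beta`) and its known partner proteins (weight `1 - beta`, shared
#' uniformly). Queries with no known partner are allowed; their full
#' restart mass sits on the lncRNA node.
#'
#' @param network An [lpihn_network()].
#' @param queries Character vector of query lncRNA ids; default all
#'   registered lncRNAs.
#' @param top_k Predictions ranked within `top_k` are flagged in the
#'   `in_top_k` column (default 10).
#' @return A tibble with columns `query`, `protein`, `score`, `rank`,
#'   `in_top_k`, grouped consecutively by query.
#' @export
predict_partners <- function(network, queries = NULL, top_k = 10L) {
  stopifnot(inherits(network, "lpihn_network"))
  queries <- queries %||% network$registry$lncrna_ids
  missing <- setdiff(queries, network$registry$lncrna_ids)
  if (length(missing)) {
    abort(sprintf("unknown query lncRNA id(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- purrr::map(queries, function(q) {
    y0 <- build_initial_vector(q, network$I, network$params$beta)
    pr <- propagate(network$transition, y0, network$params)
    rank_candidates(pr, network$I, q)
  })
  dplyr::bind_rows(out) |>
    mutate(in_top_k = .data$rank <= top_k)
}
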