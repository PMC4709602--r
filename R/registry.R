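#' Node registry: stable index orderings for proteins and lncRNAs
#'
#' Collects the union of protein and lncRNA identifiers appearing in the
#' input tables and fixes their matrix index order by sorting
#' lexicographically (C locale). Every matrix in the pipeline uses these
#' orderings, so indices are reproducible across runs given the same
#' inputs.
#'
#' @param interactions Optional tibble from [read_interactions()]
#'   (columns `lncrna`, `protein`).
#' @param ppi Optional tibble from [read_ppi()] (columns `protein_a`,
#'   `protein_b`, `score`).
#' @param expression Optional tibble from [read_expression()] (first
#'   column `lncrna`).
#' @param proteins,lncrnas Extra identifiers to register explicitly, e.g.
#'   nodes known to exist but absent from every edge table.
#' @return An object of class `node_registry`: a list with character
#'   vectors `protein_ids` and `lncrna_ids`, each sorted and duplicate
#'   free.
#' @examples
#' node_registry(proteins = c("P2", "P1"), lncrnas = "L1")
#' @export
node_registry <- function(interactions = NULL, ppi = NULL, expression = NULL,
                          proteins = character(), lncrnas = character()) {
  if (!is.null(interactions)) {
    proteins <- c(proteins, interactions$protein)
    lncrnas <- c(lncrnas, interactions$lncrna)
  }
  if (!is.null(ppi)) {
    proteins <- c(proteins, ppi$protein_a, ppi$protein_b)
  }
  if (!is.null(expression)) {
    lncrnas <- c(lncrnas, expression$lncrna)
  }
  structure(
    list(protein_ids = sort(unique(proteins), method = "radix"),
         lncrna_ids = sort(unique(lncrnas), method = "radix")),
    class = "node_registry"
  )
}

#' @export
print.node_registry <- function(x, ...) {
  cat(sprintf("Node registry: %d proteins, %d lncRNAs\n",
              length(x$protein_ids), length(x$lncrna_ids)))
  invisible(x)
}
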