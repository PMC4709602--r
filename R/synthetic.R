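# Synthetic planted-structure data generator. Co-interaction groups of
# lncRNAs and proteins give the statistical structure the walk exploits:
# lncRNAs in a group share a latent expression profile (high within-group
# |PCC|), the group's proteins are densely connected with high PPI
# scores, and interactions fall inside the group except for a noise
# fraction.

#' Configuration of a synthetic scenario
#'
#' @param n_lncrnas,n_proteins Node counts. Defaults 60 and 40: small
#'   enough for a full LOOCV in seconds, large enough for stable AUC.
#' @param n_conditions Number of expression conditions (tissues/cell
#'   types); default 24.
#' @param n_groups Number of planted co-interaction groups; must not
#'   exceed either node count. Default 4.
#' @param within_group_expression_correlation Target Pearson correlation
#'   between profiles of lncRNAs in the same group, in (0, 1). Default
#'   0.8.
#' @param ppi_within_density,ppi_between_density Probability of a PPI
#'   edge within / between protein groups. Defaults 0.7 and 0.05.
#' @param ppi_within_score_range,ppi_between_score_range Uniform score
#'   ranges for within- and between-group PPI edges.
#' @param interactions_per_lncrna_mean Mean number of protein partners
#'   per lncRNA; partners are drawn as `1 + Poisson(mean - 1)`, capped at
#'   the available pool. Default 4.37, the average partner count observed
#'   in curated human lncRNA-protein interaction data.
#' @param noise_rate Probability that an interaction falls outside the
#'   lncRNA's group, in `[0, 1]`. Default 0.1.
#' @param seed Integer RNG seed; generation is bit-reproducible.
#' @return An object of class `scenario_config` (named list).
#' @export
scenario_config <- function(n_lncrnas = 60L, n_proteins = 40L,
                            n_conditions = 24L, n_groups = 4L,
                            within_group_expression_correlation = 0.8,
                            ppi_within_density = 0.7,
                            ppi_between_density = 0.05,
                            ppi_within_score_range = c(0.6, 1),
                            ppi_between_score_range = c(0.05, 0.3),
                            interactions_per_lncrna_mean = 4.37,
                            noise_rate = 0.1,
                            seed = 1L) {
  for (v in c("n_lncrnas", "n_proteins", "n_conditions", "n_groups")) {
    x <- get(v)
    if (!is.numeric(x) || length(x) != 1L || x < 1) {
      abort(sprintf("`%s` must be a positive count", v))
    }
  }
  if (n_conditions < 2) abort("`n_conditions` must be >= 2")
  if (n_groups > min(n_lncrnas, n_proteins)) {
    abort("`n_groups` must not exceed min(n_lncrnas, n_proteins)")
  }
  .check_prob(within_group_expression_correlation,
              "within_group_expression_correlation")
  .check_prob(ppi_within_density, "ppi_within_density",
              lo_open = FALSE, hi_open = FALSE)
  .check_prob(ppi_between_density, "ppi_between_density",
              lo_open = FALSE, hi_open = FALSE)
  .check_prob(noise_rate, "noise_rate", lo_open = FALSE, hi_open = FALSE)
  if (interactions_per_lncrna_mean < 1) {
    abort("`interactions_per_lncrna_mean` must be >= 1")
  }
  prots_per_group <- floor(n_proteins / n_groups)
  if (interactions_per_lncrna_mean > prots_per_group) {
    abort(sprintf(
      "infeasible config: mean degree %.2f exceeds the %d proteins per group",
      interactions_per_lncrna_mean, prots_per_group))
  }
  structure(
    list(n_lncrnas = as.integer(n_lncrnas),
         n_proteins = as.integer(n_proteins),
         n_conditions = as.integer(n_conditions),
         n_groups = as.integer(n_groups),
         within_group_expression_correlation = within_group_expression_correlation,
         ppi_within_density = ppi_within_density,
         ppi_between_density = ppi_between_density,
         ppi_within_score_range = ppi_within_score_range,
         ppi_between_score_range = ppi_between_score_range,
         interactions_per_lncrna_mean = interactions_per_lncrna_mean,
         noise_rate = noise_rate,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Generate a synthetic scenario with planted structure
#'
#' lncRNAs in the same group draw their expression profile as
#' `sqrt(rho) * latent + sqrt(1 - rho) * noise` around a shared latent
#' profile, so the expected within-group correlation is `rho`; proteins
#' in the same group are densely connected with high scores; each lncRNA
#' interacts with proteins of its own group except with probability
#' `noise_rate`. With `noise_rate = 0` the interaction matrix is
#' block-diagonal under group ordering.
#'
#' @param config A [scenario_config()].
#' @return A list with tibbles `expression`, `ppi`, `interactions` (valid
#'   inputs for the readers/writers and [lpihn_network()]) and `groups`
#'   (columns `id`, `type`, `group`), plus the `config` used.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- cfg$n_lncrnas; m <- cfg$n_proteins
    g <- cfg$n_groups; k <- cfg$n_conditions
    wid <- function(prefix, total) {
      sprintf(paste0(prefix, "%0", nchar(total), "d"), seq_len(total))
    }
    lnc_ids <- wid("L", n)
    prot_ids <- wid("P", m)
    lgrp <- sort(rep(seq_len(g), length.out = n))
    pgrp <- sort(rep(seq_len(g), length.out = m))

    # expression: shared latent profile per group plus independent noise
    rho <- cfg$within_group_expression_correlation
    latent <- matrix(rnorm(g * k), g, k)
    X <- sqrt(rho) * latent[lgrp, , drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
    expression <- dplyr::bind_cols(
      tibble(lncrna = lnc_ids),
      as_tibble(as.data.frame(X), .name_repair = "minimal") |>
        setNames(sprintf("tissue_%02d", seq_len(k)))
    )

    # PPI: dense high-score within groups, sparse low-score between
    pairs <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
    within <- pgrp[pairs[, 1L]] == pgrp[pairs[, 2L]]
    dens <- ifelse(within, cfg$ppi_within_density, cfg$ppi_between_density)
    keep <- runif(nrow(pairs)) < dens
    lo <- ifelse(within, cfg$ppi_within_score_range[1L],
                 cfg$ppi_between_score_range[1L])
    hi <- ifelse(within, cfg$ppi_within_score_range[2L],
                 cfg$ppi_between_score_range[2L])
    scores <- runif(nrow(pairs), lo, hi)
    ppi <- tibble(
      protein_a = prot_ids[pairs[keep, 1L]],
      protein_b = prot_ids[pairs[keep, 2L]],
      score = scores[keep]
    ) |>
      arrange(.data$protein_a, .data$protein_b)

    # interactions: degree 1 + Poisson, within-group except noise
    lambda <- cfg$interactions_per_lncrna_mean - 1
    edges <- vector("list", n)
    for (i in seq_len(n)) {
      own <- which(pgrp == lgrp[i])
      other <- which(pgrp != lgrp[i])
      deg <- min(1L + rpois(1L, lambda), m)
      n_in <- min(rbinom(1L, deg, 1 - cfg$noise_rate), length(own))
      n_out <- min(deg - n_in, length(other))
      partners <- c(.sample_ids(own, n_in), .sample_ids(other, n_out))
      edges[[i]] <- tibble(lncrna = lnc_ids[i], protein = prot_ids[partners])
    }
    interactions <- dplyr::bind_rows(edges) |>
      arrange(.data$lncrna, .data$protein)

    groups <- dplyr::bind_rows(
      tibble(id = lnc_ids, type = "lncrna", group = lgrp),
      tibble(id = prot_ids, type = "protein", group = pgrp)
    )
    list(expression = expression, ppi = ppi, interactions = interactions,
         groups = groups, config = cfg)
  })
}

#' Write a generated scenario to a directory
#'
#' Writes `interactions.tsv`, `expression.tsv`, `ppi.tsv` and
#' `groups.tsv` plus `config.json` recording the generating parameters.
#'
#' @param scenario The list returned by [generate_scenario()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactions(scenario$interactions, file.path(dir, "interactions.tsv"))
  write_expression(scenario$expression, file.path(dir, "expression.tsv"))
  write_ppi(scenario$ppi, file.path(dir, "ppi.tsv"))
  writeLines(c("# id\ttype\tgroup",
               paste(scenario$groups$id, scenario$groups$type,
                     scenario$groups$group, sep = "\t")),
             file.path(dir, "groups.tsv"))
  jsonlite::write_json(unclass(scenario$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Hand-checkable degenerate fixtures
#'
#' Tiny named datasets exercising the edge cases of the pipeline:
#' \describe{
#'   \item{tiny_2x2}{2 proteins, 2 lncRNAs, one interaction; its 4x4
#'     transition matrix can be verified entry by entry by hand.}
#'   \item{star_ppi}{a hub protein connected to three leaves with unit
#'     scores; normalization gives `1/sqrt(3)` on the spokes.}
#'   \item{zero_variance}{an lncRNA with a flat expression profile
#'     (undefined correlation, similarity forced to 0).}
#'   \item{isolated_protein}{a registered protein with no edges at all
#'     (all-zero transition row).}
#'   \item{single_partner}{an lncRNA with one known partner, excluded by
#'     the LOOCV >= 2 filter.}
#' }
#'
#' @return A named list; each element has tibbles `interactions`,
#'   `expression`, `ppi` and a character vector `extra_proteins` of ids
#'   to register explicitly.
#' @export
degenerate_fixtures <- function() {
  expr2 <- tibble(lncrna = c("L1", "L2"),
                  t1 = c(1, 2), t2 = c(2, 4), t3 = c(3, 6), t4 = c(4, 8))
  fx <- list(
    tiny_2x2 = list(
      interactions = tibble(lncrna = "L1", protein = "P1"),
      expression = expr2,
      ppi = tibble(protein_a = "P1", protein_b = "P2", score = 0.8),
      extra_proteins = character()
    ),
    star_ppi = list(
      interactions = tibble(lncrna = "L1", protein = "P1"),
      expression = expr2,
      ppi = tibble(protein_a = c("P1", "P1", "P1"),
                   protein_b = c("P2", "P3", "P4"),
                   score = c(1, 1, 1)),
      extra_proteins = character()
    ),
    zero_variance = list(
      interactions = tibble(lncrna = c("L1", "L2"), protein = c("P1", "P2")),
      expression = tibble(lncrna = c("L1", "L2", "L3"),
                          t1 = c(5, 1, 2), t2 = c(5, 2, 4),
                          t3 = c(5, 3, 6), t4 = c(5, 4, 8)),
      ppi = tibble(protein_a = "P1", protein_b = "P2", score = 0.8),
      extra_proteins = character()
    ),
    isolated_protein = list(
      interactions = tibble(lncrna = "L1", protein = "P1"),
      expression = expr2,
      ppi = tibble(protein_a = "P1", protein_b = "P2", score = 0.8),
      extra_proteins = "P9"
    ),
    single_partner = list(
      interactions = tibble(lncrna = c("L1", "L1", "L2"),
                            protein = c("P1", "P2", "P1")),
      expression = expr2,
      ppi = tibble(protein_a = "P1", protein_b = "P2", score = 0.8),
      extra_proteins = character()
    )
  )
  fx
}
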