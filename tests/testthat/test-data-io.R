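# Readers, writers and the node registry.

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("interaction reader deduplicates and validates", {
  p <- write_lines_tmp(c("L1\tP1", "L1\tP1", "L2\tP1"))
  expect_message(tab <- read_interactions(p), "1 duplicate")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$lncrna, c("L1", "L2"))

  p <- write_lines_tmp(c("L1"))
  expect_error(read_interactions(p), "line 1")

  p <- write_lines_tmp(c("# comment", "", "L1\tP1", "bad_line"))
  expect_error(read_interactions(p), "line 4")

  p <- write_lines_tmp(c("# only a comment"))
  expect_error(read_interactions(p), "no interaction records")

  # header row skipped on request; extra columns tolerated
  p <- write_lines_tmp(c("lncrna\tprotein", "L1\tP1\textra"))
  expect_equal(nrow(read_interactions(p, header = TRUE)), 1L)
})

test_that("expression reader drops bad rows and rejects duplicates", {
  p <- write_lines_tmp(c("lncrna\tt1\tt2\tt3",
                         "L1\t1\t2\t3",
                         "L2\t2\tNA\t6",
                         "L3\t5\t4\t3"))
  expect_warning(tab <- read_expression(p), "L2")
  expect_equal(tab$lncrna, c("L1", "L3"))
  expect_equal(tab$t3, c(3, 3))

  p <- write_lines_tmp(c("lncrna\tt1\tt2", "L1\t1\t2", "L1\t3\t4"))
  expect_error(read_expression(p), "duplicate lncRNA id.*L1")

  p <- write_lines_tmp(c("lncrna\tt1\tt2", "L1\t1"))
  expect_error(read_expression(p), "ragged")

  p <- write_lines_tmp(c("lncrna\tt1\tt2", "L1\tx\ty"))
  expect_error(expect_warning(read_expression(p)), "no usable")
})

test_that("ppi reader applies max-keep dedup and drops self-edges", {
  p <- write_lines_tmp(c("P1\tP2\t0.9", "P2\tP1\t0.7"))
  expect_message(tab <- read_ppi(p), "1 duplicate")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$score, 0.9)
  expect_equal(tab$protein_a, "P1")  # canonical order

  p <- write_lines_tmp(c("P1\tP1\t0.5", "P1\tP2\t0.3"))
  expect_warning(tab <- read_ppi(p), "self-edge")
  expect_equal(nrow(tab), 1L)

  p <- write_lines_tmp(c("P1\tP2\t-0.1"))
  expect_error(read_ppi(p), "negative")

  p <- write_lines_tmp(c("P1\tP2\tabc"))
  expect_error(read_ppi(p), "line 1")
})

test_that("write/read round trip reproduces the tables exactly", {
  scn <- generate_scenario(scenario_config(n_lncrnas = 8, n_proteins = 6,
                                           n_groups = 2,
                                           interactions_per_lncrna_mean = 2.5, seed = 7))
  d <- withr::local_tempdir()
  write_interactions(scn$interactions, file.path(d, "i.tsv"))
  write_expression(scn$expression, file.path(d, "e.tsv"))
  write_ppi(scn$ppi, file.path(d, "p.tsv"))
  expect_equal(read_interactions(file.path(d, "i.tsv")), scn$interactions)
  expect_equal(read_expression(file.path(d, "e.tsv")), scn$expression)
  expect_equal(read_ppi(file.path(d, "p.tsv")), scn$ppi)
})

test_that("node registry sorts ids and is deterministic", {
  ints <- tibble::tibble(lncrna = c("L2", "L1"), protein = c("P3", "P1"))
  ppi <- tibble::tibble(protein_a = "P2", protein_b = "P1", score = 1)
  expr <- tibble::tibble(lncrna = c("L9", "L1"), t1 = c(1, 2), t2 = c(3, 4))
  reg <- node_registry(ints, ppi, expr, proteins = "P0")
  expect_equal(reg$protein_ids, c("P0", "P1", "P2", "P3"))
  expect_equal(reg$lncrna_ids, c("L1", "L2", "L9"))
  expect_identical(reg, node_registry(ints, ppi, expr, proteins = "P0"))
})

test_that("prediction writer enforces rank and score structure", {
  ranked <- tibble::tibble(
    query = c("L1", "L1", "L2"),
    protein = c("P2", "P1", "P1"),
    score = c(0.9, 0.4, 0.7),
    rank = c(1L, 2L, 1L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(ranked, path)
  lines <- readLines(path)
  expect_equal(lines[1], "query_lncrna\tprotein_id\tscore\trank")
  expect_equal(length(lines), 4L)

  bad <- ranked
  bad$rank <- c(1L, 3L, 1L)
  expect_error(write_predictions(bad, path), "consecutive")
  bad <- ranked
  bad$score <- c(0.1, 0.4, 0.7)
  expect_error(write_predictions(bad, path), "non-increasing")
  expect_error(write_predictions(ranked[0, ], path), "at least one")
})
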