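# Readers and writers for the three TSV inputs and the prediction output.
# All readers skip blank lines and lines starting with "#". Parse failures
# report the offending 1-based line number of the file.

.read_data_lines <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    abort("`path` must be a single file path")
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a known lncRNA-protein interaction table
#'
#' Expects tab-separated lines `lncrna_id<TAB>protein_id`. Comment lines
#' starting with `#` and blank lines are skipped. Duplicate pairs are
#' collapsed to one, with a message reporting how many were dropped.
#'
#' @param path Path to the TSV file.
#' @param header If `TRUE`, the first non-comment line is a header row and
#'   is skipped. Default `FALSE`.
#' @return A tibble with columns `lncrna` and `protein`, one row per
#'   distinct interaction.
#' @seealso [write_interactions()], [read_expression()], [read_ppi()]
#' @export
read_interactions <- function(path, header = FALSE) {
  dat <- .read_data_lines(path)
  if (header && length(dat$lines)) {
    dat$lines <- dat$lines[-1L]
    dat$lineno <- dat$lineno[-1L]
  }
  if (!length(dat$lines)) abort(sprintf("no interaction records in %s", path))
  fields <- .split_fields(dat$lines)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    abort(sprintf(
      "parse error in %s at line %d: expected at least 2 tab-separated fields",
      path, dat$lineno[bad[1L]]))
  }
  lnc <- vapply(fields, `[[`, character(1), 1L)
  prot <- vapply(fields, `[[`, character(1), 2L)
  dup <- duplicated(paste(lnc, prot, sep = "\r"))
  if (any(dup)) {
    inform(sprintf("read_interactions: dropped %d duplicate pair(s)", sum(dup)))
  }
  tibble(lncrna = lnc[!dup], protein = prot[!dup])
}

#' Read an lncRNA expression matrix
#'
#' Expects a header row `lncrna<TAB><cond1>...<condK>` followed by one row
#' per lncRNA. Rows containing non-numeric or missing cells are dropped
#' with a warning naming the affected lncRNAs; duplicate lncRNA ids are an
#' error.
#'
#' @inheritParams read_interactions
#' @return A tibble whose first column `lncrna` holds the ids and whose
#'   remaining numeric columns are the conditions (tissues/cell types).
#' @export
read_expression <- function(path) {
  dat <- .read_data_lines(path)
  if (length(dat$lines) < 2L) {
    abort(sprintf("expression file %s needs a header row and at least one data row", path))
  }
  hdr <- .split_fields(dat$lines[1L])[[1L]]
  if (length(hdr) < 2L) {
    abort(sprintf("parse error in %s at line %d: header needs an id column and at least one condition",
                  path, dat$lineno[1L]))
  }
  conds <- hdr[-1L]
  k <- length(conds)
  fields <- .split_fields(dat$lines[-1L])
  lineno <- dat$lineno[-1L]
  bad <- which(lengths(fields) != k + 1L)
  if (length(bad)) {
    abort(sprintf("parse error in %s at line %d: %d fields, expected %d (ragged row)",
                  path, lineno[bad[1L]], lengths(fields)[bad[1L]], k + 1L))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate lncRNA id in %s: %s",
                  path, ids[duplicated(ids)][1L]))
  }
  vals <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(fields, `[`, -1L)))),
    nrow = length(ids), ncol = k, byrow = TRUE
  )
  usable <- !apply(is.na(vals), 1L, any)
  if (any(!usable)) {
    warn(sprintf("read_expression: dropped %d row(s) with missing or non-numeric values: %s",
                 sum(!usable), paste(ids[!usable], collapse = ", ")))
  }
  if (!any(usable)) abort(sprintf("no usable expression rows in %s", path))
  out <- as_tibble(as.data.frame(vals[usable, , drop = FALSE]),
                   .name_repair = "minimal")
  names(out) <- conds
  dplyr::bind_cols(tibble(lncrna = ids[usable]), out)
}

#' Read a weighted protein-protein interaction table
#'
#' Expects tab-separated lines `protein_a<TAB>protein_b<TAB>score` with
#' nonnegative scores. Self-edges are dropped with a warning; duplicate
#' unordered pairs are collapsed keeping the maximum score. Pairs are
#' returned in canonical order (`protein_a < protein_b` lexicographically).
#'
#' @inheritParams read_interactions
#' @return A tibble with columns `protein_a`, `protein_b`, `score`.
#' @export
read_ppi <- function(path, header = FALSE) {
  dat <- .read_data_lines(path)
  if (header && length(dat$lines)) {
    dat$lines <- dat$lines[-1L]
    dat$lineno <- dat$lineno[-1L]
  }
  if (!length(dat$lines)) abort(sprintf("no PPI records in %s", path))
  fields <- .split_fields(dat$lines)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(sprintf("parse error in %s at line %d: expected 3 tab-separated fields",
                  path, dat$lineno[bad[1L]]))
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(s)) {
    abort(sprintf("parse error in %s at line %d: score is not a number",
                  path, dat$lineno[which(is.na(s))[1L]]))
  }
  if (any(s < 0)) {
    abort(sprintf("negative PPI score in %s at line %d",
                  path, dat$lineno[which(s < 0)[1L]]))
  }
  self <- a == b
  if (any(self)) {
    warn(sprintf("read_ppi: dropped %d self-edge(s)", sum(self)))
    a <- a[!self]; b <- b[!self]; s <- s[!self]
  }
  if (!length(a)) abort(sprintf("no usable PPI records in %s", path))
  pa <- pmin(a, b)
  pb <- pmax(a, b)
  tab <- tibble(protein_a = pa, protein_b = pb, score = s)
  n_raw <- nrow(tab)
  tab <- tab |>
    group_by(.data$protein_a, .data$protein_b) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    arrange(.data$protein_a, .data$protein_b)
  if (nrow(tab) < n_raw) {
    inform(sprintf("read_ppi: collapsed %d duplicate pair(s), keeping the maximum score",
                   n_raw - nrow(tab)))
  }
  tab
}

# shortest decimal representation that round-trips a double exactly
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write the input tables back to TSV
#'
#' Writers emit a `#`-prefixed header comment followed by tab-separated
#' records, so that reading the file back with the corresponding reader
#' reproduces the in-memory tibble exactly (numeric values are written
#' with round-trip precision).
#'
#' @param x The tibble to write (as returned by the matching reader).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_interactions <- function(x, path) {
  stopifnot(all(c("lncrna", "protein") %in% names(x)))
  writeLines(c("# lncrna\tprotein",
               paste(x$lncrna, x$protein, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_ppi <- function(x, path) {
  stopifnot(all(c("protein_a", "protein_b", "score") %in% names(x)))
  writeLines(c("# protein_a\tprotein_b\tscore",
               paste(x$protein_a, x$protein_b, .fmt_num(x$score), sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_expression <- function(x, path) {
  stopifnot(names(x)[1L] == "lncrna")
  vals <- as.matrix(x[-1L])
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(x$lncrna[i], .fmt_num(vals[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(names(x), collapse = "\t"), body), path)
  invisible(path)
}

#' Write ranked predictions to TSV
#'
#' Emits columns `query_lncrna`, `protein_id`, `score`, `rank`; ranks are
#' 1-based and restart at 1 for each query; scores are validated to be
#' non-increasing within a query.
#'
#' @param ranked A tibble of ranked predictions with columns `query`,
#'   `protein`, `score`, `rank` (as produced by [rank_candidates()] or
#'   [predict_partners()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ranked, path) {
  stopifnot(all(c("query", "protein", "score", "rank") %in% names(ranked)))
  if (!nrow(ranked)) abort("`ranked` must contain at least one prediction")
  by_query <- split(ranked, ranked$query)
  for (b in by_query) {
    if (is.unsorted(-b$score)) {
      abort(sprintf("scores for query %s are not non-increasing", b$query[1L]))
    }
    if (!all(b$rank == seq_len(nrow(b)))) {
      abort(sprintf("ranks for query %s are not consecutive from 1", b$query[1L]))
    }
  }
  writeLines(c("query_lncrna\tprotein_id\tscore\trank",
               paste(ranked$query, ranked$protein,
                     .fmt_num(ranked$score), ranked$rank, sep = "\t")),
             path)
  invisible(path)
}
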