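# Independent oracles used across test files.

# AUC as the normalized Mann-Whitney rank-sum statistic (ties get half
# credit via midranks) -- independent of the package's threshold sweep.
mw_auc <- function(score, label) {
  r <- rank(score)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Closed-form RWR fixed point: delta * (Id - (1 - delta) W')^{-1} y0
solve_oracle <- function(W, y0, delta) {
  as.numeric(delta * solve(diag(nrow(W)) - (1 - delta) * t(W), y0))
}

# Random heterogeneous network pieces with valid invariants (symmetric
# nonnegative similarity matrices with zero diagonal, binary I).
random_network <- function(m, n, ppi_density = 0.3, sl_density = 0.4,
                           int_density = 0.2) {
  pid <- sprintf("P%03d", seq_len(m))
  lid <- sprintf("L%03d", seq_len(n))
  sym_mat <- function(k, dens, ids) {
    x <- matrix(runif(k * k), k)
    x <- (x + t(x)) / 2
    mask <- matrix(runif(k * k) < dens, k)
    mask <- mask & t(mask)
    x[!mask] <- 0
    diag(x) <- 0
    dimnames(x) <- list(ids, ids)
    x
  }
  I <- matrix(rbinom(m * n, 1L, int_density), m, n,
              dimnames = list(pid, lid))
  list(sp = sym_mat(m, ppi_density, pid),
       sl = sym_mat(n, sl_density, lid),
       I = I)
}

# A minimal lpihn_loocv object built from explicit per-trial scores.
# `trials` is a list of lists with fields: held_out, candidates, scores.
make_trials <- function(trials, n_proteins = NULL, query = NULL) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    o <- order(tr$scores, tr$candidates,
               decreasing = c(TRUE, FALSE), method = "radix")
    cand <- tr$candidates[o]
    sc <- tr$scores[o]
    tibble::tibble(
      query = if (is.null(query)) sprintf("L%d", i) else query[i],
      held_out = tr$held_out,
      rank = which(cand == tr$held_out),
      n_candidates = length(cand),
      seeds = list(character()),
      candidates = list(cand),
      scores = list(sc)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_proteins") <- n_proteins %||% max(out$n_candidates)
  attr(out, "method") <- "manual"
  class(out) <- c("lpihn_loocv", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The hand-applied 4x4 transition matrix of the two-protein /
# two-lncRNA worked example (gamma = 0.5): protein P1 interacts with
# lncRNA L1, P1-P2 is the only PPI edge, L1-L2 the only similarity edge.
hand_worked_W <- function() {
  matrix(c(0,   0.5, 0.5, 0,
           1,   0,   0,   0,
           0.5, 0,   0,   0.5,
           0,   0,   1,   0),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("P1", "P2", "L1", "L2"),
                         c("P1", "P2", "L1", "L2")))
}
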