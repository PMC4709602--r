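# internal argument checks shared across constructors

.check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number, not %s",
                  name, paste(class(x), collapse = "/")))
  }
  invisible(x)
}

# probability in (lo, hi); closed ends only where stated
.check_prob <- function(x, name, lo = 0, hi = 1,
                        lo_open = TRUE, hi_open = TRUE) {
  .check_scalar_number(x, name)
  lo_ok <- if (lo_open) x > lo else x >= lo
  hi_ok <- if (hi_open) x < hi else x <= hi
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` must lie in %s%g, %g%s (got %g)",
                  name, if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]", x))
  }
  invisible(x)
}

# sample() without the length-1 surprise
.sample_ids <- function(x, size) {
  x[sample.int(length(x), size)]
}

# order by score descending, then id ascending, locale-independent
.rank_order <- function(score, id) {
  order(score, id, decreasing = c(TRUE, FALSE), method = "radix")
}
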