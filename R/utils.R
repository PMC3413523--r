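# Internal helpers: classed conditions and seed scoping.

# Raise a classed error. `class` is prepended so callers (and the CLI) can
# distinguish usage errors from data errors without string matching.
msa_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "msamerge_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

usage_abort <- function(msg) msa_abort(msg, "msamerge_usage_error")

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

# TRUE if integer vector a sorts lexicographically before b (same length).
lex_less <- function(a, b) {
  d <- which(a != b)
  if (length(d) == 0L) return(FALSE)
  a[d[1L]] < b[d[1L]]
}
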