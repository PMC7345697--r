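#' @keywords internal
"_PACKAGE"

# Abort with a classed condition so callers (and the CLI) can distinguish
# validation problems from I/O problems from internal contract violations.
qsrr_abort <- function(message, class) {
  stop(structure(
    class = c(class, "qsrr_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# Seeded evaluation that restores the caller's RNG state afterwards, so
# library code never perturbs the user's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derived seeds stay inside the 32-bit integer range.
derive_seed <- function(base, split = 0L, replicate = 0L) {
  as.integer((as.numeric(base) + split * 1000 + replicate) %% .Machine$integer.max)
}
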