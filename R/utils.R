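# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one integer seed, staying inside the
# 32-bit signed range expected by set.seed().
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# Sample indices covered by a half-open window [from, to) on a time axis.
window_index <- function(time_ms, window_ms) {
  if (length(window_ms) != 2L || !is.numeric(window_ms))
    abort("`window_ms` must be a numeric vector c(start, end).")
  if (window_ms[2] <= window_ms[1])
    abort(sprintf("`window_ms` end (%g) must be greater than start (%g).",
                  window_ms[2], window_ms[1]))
  idx <- which(time_ms >= window_ms[1] & time_ms < window_ms[2])
  if (length(idx) == 0L)
    abort(sprintf("window [%g, %g) ms contains no samples of the epoch.",
                  window_ms[1], window_ms[2]))
  idx
}

`%||%` <- rlang::`%||%`
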