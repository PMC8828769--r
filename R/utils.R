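# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Generators never touch global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be supplied.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_fraction <- function(x, name) check_number(x, name, 0, 1)
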