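# internal input-checking helpers

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg, call = NULL)
  invisible(TRUE)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  assert_that(lo_ok && hi_ok,
              sprintf("`%s` = %g is outside its allowed range", name, x))
  invisible(TRUE)
}

assert_count <- function(x, name, min = 1L) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x) &&
                x == floor(x) && x >= min,
              sprintf("`%s` must be an integer >= %d", name, min))
  invisible(TRUE)
}

# deterministic child seed, kept below 2^31 for R's 32-bit integer seeds
child_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
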