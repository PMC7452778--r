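# Internal helpers shared across modules.

#' Derive a child seed from a root seed
#'
#' Deterministic splitting rule used wherever one user-facing seed has to
#' drive several independent random streams (one per population, per stage,
#' ...). Children are kept strictly below 2^31 - 1 so they remain valid R
#' integer seeds.
#'
#' @param seed integer root seed.
#' @param index integer child index (1-based).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  as.integer((as.double(seed) + 1000003 * as.double(index)) %% 2147483647)
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

# strict integer coercion for parsers: NA on anything that is not a plain
# base-10 integer literal
.strict_integer <- function(x) {
  out <- suppressWarnings(as.integer(x))
  bad <- !grepl("^[+-]?[0-9]+$", x)
  out[bad] <- NA_integer_
  out
}
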