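#' @keywords internal
"_PACKAGE"

# Run code with a local, restored RNG state so generators are seed-pure.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

#' Derive a stream-specific child seed from a parent seed
#'
#' Deterministic mixing of a parent seed and a stream index, kept inside
#' the 32-bit integer range, so that independent pipeline stages draw from
#' distinct but reproducible random streams.
#' @param seed parent integer seed.
#' @param stream integer stream index.
#' @export
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) %% 1009L
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))
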