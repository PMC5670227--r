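# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the session RNG, evaluates `code`, and restores the previous RNG
#' state so that seeded package functions never disturb the caller's random
#' stream. A `NULL` seed evaluates `code` against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Draw a child seed from the current stream; keeps nested generators
# reproducible from a single top-level seed while staying below 2^31.
draw_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

stop_input <- function(...) stop(..., call. = FALSE)

# round() with IEEE round-half-even is fine for internal work; reported DHW is
# rounded UP (see report_dhw) so the risk index is never understated.
round_up_1dp <- function(x) ceiling(round(x * 10, 6)) / 10
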