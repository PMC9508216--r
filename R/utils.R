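#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so simulators are deterministic without clobbering
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
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

#' Derive a child seed from a global seed
#'
#' Deterministic fan-out so each pipeline stage has an independently
#' reproducible stream. Kept below 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param stage integer stage index (>= 1).
#' @return integer child seed.
#' @export
child_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + as.double(stage) * 104729) %% 2147483629)
}

# scalar positive check used by argument validation throughout
is_pos_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
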