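#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
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
  set.seed(seed)
  code
}

# Expand one master seed into reproducible per-stage / per-replicate sub-seeds.
# Stage codes keep streams for different pipeline stages disjoint; everything
# stays below 2^31 - 1.
derive_seed <- function(master, stage, index = 0L) {
  codes <- c(universe = 1L, network = 2L, samples = 3L, targets = 4L,
             walks = 5L, embedding = 6L, negatives = 7L, split = 8L,
             importance = 9L, shuffle = 10L, tune = 11L, fit = 12L,
             retrain = 13L, predict = 14L, citation = 15L, misc = 16L)
  code <- codes[[stage]]
  s <- (as.double(master) %% 1000003) * 1009 + code * 9973 + as.double(index) * 7
  as.integer(s %% 2147483646) + 1L
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# message() wrapper so generators/filters can report dropped records uniformly
log_note <- function(fmt, ...) message(sprintf(fmt, ...))
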