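# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published survey tables almost
#' universally round half up. All display rounding in this package goes
#' through this helper so that, e.g., 86.5 renders as 87.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded with ties going away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), 0)
#' round_half_up(47.25, 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a classed condition so callers/tests can distinguish
# configuration errors from data errors.
abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("crcdqi_config_error", "error")))
}

abort_data <- function(msg) {
  stop(errorCondition(msg, class = c("crcdqi_data_error", "error")))
}

# Seed a stage-specific RNG substream. Streams are derived from the base
# seed with fixed offsets so enabling/disabling a later stage (e.g.
# missingness) cannot perturb draws made by an earlier one.
stage_seed <- function(seed, stage) {
  offsets <- c(
    demographics = 11L, goals = 23L, screening = 37L, knowledge = 53L,
    top_three = 71L, involvement = 89L, missingness = 101L, retest = 131L,
    assignment = 151L
  )
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 1009 + off) %% 2147483647)
}

with_stage_seed <- function(seed, stage, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(stage_seed(seed, stage))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}
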