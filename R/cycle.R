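#' Draw cell-cycle lengths from the shifted gamma distribution
#'
#' Returns `refractory_h + Gamma(shape, scale)` draws, so every cycle length
#' is at least the refractory period. All randomness uses R's global RNG; set
#' [set.seed()] for reproducibility.
#'
#' @param params [cell_cycle_params()].
#' @param n Number of draws.
#' @return Numeric vector of cycle lengths in hours.
#' @examples
#' set.seed(1)
#' x <- sample_cycle(cell_cycle_params(), 1000)
#' c(mean(x), sd(x), min(x))   # ~6, ~1, >= 4
#' @export
sample_cycle <- function(params = cell_cycle_params(), n = 1) {
  stopifnot(inherits(params, "cell_cycle_params"))
  params$refractory_h + stats::rgamma(n, shape = params$shape, scale = params$scale)
}

#' Draw division modes at a given internal-clock time
#'
#' The mode (PP, PD or DD) is drawn from the schedule window containing the
#' clock time; windows are half-open, so a clock exactly at a boundary uses
#' the later window.
#'
#' @param clock_h Internal-clock times in hours (vectorised), each >= 0.
#' @param schedule [mode_schedule()].
#' @return Character vector of modes, values in `"PP"`, `"PD"`, `"DD"`.
#' @export
choose_mode <- function(clock_h, schedule = mode_schedule()) {
  stopifnot(inherits(schedule, "mode_schedule"))
  if (any(clock_h < 0)) stop("clock_h must be >= 0")
  win <- findInterval(clock_h, schedule$breaks) + 1L
  modes <- colnames(schedule$probs)
  vapply(win, function(w)
    sample(modes, 1L, prob = schedule$probs[w, ]), character(1))
}
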