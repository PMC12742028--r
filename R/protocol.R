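#' Session protocol: ordered state blocks
#'
#' A `session_protocol` is the block layout of one recording session: an
#' ordered set of contiguous state segments (rest, self-boundary
#' dissolution `SBminus`, self-boundary maintenance `SBplus`), each with a
#' duration in whole seconds, plus the sampling rate of the simulated
#' signal.
#'
#' @param states character vector of segment states, each one of
#'   `"rest"`, `"SBminus"`, `"SBplus"`.
#' @param durations_s integer-valued segment durations in seconds
#'   (positive multiples of 1 s), same length as `states`.
#' @param sampling_rate sampling rate in Hz.
#' @return A `session_protocol` object (data frame of segments plus the
#'   sampling rate as an attribute).
#' @seealso [default_protocol()]
#' @export
session_protocol <- function(states, durations_s, sampling_rate = 300) {
  if (length(states) != length(durations_s) || length(states) == 0)
    stop("invalid protocol: states and durations must be non-empty and equal length")
  if (!all(states %in% STATES))
    stop("invalid protocol: unknown state label(s): ",
         paste(setdiff(states, STATES), collapse = ", "))
  if (any(durations_s <= 0) || any(durations_s != round(durations_s)))
    stop("invalid protocol: durations must be positive whole seconds")
  if (sampling_rate <= 0) stop("invalid protocol: non-positive sampling rate")
  out <- data.frame(state = states, duration_s = as.integer(durations_s),
                    stringsAsFactors = FALSE)
  out$start_s <- cumsum(c(0L, out$duration_s[-nrow(out)]))
  out$end_s <- out$start_s + out$duration_s
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("session_protocol", "data.frame")
  out
}

#' Default session protocol (300 s per state)
#'
#' Two blocks, each starting with 100 s of rest followed by five
#' alternations between self-boundary dissolution and maintenance (60 s
#' each, the first block starting with SBminus, the second with SBplus so
#' the two states balance), and a third 100 s resting segment at the end.
#' Every state totals exactly 300 s.
#'
#' @param sampling_rate sampling rate in Hz (default 300).
#' @return A [session_protocol()].
#' @examples
#' p <- default_protocol()
#' tapply(p$duration_s, p$state, sum)  # 300 s per state
#' @export
default_protocol <- function(sampling_rate = 300) {
  block1 <- c("rest", rep(c("SBminus", "SBplus"), length.out = 5))
  block2 <- c("rest", rep(c("SBplus", "SBminus"), length.out = 5))
  states <- c(block1, block2, "rest")
  durations <- c(100, rep(60, 5), 100, rep(60, 5), 100)
  session_protocol(states, durations, sampling_rate)
}

#' Per-state total duration of a protocol
#' @param protocol a [session_protocol()].
#' @return named numeric vector of seconds per state.
#' @export
protocol_state_totals <- function(protocol) {
  tot <- tapply(protocol$duration_s, protocol$state, sum)
  out <- stats::setNames(numeric(length(tot)), names(tot))
  out[] <- tot
  out
}
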