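#' Five-phase exposure protocol
#'
#' Builds the phase timeline used by every downstream stage: an ordered set
#' of contiguous, half-open phase intervals `[start, end)` in seconds from
#' recording start. The default is the standard exposure protocol of five
#' 15-min phases: two pre-exposure baselines (S1, S2), the exposure phase
#' (E), and two post-exposure phases (P1, P2), 75 min in total.
#'
#' @param labels Character vector of ordered phase labels.
#' @param durations Phase durations in seconds; recycled to `length(labels)`.
#'   Default 900 s (15 min) each.
#' @return An object of class `phase_protocol` with elements `labels`,
#'   `start`, `end` (seconds) and `total_duration`.
#' @examples
#' p <- phase_protocol()
#' phase_of(c(0, 1800, 4499.9), p)
#' @export
phase_protocol <- function(labels = c("S1", "S2", "E", "P1", "P2"),
                           durations = 900) {
  if (length(labels) < 1L || anyDuplicated(labels))
    stop("phase labels must be non-empty and unique")
  durations <- rep_len(as.numeric(durations), length(labels))
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("phase durations must be positive and finite")
  end <- cumsum(durations)
  structure(
    list(labels = as.character(labels),
         start = c(0, end[-length(end)]),
         end = end,
         total_duration = end[length(end)]),
    class = "phase_protocol")
}

#' @export
print.phase_protocol <- function(x, ...) {
  cat("<phase_protocol> ", length(x$labels), " phases, ",
      x$total_duration, " s total\n", sep = "")
  for (i in seq_along(x$labels))
    cat(sprintf("  %-4s [%g, %g)\n", x$labels[i], x$start[i], x$end[i]))
  invisible(x)
}

#' Map times to protocol phases
#'
#' Each time maps to the unique phase whose half-open interval `[start, end)`
#' contains it; a time sitting exactly on a boundary therefore belongs to the
#' later phase.
#'
#' @param t Numeric vector of times in seconds from recording start.
#' @param protocol A [phase_protocol()].
#' @return Character vector of phase labels, same length as `t`.
#' @export
phase_of <- function(t, protocol) {
  stopifnot(inherits(protocol, "phase_protocol"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0) || any(t >= protocol$total_duration))
    stop("times must lie in [0, ", protocol$total_duration, ")")
  idx <- findInterval(t, c(protocol$start, protocol$total_duration),
                      left.open = FALSE)
  protocol$labels[idx]
}

#' Duration of each phase in seconds
#' @param protocol A [phase_protocol()].
#' @return Named numeric vector of durations.
#' @export
phase_durations <- function(protocol) {
  stopifnot(inherits(protocol, "phase_protocol"))
  stats::setNames(protocol$end - protocol$start, protocol$labels)
}
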