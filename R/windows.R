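#' Sliding analysis window specification
#'
#' Defines the sliding window over which symbol histograms are accumulated for
#' entropy, neurodynamic information (NI) and power-value (EEG-PV) traces.
#' The canonical analysis models symbol distributions over 60 s, updated each
#' second; those are the defaults.
#'
#' @param length_s Window length in seconds (default 60).
#' @param step_s Step between successive windows in seconds (default 1).
#' @param alignment `"trailing"` (default) anchors each window at its final
#'   second, so the value at time `t` summarizes `(t - length_s, t]` and the
#'   trace is causal; `"centered"` anchors at the window midpoint.
#' @param min_occupancy Minimum fraction of unmasked epochs a window must
#'   contain for a value to be emitted; windows below the floor yield `NA`.
#'
#' @details A window much shorter than about five times the alphabet size
#'   gives a heavily biased plug-in entropy estimate; a warning is issued at
#'   trace time when that holds.  The plug-in bias for an i.i.d. stream is
#'   approximately `(S - 1) / (2 N ln 2)` bits for alphabet size `S` and
#'   window occupancy `N`.
#'
#' @return An object of class `nd_window`.
#' @examples
#' window_spec()            # the 60 s / 1 s default
#' window_spec(30, 1)
#' @export
window_spec <- function(length_s = 60, step_s = 1, alignment = c("trailing", "centered"),
                        min_occupancy = 0.5) {
  alignment <- match.arg(alignment)
  if (!is.numeric(length_s) || length_s < 1) {
    stop_neurodyn("window length must be a positive number of seconds",
                  class = "neurodyn_config_error")
  }
  if (!is.numeric(step_s) || step_s < 1) {
    stop_neurodyn("window step must be >= 1 s", class = "neurodyn_config_error")
  }
  if (min_occupancy <= 0 || min_occupancy > 1) {
    stop_neurodyn("min_occupancy must be in (0, 1]", class = "neurodyn_config_error")
  }
  structure(list(length_s = as.integer(length_s), step_s = as.integer(step_s),
                 alignment = alignment, min_occupancy = min_occupancy),
            class = "nd_window")
}

#' @export
print.nd_window <- function(x, ...) {
  cat(sprintf("<nd_window> %d s, step %d s, %s, occupancy floor %.0f%%\n",
              x$length_s, x$step_s, x$alignment, 100 * x$min_occupancy))
  invisible(x)
}

same_window <- function(a, b) {
  identical(a$length_s, b$length_s) && identical(a$step_s, b$step_s) &&
    identical(a$alignment, b$alignment)
}

# Start indices (1-based) of each emitted window over a stream of length n.
window_starts <- function(window, n) {
  if (n < window$length_s) return(integer(0))
  seq.int(1L, n - window$length_s + 1L, by = window$step_s)
}

# Anchor times for windows over stream times t0 .. t0+n-1.
window_anchors <- function(window, n, t0 = 1) {
  s <- window_starts(window, n)
  if (window$alignment == "trailing") {
    t0 - 1 + s + window$length_s - 1L
  } else {
    t0 - 1 + s + (window$length_s - 1L) / 2
  }
}
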