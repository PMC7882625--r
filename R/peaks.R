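# Local maxima indices of x (no NAs), plateau-aware: a plateau bounded by
# strictly lower values on both sides yields its middle index.  Maxima
# touching either end of the segment are edge peaks and are dropped when
# exclude_edges.
local_maxima <- function(x, exclude_edges = TRUE) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # plateau [i, j]
      if (j < n && x[j + 1L] < x[i]) {
        out <- c(out, i + (j - i) %/% 2L)
        i <- j + 1L
        next
      }
      if (j >= n && !exclude_edges) out <- c(out, i + (j - i) %/% 2L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!exclude_edges && n >= 2) {
    if (x[1] > x[2]) out <- c(1L, out)
  }
  sort(out)
}

# Topographic prominence of peak p in x: extend left/right until a strictly
# higher sample or the segment edge; prominence = height - max(min_left, min_right).
# Returns list(prominence, lb, rb) where lb/rb bound the peak's base interval.
peak_prominence <- function(x, p) {
  h <- x[p]
  i <- p
  while (i > 1L && x[i - 1L] <= h) i <- i - 1L
  lb <- i
  min_l <- min(x[lb:p])
  i <- p
  n <- length(x)
  while (i < n && x[i + 1L] <= h) i <- i + 1L
  rb <- i
  min_r <- min(x[p:rb])
  list(prominence = h - max(min_l, min_r), lb = lb, rb = rb)
}

# Interpolated crossing of level `ref` walking outward from peak p within
# [lb, rb]; returns fractional index.
cross_left <- function(x, p, lb, ref) {
  j <- p
  while (j > lb && x[j - 1L] >= ref) j <- j - 1L
  if (j == lb || x[j - 1L] >= ref) return(as.numeric(j))
  # x[j-1] < ref <= x[j]: linear interpolation between j-1 and j
  (j - 1L) + (ref - x[j - 1L]) / (x[j] - x[j - 1L])
}

cross_right <- function(x, p, rb, ref) {
  j <- p
  while (j < rb && x[j + 1L] >= ref) j <- j + 1L
  if (j == rb || x[j + 1L] >= ref) return(as.numeric(j))
  j + (x[j] - ref) / (x[j] - x[j + 1L])
}

#' Detect NI peaks by prominence, with half-prominence durations
#'
#' Finds local maxima of a trace whose topographic prominence (height above
#' the higher of the two flanking minima) reaches `min_prominence`, and
#' measures each peak's duration as the width of the interval in which the
#' trace exceeds `height - prominence / 2`, interpolating linearly between
#' samples.  Masked (`NA`) stretches split the trace; maxima at segment edges
#' have no defined width and are excluded.
#'
#' @param trace An [nd_trace()] (typically baseline-corrected NI) or a
#'   numeric vector.
#' @param min_prominence Minimum prominence in bits (default 0.1, the
#'   operating threshold for uncertainty episodes).
#' @param min_height Minimum peak height in bits (default 0).
#' @param times Anchor times when `trace` is a bare numeric vector.
#' @param width_reference `"half_prominence"` (default) or `"full_prominence"`
#'   (width at `height - prominence`).
#' @return A data frame of peak records: `anchor_time`, `magnitude`,
#'   `prominence`, `duration`, `left_edge`, `right_edge` (seconds/bits),
#'   sorted by time.  Zero rows is a valid result.
#' @examples
#' bump <- c(seq(0, 0.4, length.out = 21), seq(0.4, 0, length.out = 21)[-1])
#' detect_peaks(bump, times = seq_along(bump))$duration  # 20 s at half prominence
#' @export
detect_peaks <- function(trace, min_prominence = 0.1, min_height = 0,
                         times = NULL,
                         width_reference = c("half_prominence", "full_prominence")) {
  width_reference <- match.arg(width_reference)
  if (inherits(trace, "nd_trace")) {
    x_all <- trace$values
    t_all <- trace$time
    coords <- trace$coords
  } else {
    x_all <- as.numeric(trace)
    t_all <- if (is.null(times)) seq_along(x_all) else as.numeric(times)
    coords <- stream_coords()
  }
  stopifnot(length(x_all) == length(t_all))
  empty <- data.frame(anchor_time = numeric(0), magnitude = numeric(0),
                      prominence = numeric(0), duration = numeric(0),
                      left_edge = numeric(0), right_edge = numeric(0),
                      member = character(0), channel = character(0),
                      bin_hz = numeric(0), stringsAsFactors = FALSE)
  # split on NA into contiguous segments
  ok <- !is.na(x_all)
  if (!any(ok)) return(empty)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rows <- list()
  for (r in which(runs$values)) {
    seg <- starts[r]:ends[r]
    if (length(seg) < 3) next
    x <- x_all[seg]
    tt <- t_all[seg]
    for (p in local_maxima(x)) {
      pr <- peak_prominence(x, p)
      if (pr$prominence < min_prominence || x[p] < min_height) next
      ref <- if (width_reference == "half_prominence") x[p] - pr$prominence / 2
             else x[p] - pr$prominence
      li <- cross_left(x, p, pr$lb, ref)
      ri <- cross_right(x, p, pr$rb, ref)
      # fractional indices -> times (uniform spacing within a segment)
      idx_to_t <- function(fi) {
        f0 <- floor(fi)
        if (f0 >= length(tt)) return(tt[length(tt)])
        tt[f0] + (fi - f0) * (tt[min(f0 + 1, length(tt))] - tt[f0])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        anchor_time = tt[p], magnitude = x[p], prominence = pr$prominence,
        duration = idx_to_t(ri) - idx_to_t(li),
        left_edge = idx_to_t(li), right_edge = idx_to_t(ri),
        member = as.character(coords$member),
        channel = as.character(coords$channel),
        bin_hz = as.numeric(coords$bin_hz), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$anchor_time), , drop = FALSE]
}

#' Mean peak duration across a grid of prominence thresholds
#'
#' Re-detects peaks at each threshold of an ascending prominence grid and
#' summarizes duration — the curve whose plateau locates the natural temporal
#' scale of uncertainty episodes.
#'
#' @param traces A list of [nd_trace()]s (or one trace).
#' @param prominence_grid Ascending numeric thresholds in bits.
#' @param ... Passed to [detect_peaks()].
#' @return A data frame: `min_prominence`, `n_peaks`, `mean_duration`,
#'   `sd_duration`, `mean_magnitude`.
#' @export
duration_vs_magnitude <- function(traces, prominence_grid, ...) {
  if (inherits(traces, "nd_trace")) traces <- list(traces)
  if (length(prominence_grid) == 0) {
    stop_neurodyn("prominence grid is empty", class = "neurodyn_config_error")
  }
  if (is.unsorted(prominence_grid, strictly = TRUE)) {
    stop_neurodyn("prominence grid must be strictly ascending",
                  class = "neurodyn_config_error")
  }
  res <- lapply(prominence_grid, function(th) {
    pk <- do.call(rbind, lapply(traces, detect_peaks, min_prominence = th, ...))
    data.frame(min_prominence = th, n_peaks = nrow(pk),
               mean_duration = if (nrow(pk)) mean(pk$duration) else NA_real_,
               sd_duration = if (nrow(pk) > 1) stats::sd(pk$duration) else NA_real_,
               mean_magnitude = if (nrow(pk)) mean(pk$magnitude) else NA_real_)
  })
  do.call(rbind, res)
}

#' Incidence of peak epochs across streams
#'
#' Counts how many analyzed time points fall inside any detected peak
#' interval, per stream, in the union sense (an epoch inside two overlapping
#' peaks counts once).
#'
#' @param peaks A data frame of peak records, or a list of them matched to
#'   `traces` by position.
#' @param traces A list of [nd_trace()]s the peaks were detected on.
#' @return A list of class `incidence_summary`: `total_epochs`,
#'   `epochs_in_peaks`, `fraction` (2-decimal convention in print), and
#'   `percent` (= 100 * fraction).
#' @examples
#' tr <- nd_trace(c(rep(0, 5), 0.1, 0.3, 0.1, rep(0, 5)), 1:13,
#'                window_spec(3), "ni", 3)
#' incidence(detect_peaks(tr, 0.1), list(tr))
#' @export
incidence <- function(peaks, traces) {
  if (inherits(traces, "nd_trace")) traces <- list(traces)
  if (is.data.frame(peaks)) peaks <- list(peaks)
  if (length(peaks) != length(traces)) {
    if (length(peaks) == 1) peaks <- rep(peaks, length(traces))
    else stop_neurodyn("one peak table per trace required",
                       class = "neurodyn_config_error")
  }
  total <- 0L
  inpeak <- 0L
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    pk <- peaks[[i]]
    t_ok <- tr$time[!is.na(tr$values)]
    total <- total + length(t_ok)
    if (nrow(pk) > 0) {
      if (any(pk$left_edge < min(tr$time) - 1e-9) ||
          any(pk$right_edge > max(tr$time) + 1e-9)) {
        stop_neurodyn("peak intervals fall outside their trace",
                      class = "neurodyn_config_error")
      }
      covered <- rep(FALSE, length(t_ok))
      for (j in seq_len(nrow(pk))) {
        covered <- covered | (t_ok >= pk$left_edge[j] & t_ok <= pk$right_edge[j])
      }
      inpeak <- inpeak + sum(covered)
    }
  }
  structure(list(total_epochs = total, epochs_in_peaks = inpeak,
                 fraction = if (total > 0) inpeak / total else 0,
                 percent = if (total > 0) 100 * inpeak / total else 0),
            class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("<incidence> %d of %d epochs in peaks: fraction %.2f (%.1f%%)\n",
              x$epochs_in_peaks, x$total_epochs, x$fraction, x$percent))
  invisible(x)
}
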