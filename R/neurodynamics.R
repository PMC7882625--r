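#' Windowed trace container
#'
#' Internal-facing constructor for the per-window traces produced by
#' [windowed_entropy()], [windowed_ni()] and [eeg_pv()]: a numeric value per
#' emitted window (NA = masked), anchor times, effective occupancy, the
#' window spec and the stream coordinates.
#'
#' @param values Numeric vector, one value per emitted window.
#' @param time Anchor times (s), same length as `values`.
#' @param window An [window_spec()].
#' @param kind One of `"entropy"`, `"ni"`, `"pv"`, `"mi"`, `"r"`.
#' @param n_symbols Alphabet size the values refer to (NA for `"pv"`/`"r"`).
#' @param n_eff Effective (unmasked) occupancy per window.
#' @param coords Stream coordinates.
#' @param baseline Optional matched baseline values (same length).
#' @param corrected Logical: has a baseline been subtracted?
#' @return An object of class `nd_trace`.
#' @export
nd_trace <- function(values, time, window, kind, n_symbols = NA_integer_,
                     n_eff = NULL, coords = stream_coords(),
                     baseline = NULL, corrected = FALSE) {
  stopifnot(length(values) == length(time))
  structure(list(values = as.numeric(values), time = as.numeric(time),
                 window = window, kind = kind, n_symbols = n_symbols,
                 n_eff = n_eff, coords = coords, baseline = baseline,
                 corrected = corrected),
            class = "nd_trace")
}

#' @export
print.nd_trace <- function(x, ...) {
  cat(sprintf("<nd_trace:%s> %d window(s) [%s]%s mean %.4g\n", x$kind,
              length(x$values), coords_label(x$coords),
              if (x$corrected) " (baseline-corrected)" else "",
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
length.nd_trace <- function(x) length(x$values)

#' @export
mean.nd_trace <- function(x, ...) mean(x$values, na.rm = TRUE)

# Sliding histogram entropies over integer codes 1..S.  Returns list
# (H bits, n_eff, anchors); windows below the occupancy floor give NA.
sliding_entropy <- function(codes, S, window, t0 = 1) {
  n <- length(codes)
  starts <- window_starts(window, n)
  H <- rep(NA_real_, length(starts))
  n_eff <- integer(length(starts))
  if (length(starts) == 0) {
    return(list(H = H, n_eff = n_eff, time = numeric(0)))
  }
  L <- window$length_s
  floor_n <- ceiling(window$min_occupancy * L)
  counts <- integer(S)
  w0 <- codes[starts[1]:(starts[1] + L - 1L)]
  for (v in w0) if (!is.na(v)) counts[v] <- counts[v] + 1L
  for (i in seq_along(starts)) {
    if (i > 1) {
      # slide: drop symbols leaving, add symbols entering
      for (j in starts[i - 1]:(starts[i] - 1L)) {
        v <- codes[j]
        if (!is.na(v)) counts[v] <- counts[v] - 1L
      }
      for (j in (starts[i - 1] + L):(starts[i] + L - 1L)) {
        v <- codes[j]
        if (!is.na(v)) counts[v] <- counts[v] + 1L
      }
    }
    m <- sum(counts)
    n_eff[i] <- m
    if (m >= floor_n) H[i] <- entropy_bits(counts)
  }
  list(H = H, n_eff = n_eff, time = window_anchors(window, n, t0))
}

#' Sliding-window Shannon entropy of a symbol stream
#'
#' Plug-in (maximum-likelihood) Shannon entropy, base 2, of the symbol
#' histogram in each sliding window — the canonical model is a 60-s window
#' updated each second.  Masked epochs are excluded from the histogram;
#' windows whose unmasked occupancy falls below the spec's floor emit `NA`.
#'
#' @param stream A [symbol_stream()] or [compose_team()] stream.
#' @param window An [window_spec()].
#' @return An [nd_trace()] of kind `"entropy"` (bits).
#' @examples
#' s <- symbol_stream(rep(c(-1, 1, 3), 40))
#' max(windowed_entropy(s, window_spec())$values)  # log2(3)
#' @export
windowed_entropy <- function(stream, window = window_spec()) {
  S <- alphabet_size(stream)
  codes <- symbol_codes(stream)
  if (length(codes) < window$length_s) {
    stop_neurodyn("stream shorter than the analysis window",
                  class = "neurodyn_config_error")
  }
  if (window$length_s < 5 * S) {
    warning(sprintf(paste0("window of %d s is short for a %d-symbol alphabet; ",
                           "plug-in entropy will be heavily biased"),
                    window$length_s, S))
  }
  res <- sliding_entropy(codes, S, window, t0 = stream$t0)
  nd_trace(res$H, res$time, window, "entropy", n_symbols = S,
           n_eff = res$n_eff, coords = stream$coords)
}

#' Neurodynamic information from entropy
#'
#' NI is the maximum entropy of the alphabet minus the observed windowed
#' entropy: `NI = log2(S) - H`, a positive quantity of information.  A fully
#' ordered (single-symbol) window therefore carries the whole alphabet
#' capacity: 1.58 bits for an individual (S = 3), 3.17 bits for a dyad
#' (S = 9), 4.75 bits for a triad (S = 27).
#'
#' @param entropy An entropy [nd_trace()] or a numeric vector of entropies (bits).
#' @param n_symbols Alphabet size (taken from the trace when omitted).
#' @param tol Numerical tolerance for bound checks (values in
#'   `[-tol, 0)` clamp to 0).
#' @return An `nd_trace` of kind `"ni"`, or a numeric vector when `entropy`
#'   is numeric.
#' @examples
#' ni_from_entropy(0, 27)        # 4.75 bits
#' ni_from_entropy(log2(9), 9)   # 0
#' @export
ni_from_entropy <- function(entropy, n_symbols = NULL, tol = 1e-9) {
  if (inherits(entropy, "nd_trace")) {
    if (is.null(n_symbols)) n_symbols <- entropy$n_symbols
    ni <- ni_from_entropy(entropy$values, n_symbols, tol)
    out <- nd_trace(ni, entropy$time, entropy$window, "ni",
                    n_symbols = n_symbols, n_eff = entropy$n_eff,
                    coords = entropy$coords)
    return(out)
  }
  if (is.null(n_symbols)) {
    stop_neurodyn("n_symbols required for numeric input", class = "neurodyn_config_error")
  }
  hmax <- log2(n_symbols)
  bad <- !is.na(entropy) & (entropy < -tol | entropy > hmax + tol)
  if (any(bad)) {
    stop_neurodyn(sprintf("entropy outside [0, log2(%d)] beyond tolerance", n_symbols),
                  class = "neurodyn_internal_error")
  }
  pmax(hmax - entropy, 0)
}

#' Windowed neurodynamic information of a stream
#'
#' Convenience composition of [windowed_entropy()] and [ni_from_entropy()].
#'
#' @inheritParams windowed_entropy
#' @return An [nd_trace()] of kind `"ni"` (bits).
#' @export
windowed_ni <- function(stream, window = window_spec()) {
  ni_from_entropy(windowed_entropy(stream, window))
}

#' Randomized (surrogate) NI baseline
#'
#' Temporally shuffles the stream's unmasked symbols (a uniform random
#' permutation, destroying all temporal structure while preserving the symbol
#' distribution), recomputes windowed NI for each shuffle and averages per
#' window index.  The mean baseline of an i.i.d. stream equals the plug-in
#' estimator's bias — approximately `(S - 1) / (2 N ln 2)` bits, about 0.1
#' bits for a nine-symbol dyad in a 60-s window — so subtracting it is the
#' method's own bias control.
#'
#' @inheritParams windowed_entropy
#' @param n_shuffles Number of random permutations to average (default 6).
#' @param seed Optional integer seed; shuffles are drawn from a local RNG
#'   stream so global state is untouched.
#' @return An [nd_trace()] of kind `"ni"` representing the baseline.
#' @export
randomized_baseline <- function(stream, window = window_spec(), n_shuffles = 6,
                                seed = NULL) {
  if (n_shuffles < 1) {
    stop_neurodyn("n_shuffles must be >= 1", class = "neurodyn_config_error")
  }
  codes <- symbol_codes(stream)
  S <- alphabet_size(stream)
  ok <- which(!is.na(codes))
  acc <- NULL
  with_seed(seed, {
    for (i in seq_len(n_shuffles)) {
      sh <- codes
      sh[ok] <- codes[sample(ok)]
      res <- sliding_entropy(sh, S, window, t0 = stream$t0)
      ni <- ni_from_entropy(res$H, S)
      acc <- if (is.null(acc)) ni else acc + ni
    }
  })
  res <- sliding_entropy(codes, S, window, t0 = stream$t0)  # for anchors/n_eff
  nd_trace(acc / n_shuffles, res$time, window, "ni", n_symbols = S,
           n_eff = res$n_eff, coords = stream$coords)
}

#' Subtract a randomized baseline from a raw NI trace
#'
#' Elementwise `raw - baseline`, floored at zero (NI is defined as a positive
#' quantity of information); the result carries the baseline and a
#' `corrected` flag.
#'
#' @param raw,baseline Matched [nd_trace()]s of kind `"ni"` (same window and
#'   anchors).
#' @return A corrected `nd_trace`.
#' @export
subtract_baseline <- function(raw, baseline) {
  stopifnot(inherits(raw, "nd_trace"), inherits(baseline, "nd_trace"))
  if (!same_window(raw$window, baseline$window) ||
      length(raw$values) != length(baseline$values) ||
      !isTRUE(all.equal(raw$time, baseline$time))) {
    stop_neurodyn("raw and baseline traces are not aligned",
                  class = "neurodyn_alignment_error")
  }
  nd_trace(pmax(raw$values - baseline$values, 0), raw$time, raw$window, "ni",
           n_symbols = raw$n_symbols, n_eff = raw$n_eff, coords = raw$coords,
           baseline = baseline$values, corrected = TRUE)
}

#' Corrected NI in one call
#'
#' Raw windowed NI minus its matched randomized baseline.
#'
#' @inheritParams randomized_baseline
#' @return A corrected [nd_trace()].
#' @export
corrected_ni <- function(stream, window = window_spec(), n_shuffles = 6, seed = NULL) {
  subtract_baseline(windowed_ni(stream, window),
                    randomized_baseline(stream, window, n_shuffles, seed))
}

#' Shared information of a dyad and the team decomposition
#'
#' Per-window mutual information between the two members' symbol streams,
#' `MI = H(X) + H(Y) - H(X, Y)`, with plug-in entropies over the shared
#' unmasked epochs.  Because the team alphabet is the member product
#' (`log2 9 = log2 3 + log2 3`), the decomposition
#' `NI_team = NI_X + NI_Y + MI` holds exactly per window.
#'
#' @param x,y Member [symbol_stream()]s (aligned).
#' @param team Optional `team_stream` built from `x` and `y`; composed
#'   internally when omitted.
#' @inheritParams windowed_entropy
#' @return A list of [nd_trace()]s: `mi`, `ni_team`, `ni_x`, `ni_y` (all on
#'   identical anchors).  Triads are not supported; decompose pairwise.
#' @export
shared_information <- function(x, y, team = NULL, window = window_spec()) {
  if (!inherits(x, "symbol_stream") || !inherits(y, "symbol_stream")) {
    stop_neurodyn("shared_information is defined for dyads (two member streams)",
                  class = "neurodyn_config_error")
  }
  if (length(x$symbols) != length(y$symbols)) {
    stop_neurodyn("member streams differ in length", class = "neurodyn_alignment_error")
  }
  if (is.null(team)) team <- compose_team(list(x, y))
  if (team$k != 2) {
    stop_neurodyn("team stream must be a dyad", class = "neurodyn_config_error")
  }
  # common mask so all four entropies see the same epochs
  mask <- is.na(x$symbols) | is.na(y$symbols) | is.na(team$symbols)
  cx <- match(x$symbols, SYMBOL_ALPHABET); cx[mask] <- NA_integer_
  cy <- match(y$symbols, SYMBOL_ALPHABET); cy[mask] <- NA_integer_
  ct <- team$symbols; ct[mask] <- NA_integer_
  hx <- sliding_entropy(cx, 3L, window, t0 = x$t0)
  hy <- sliding_entropy(cy, 3L, window, t0 = x$t0)
  ht <- sliding_entropy(ct, 9L, window, t0 = x$t0)
  mi <- hx$H + hy$H - ht$H
  w <- window
  list(mi = nd_trace(mi, hx$time, w, "mi", n_symbols = 9L, n_eff = ht$n_eff,
                     coords = team$coords),
       ni_team = nd_trace(ni_from_entropy(ht$H, 9L), ht$time, w, "ni", 9L,
                          n_eff = ht$n_eff, coords = team$coords),
       ni_x = nd_trace(ni_from_entropy(hx$H, 3L), hx$time, w, "ni", 3L,
                       n_eff = hx$n_eff, coords = x$coords),
       ni_y = nd_trace(ni_from_entropy(hy$H, 3L), hy$time, w, "ni", 3L,
                       n_eff = hy$n_eff, coords = y$coords))
}

#' Average NI traces across a stratum
#'
#' Drill-down aggregation: the arithmetic mean, per time index, of the traces
#' in the selected stratum — all streams (`"scalp"`), one sensor across bins
#' (`"sensor"`), a named scalp region (`"region"`), or one 1-Hz bin across
#' sensors (`"frequency"`).
#'
#' @param traces A list of [nd_trace()]s sharing window and anchors.
#' @param level Aggregation level.
#' @param channel Sensor label (for `level = "sensor"`).
#' @param bin_hz Frequency bin (for `level = "frequency"`).
#' @param region Region name (for `level = "region"`).
#' @param scheme A [region_scheme()] (for `level = "region"`).
#' @return An `nd_trace` whose coords name the stratum; the stratum size is
#'   stored in `n_eff`.
#' @export
aggregate_ni <- function(traces, level = c("scalp", "sensor", "region", "frequency"),
                         channel = NULL, bin_hz = NULL, region = NULL,
                         scheme = region_scheme()) {
  level <- match.arg(level)
  stopifnot(length(traces) >= 1)
  sel <- switch(level,
    scalp = rep(TRUE, length(traces)),
    sensor = {
      if (is.null(channel)) stop_neurodyn("channel required for sensor level",
                                          class = "neurodyn_config_error")
      vapply(traces, function(tr) identical(as.character(tr$coords$channel), channel),
             logical(1))
    },
    frequency = {
      if (is.null(bin_hz)) stop_neurodyn("bin_hz required for frequency level",
                                         class = "neurodyn_config_error")
      vapply(traces, function(tr) isTRUE(tr$coords$bin_hz == bin_hz), logical(1))
    },
    region = {
      if (is.null(region)) stop_neurodyn("region required for region level",
                                         class = "neurodyn_config_error")
      chs <- names(scheme)[scheme == region]
      if (length(chs) == 0) stop_neurodyn("region '", region, "' not in scheme",
                                          class = "neurodyn_config_error")
      vapply(traces, function(tr) as.character(tr$coords$channel) %in% chs, logical(1))
    })
  if (!any(sel)) {
    stop_neurodyn("empty stratum for level '", level, "' (",
                  paste0(c(channel, bin_hz, region), collapse = ","), ")",
                  class = "neurodyn_config_error")
  }
  sub <- traces[sel]
  t1 <- sub[[1]]
  for (tr in sub) {
    if (!same_window(tr$window, t1$window) ||
        !isTRUE(all.equal(tr$time, t1$time))) {
      stop_neurodyn("traces differ in window or anchors", class = "neurodyn_alignment_error")
    }
  }
  vals <- matrix(vapply(sub, function(tr) tr$values, numeric(length(t1$values))),
                 nrow = length(t1$values))
  m <- rowMeans(vals, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  lab <- switch(level, scalp = "scalp", sensor = channel,
                region = region, frequency = paste0(bin_hz, "Hz"))
  nd_trace(m, t1$time, t1$window, t1$kind, n_symbols = t1$n_symbols,
           n_eff = rep(length(sub), length(t1$values)),
           coords = stream_coords(NA, lab, if (level == "frequency") bin_hz else NA_real_))
}
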