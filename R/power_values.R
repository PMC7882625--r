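#' Scalp region scheme
#'
#' Maps 10-20 channel labels to scalp regions.  The default partitions the
#' 19-channel montage into frontal (Fp1, Fp2, F7, F3, Fz, F4, F8), central
#' (T3, C3, Cz, C4, T4), parietal (P7, P3, Pz, P4, P8) and occipital (O1, O2).
#'
#' @param mapping Named character vector `channel -> region`; default as above.
#' @return A named character vector of class `region_scheme`.
#' @export
region_scheme <- function(mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- c(
      Fp1 = "frontal", Fp2 = "frontal", F7 = "frontal", F3 = "frontal",
      Fz = "frontal", F4 = "frontal", F8 = "frontal",
      T3 = "central", C3 = "central", Cz = "central", C4 = "central",
      T4 = "central",
      P7 = "parietal", P3 = "parietal", Pz = "parietal", P4 = "parietal",
      P8 = "parietal",
      O1 = "occipital", O2 = "occipital")
  }
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop_neurodyn("region scheme must be a named channel -> region vector",
                  class = "neurodyn_config_error")
  }
  structure(mapping, class = c("region_scheme", class(mapping)))
}

#' Numeric EEG power-value trace (EEG-PV)
#'
#' Reads the ternary symbols numerically (-1 = deactivated, 1 = average,
#' 3 = activated) and takes their moving average over the analysis window, on
#' the same anchors as NI.  A complete equal-occupancy stream has a
#' whole-performance mean of exactly 1.0; windowed values above 1 indicate
#' net activation, below 1 net deactivation.
#'
#' @param stream A [symbol_stream()].
#' @param window An [window_spec()].
#' @return An [nd_trace()] of kind `"pv"` (dimensionless, in `[-1, 3]`).
#' @examples
#' s <- symbol_stream(rep(c(-1, 1, 3), 40))
#' range(eeg_pv(s, window_spec())$values)  # 1 1
#' @export
eeg_pv <- function(stream, window = window_spec()) {
  if (!inherits(stream, "symbol_stream")) {
    stop_neurodyn("EEG-PV is defined on member symbol streams",
                  class = "neurodyn_config_error")
  }
  v <- as.numeric(stream$symbols)
  n <- length(v)
  if (n < window$length_s) {
    stop_neurodyn("stream shorter than the analysis window",
                  class = "neurodyn_config_error")
  }
  starts <- window_starts(window, n)
  L <- window$length_s
  floor_n <- ceiling(window$min_occupancy * L)
  out <- rep(NA_real_, length(starts))
  n_eff <- integer(length(starts))
  for (i in seq_along(starts)) {
    w <- v[starts[i]:(starts[i] + L - 1L)]
    m <- sum(!is.na(w))
    n_eff[i] <- m
    if (m >= floor_n) out[i] <- mean(w, na.rm = TRUE)
  }
  nd_trace(out, window_anchors(window, n, stream$t0), window, "pv",
           n_eff = n_eff, coords = stream$coords)
}

# Pearson r with NA-pair removal; NA when < 3 complete pairs or either side
# has zero variance.
safe_cor <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Correlation between NI and EEG-PV traces
#'
#' Pearson correlation of two aligned traces, either over the whole
#' performance (a scalar) or in a sliding window over the trace anchors (a
#' correlation trace).  Windows in which either input is constant have an
#' undefined r and are masked, never zero-filled.
#'
#' @param ni,pv Aligned [nd_trace()]s (same anchors).
#' @param window `"whole"` (default) for a single coefficient, or an
#'   [window_spec()] for a windowed correlation series.
#' @return A scalar, or an `nd_trace` of kind `"r"`.
#' @export
ni_pv_correlation <- function(ni, pv, window = "whole") {
  stopifnot(inherits(ni, "nd_trace"), inherits(pv, "nd_trace"))
  if (length(ni$values) != length(pv$values) ||
      !isTRUE(all.equal(ni$time, pv$time))) {
    stop_neurodyn("NI and PV traces are not aligned", class = "neurodyn_alignment_error")
  }
  if (identical(window, "whole")) {
    return(safe_cor(ni$values, pv$values))
  }
  stopifnot(inherits(window, "nd_window"))
  n <- length(ni$values)
  starts <- window_starts(window, n)
  L <- window$length_s
  out <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + L - 1L)
    out[i] <- safe_cor(ni$values[idx], pv$values[idx])
  }
  anchors <- ni$time[starts + L - 1L]
  nd_trace(out, anchors, window, "r", coords = ni$coords)
}

#' Regional NI / EEG-PV correlation maps
#'
#' Aggregates NI and PV traces within each stratum (whole scalp, scalp
#' region, or region-by-frequency) by per-index averaging, then correlates
#' the aggregated traces — aggregate-then-correlate, so each map entry
#' describes the stratum's common signal rather than an average of noisy
#' stream-level correlations.
#'
#' @param ni_traces,pv_traces Lists of matched [nd_trace()]s with identical
#'   stream coordinates (one NI and one PV trace per stream).
#' @param scheme A [region_scheme()].
#' @param granularity `"scalp"`, `"region"`, or `"region_frequency"`.
#' @param window `"whole"` or an [window_spec()], as in [ni_pv_correlation()].
#' @return A data frame with columns `stratum` (and `bin_hz` for
#'   region-by-frequency) plus either `r` (whole) or one row per stratum with
#'   the windowed trace in a list column `trace`.
#' @export
correlation_map <- function(ni_traces, pv_traces, scheme = region_scheme(),
                            granularity = c("scalp", "region", "region_frequency"),
                            window = "whole") {
  granularity <- match.arg(granularity)
  stopifnot(length(ni_traces) == length(pv_traces), length(ni_traces) >= 1)
  key <- function(tr) coords_label(tr$coords)
  if (!identical(vapply(ni_traces, key, character(1)),
                 vapply(pv_traces, key, character(1)))) {
    stop_neurodyn("NI and PV trace sets do not match stream for stream",
                  class = "neurodyn_alignment_error")
  }
  chans <- vapply(ni_traces, function(tr) as.character(tr$coords$channel), character(1))
  bins <- vapply(ni_traces, function(tr) as.numeric(tr$coords$bin_hz), numeric(1))
  strata <- switch(granularity,
    scalp = data.frame(stratum = "scalp", stringsAsFactors = FALSE),
    region = data.frame(stratum = unique(unname(scheme[chans])), stringsAsFactors = FALSE),
    region_frequency = unique(data.frame(stratum = unname(scheme[chans]),
                                         bin_hz = bins, stringsAsFactors = FALSE)))
  strata <- strata[!is.na(strata$stratum), , drop = FALSE]
  res <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    sel <- if (granularity == "scalp") rep(TRUE, length(chans))
           else if (granularity == "region") scheme[chans] == strata$stratum[i]
           else scheme[chans] == strata$stratum[i] & bins == strata$bin_hz[i]
    sel[is.na(sel)] <- FALSE
    if (!any(sel)) {
      stop_neurodyn("empty stratum '", strata$stratum[i], "'",
                    class = "neurodyn_config_error")
    }
    agg <- function(trs) {
      t1 <- trs[[1]]
      vals <- matrix(vapply(trs, function(tr) tr$values,
                            numeric(length(t1$values))), nrow = length(t1$values))
      m <- rowMeans(vals, na.rm = TRUE)
      m[is.nan(m)] <- NA_real_
      nd_trace(m, t1$time, t1$window, t1$kind, coords = t1$coords)
    }
    res[[i]] <- ni_pv_correlation(agg(ni_traces[sel]), agg(pv_traces[sel]), window)
  }
  if (identical(window, "whole")) {
    strata$r <- vapply(res, identity, numeric(1))
  } else {
    strata$trace <- I(res)
  }
  rownames(strata) <- NULL
  strata
}
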