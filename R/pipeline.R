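#' Pipeline run configuration
#'
#' Bundles everything a full drill-down run needs: the input symbol streams
#' (or a [sim_config()] to generate them), the analysis window, the shuffle
#' count and seed for the randomized baseline, the region scheme, peak
#' thresholds and the output directory.  The config is serialized into the
#' output directory for provenance.
#'
#' @param streams A named list of [symbol_stream()]s, or `NULL` to simulate.
#' @param sim A [sim_config()] used when `streams` is `NULL`.
#' @param window An [window_spec()].
#' @param n_shuffles Shuffles for the randomized baseline.
#' @param seed Integer seed controlling the baseline shuffles.
#' @param scheme A [region_scheme()].
#' @param min_prominence Peak prominence threshold (bits).
#' @param out_dir Output directory (created if missing); `NULL` for in-memory
#'   results only.
#' @return A list of class `run_config`.
#' @export
run_config <- function(streams = NULL, sim = NULL, window = window_spec(),
                       n_shuffles = 6, seed = 1, scheme = region_scheme(),
                       min_prominence = 0.1, out_dir = NULL) {
  if (is.null(streams) && is.null(sim)) {
    stop_neurodyn("either streams or a sim_config is required",
                  class = "neurodyn_config_error")
  }
  structure(list(streams = streams, sim = sim, window = window,
                 n_shuffles = n_shuffles, seed = as.integer(seed),
                 scheme = scheme, min_prominence = min_prominence,
                 out_dir = out_dir),
            class = "run_config")
}

trace_df <- function(tr, id) {
  data.frame(time = tr$time, id = id,
             member = as.character(tr$coords$member),
             channel = as.character(tr$coords$channel),
             bin_hz = as.numeric(tr$coords$bin_hz),
             value = tr$values,
             baseline = if (is.null(tr$baseline)) NA_real_ else tr$baseline,
             stringsAsFactors = FALSE)
}

#' Run the full neurodynamic pipeline
#'
#' For every input stream: windowed NI, randomized baseline, corrected NI,
#' EEG-PV, NI/PV whole-performance correlation, peak detection and the
#' pooled incidence summary.  With an output directory set, all tables are
#' written as CSV along with a JSON manifest (seed, package version, config
#' digest); identical config and seed reproduce identical tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `streams`, `ni`, `baseline`, `corrected`, `pv`,
#'   `correlations` (data frame), `peaks` (data frame), `incidence`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  streams <- config$streams
  truth <- NULL
  if (is.null(streams)) {
    sim <- simulate_symbols(config$sim)
    streams <- sim$streams
    truth <- sim$truth
  }
  w <- config$window
  ni <- list(); base <- list(); corr <- list(); pv <- list()
  failed <- character(0)
  for (si in seq_along(streams)) {
    nm <- names(streams)[si]
    s <- streams[[si]]
    res <- tryCatch({
      raw <- windowed_ni(s, w)
      b <- randomized_baseline(s, w, config$n_shuffles,
                               seed = config$seed + si)
      list(raw = raw, b = b, c = subtract_baseline(raw, b), pv = eeg_pv(s, w))
    }, neurodyn_error = function(e) e)
    if (inherits(res, "error")) {
      warning("stream ", nm, " failed: ", conditionMessage(res))
      failed <- c(failed, nm)
      next
    }
    ni[[nm]] <- res$raw; base[[nm]] <- res$b; corr[[nm]] <- res$c; pv[[nm]] <- res$pv
  }
  if (length(corr) == 0) {
    stop_neurodyn("no stream could be analyzed", class = "neurodyn_config_error")
  }
  cors <- data.frame(id = names(corr),
                     r = vapply(names(corr), function(nm)
                       ni_pv_correlation(corr[[nm]], pv[[nm]]), numeric(1)),
                     stringsAsFactors = FALSE)
  peaks <- do.call(rbind, c(lapply(names(corr), function(nm) {
    pk <- detect_peaks(corr[[nm]], min_prominence = config$min_prominence)
    if (nrow(pk)) pk$id <- nm else pk$id <- character(0)
    pk
  }), list(make.row.names = FALSE)))
  inc <- incidence(lapply(names(corr), function(nm) peaks[peaks$id == nm, , drop = FALSE]),
                   unname(corr))
  manifest <- list(package = "neurodyn",
                   version = as.character(utils::packageVersion("neurodyn")),
                   seed = config$seed, n_shuffles = config$n_shuffles,
                   window_length_s = w$length_s, window_step_s = w$step_s,
                   min_prominence = config$min_prominence,
                   n_streams = length(corr), failed_streams = failed)
  out <- list(streams = streams, truth = truth, ni = ni, baseline = base,
              corrected = corr, pv = pv, correlations = cors, peaks = peaks,
              incidence = inc, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_symbol_table(streams, p("symbols.csv"))
    wtab <- function(traces, f) {
      df <- do.call(rbind, lapply(names(traces), function(nm)
        trace_df(traces[[nm]], nm)))
      utils::write.table(df, p(f), sep = ",", row.names = FALSE, quote = FALSE)
    }
    wtab(ni, "ni_raw.csv"); wtab(corr, "ni_corrected.csv"); wtab(pv, "pv.csv")
    utils::write.table(cors, p("correlations.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(peaks, p("peaks.csv"), sep = ",", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(data.frame(total_epochs = inc$total_epochs,
                                  epochs_in_peaks = inc$epochs_in_peaks,
                                  fraction = round(inc$fraction, 2),
                                  percent = round(inc$percent, 1)),
                       p("incidence.csv"), sep = ",", row.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(out)
}

#' Export traces as a time-by-frequency matrix
#'
#' Stacks one trace per 1-Hz bin (one member/sensor set) into a dense matrix,
#' rows in ascending Hz, ready for heatmap rendering; optionally written as
#' CSV with a `bin_hz` first column and time-stamped value columns.
#'
#' @param traces A list of [nd_trace()]s sharing anchors, one per bin.
#' @param file Optional CSV path.
#' @return A numeric matrix (bins x time) with dimnames, invisibly when
#'   written.
#' @export
export_timefreq_map <- function(traces, file = NULL) {
  if (inherits(traces, "nd_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  t1 <- traces[[1]]
  for (tr in traces) {
    if (length(tr$values) != length(t1$values) ||
        !isTRUE(all.equal(tr$time, t1$time))) {
      stop_neurodyn("traces differ in anchors; cannot form a dense map",
                    class = "neurodyn_alignment_error")
    }
  }
  bins <- vapply(traces, function(tr) as.numeric(tr$coords$bin_hz), numeric(1))
  ord <- order(bins)
  m <- t(vapply(traces[ord], function(tr) tr$values, numeric(length(t1$values))))
  m <- matrix(m, nrow = length(traces),
              dimnames = list(paste0(bins[ord], "Hz"), as.character(t1$time)))
  if (!is.null(file)) {
    df <- data.frame(bin_hz = bins[ord], m, check.names = FALSE)
    utils::write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(m))
  }
  m
}

#' Read back a time-by-frequency matrix written by [export_timefreq_map()]
#'
#' @param file CSV path.
#' @return A numeric matrix (bins x time).
#' @export
read_timefreq_map <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = ",", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- paste0(df$bin_hz, "Hz")
  m
}
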