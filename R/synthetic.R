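#' Simulation configuration
#'
#' Describes a synthetic team recording: members, channels, 1-Hz bins,
#' duration, the baseline symbol model, and planted persistent epochs —
#' stretches in which one symbol is held with high probability, emulating the
#' persistent activation/deactivation episodes that elevate NI.
#'
#' @param n_members Team size (1-3).
#' @param channels Channel labels (default `"C3"`).
#' @param bins 1-Hz bin centers (default `10`).
#' @param duration_s Performance length in seconds.
#' @param baseline `"uniform"` (i.i.d. uniform thirds, the default) or
#'   `"markov"` (first-order persistence `markov_persist` of staying on the
#'   current symbol).
#' @param markov_persist Stay probability for the Markov baseline.
#' @param epochs Optional data frame of planted epochs with columns `member`,
#'   `channel`, `bin_hz`, `start`, `duration`, `held_symbol`, `hold_prob`;
#'   generated when omitted and `n_epochs > 0`.
#' @param n_epochs Number of epochs to generate per targeted stream.
#' @param epoch_duration Epoch length in seconds (default 90).
#' @param hold_prob Probability the held symbol is emitted per second inside
#'   an epoch (default 0.8).
#' @param coupling Probability that a generated epoch is co-expressed by all
#'   members (shared timing, independent emissions); default 0.
#' @param target_channel,target_bin Stream that receives generated epochs
#'   (defaults: first channel, first bin).
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_members = 2, channels = "C3", bins = 10,
                       duration_s = 600, baseline = c("uniform", "markov"),
                       markov_persist = 0.6, epochs = NULL, n_epochs = 0,
                       epoch_duration = 90, hold_prob = 0.8, coupling = 0,
                       target_channel = channels[1], target_bin = bins[1],
                       seed) {
  baseline <- match.arg(baseline)
  if (missing(seed) || is.null(seed)) {
    stop_neurodyn("a seed is mandatory for reproducible simulation",
                  class = "neurodyn_config_error")
  }
  if (n_members < 1 || n_members > 3) {
    stop_neurodyn("n_members must be 1, 2 or 3", class = "neurodyn_config_error")
  }
  for (p in c(markov_persist, hold_prob, coupling)) {
    if (p < 0 || p > 1) stop_neurodyn("probabilities must be in [0, 1]",
                                      class = "neurodyn_config_error")
  }
  if (hold_prob == 0) {
    stop_neurodyn("hold_prob must be in (0, 1]", class = "neurodyn_config_error")
  }
  cfg <- list(n_members = as.integer(n_members), channels = channels,
              bins = as.numeric(bins), duration_s = as.integer(duration_s),
              baseline = baseline, markov_persist = markov_persist,
              epochs = epochs, n_epochs = as.integer(n_epochs),
              epoch_duration = as.integer(epoch_duration),
              hold_prob = hold_prob, coupling = coupling,
              target_channel = target_channel, target_bin = target_bin,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Non-overlapping epoch starts: one epoch per equal block, random offset.
place_epochs <- function(n_epochs, epoch_duration, duration_s) {
  if (n_epochs * epoch_duration > duration_s) {
    stop_neurodyn("epochs do not fit in the performance without overlap",
                  class = "neurodyn_config_error")
  }
  block <- duration_s %/% n_epochs
  vapply(seq_len(n_epochs), function(i) {
    lo <- (i - 1L) * block + 1L
    hi <- i * block - epoch_duration + 1L
    if (hi < lo) lo else sample(lo:hi, 1L)
  }, numeric(1))
}

check_epochs <- function(ep) {
  sp <- split(ep, paste(ep$member, ep$channel, ep$bin_hz))
  for (s in sp) {
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < (s$start + s$duration)[-nrow(s)])) {
      stop_neurodyn("planted epochs overlap within a stream",
                    class = "neurodyn_config_error")
    }
  }
  invisible(ep)
}

#' Simulate member symbol streams with planted persistent epochs
#'
#' Outside planted epochs symbols are drawn from the baseline model (i.i.d.
#' uniform over \{-1, 1, 3\}, or first-order Markov); inside an epoch the held
#' symbol is emitted with probability `hold_prob` and a uniform draw
#' otherwise.  The ground-truth epoch table is returned alongside, so peak
#' recovery can be scored against what was planted.  Identical config and
#' seed give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list: `streams` (list of [symbol_stream()]s named
#'   `"<member>.<channel>.<bin>Hz"`) and `truth` (the epoch data frame, zero
#'   rows when nothing was planted).
#' @export
simulate_symbols <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$duration_s
  with_seed(config$seed, {
    ep <- config$epochs
    if (is.null(ep) && config$n_epochs > 0) {
      rows <- list()
      for (i in seq_len(config$n_epochs)) {
        shared <- stats::runif(1) < config$coupling
        members <- if (shared) seq_len(config$n_members) else
          sample.int(config$n_members, 1L)
        rows[[i]] <- list(members = members)
      }
      starts <- place_epochs(config$n_epochs, config$epoch_duration, n)
      ep <- do.call(rbind, lapply(seq_len(config$n_epochs), function(i) {
        data.frame(member = rows[[i]]$members,
                   channel = config$target_channel,
                   bin_hz = config$target_bin,
                   start = starts[i], duration = config$epoch_duration,
                   held_symbol = sample(SYMBOL_ALPHABET, 1L),
                   hold_prob = config$hold_prob, stringsAsFactors = FALSE)
      }))
    }
    if (is.null(ep)) {
      ep <- data.frame(member = integer(0), channel = character(0),
                       bin_hz = numeric(0), start = numeric(0),
                       duration = numeric(0), held_symbol = integer(0),
                       hold_prob = numeric(0), stringsAsFactors = FALSE)
    }
    check_epochs(ep)
    streams <- list()
    for (m in seq_len(config$n_members)) {
      for (ch in config$channels) {
        for (b in config$bins) {
          sym <- if (config$baseline == "uniform") {
            sample(SYMBOL_ALPHABET, n, replace = TRUE)
          } else {
            s <- integer(n)
            s[1] <- sample(SYMBOL_ALPHABET, 1L)
            for (t in 2:n) {
              s[t] <- if (stats::runif(1) < config$markov_persist) s[t - 1]
                      else sample(SYMBOL_ALPHABET, 1L)
            }
            s
          }
          here <- ep[ep$member == m & ep$channel == ch & ep$bin_hz == b, ,
                     drop = FALSE]
          for (j in seq_len(nrow(here))) {
            idx <- here$start[j]:(here$start[j] + here$duration[j] - 1L)
            idx <- idx[idx >= 1 & idx <= n]
            hold <- stats::runif(length(idx)) < here$hold_prob[j]
            sym[idx[hold]] <- here$held_symbol[j]
            sym[idx[!hold]] <- sample(SYMBOL_ALPHABET, sum(!hold), replace = TRUE)
          }
          streams[[paste0(m, ".", ch, ".", b, "Hz")]] <-
            symbol_stream(sym, member = m, channel = ch, bin_hz = b)
        }
      }
    }
    list(streams = streams, truth = ep)
  })
}

#' Simulate raw EEG whose band amplitudes follow a ternary level process
#'
#' Each channel is a sum of band-limited oscillators at the configured bin
#' centers whose amplitude switches each second between three discrete levels
#' following a simulated symbol process, plus white Gaussian noise at the
#' requested signal-to-noise ratio.  Exercises the Welch-to-symbolization
#' path end to end: symbolizing the per-second band power should recover the
#' planted level sequence.
#'
#' @param config A [sim_config()] (its channels/bins/duration/seed are used;
#'   one member's symbol process drives each channel-bin oscillator).
#' @param fs Sampling rate in Hz (must be at least twice the highest bin).
#' @param level_amplitudes Amplitudes (microvolts) for levels -1, 1, 3.
#' @param snr Signal-to-noise power ratio; `Inf` for noiseless; must be > 0.
#' @return A list: `raw` (a [raw_eeg()]), `levels` (the planted
#'   [symbol_stream()]s per channel-bin) and `truth` (epoch table).
#' @export
simulate_raw_eeg <- function(config, fs = 128, level_amplitudes = c(1, 2, 4),
                             snr = Inf) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.infinite(snr) && snr <= 0) {
    stop_neurodyn("snr must be positive", class = "neurodyn_config_error")
  }
  if (fs < 2 * max(config$bins)) {
    stop_neurodyn("sampling rate too low for the configured bins",
                  class = "neurodyn_config_error")
  }
  if (all(level_amplitudes == 0)) {
    stop_neurodyn("zero-amplitude config carries no level signal",
                  class = "neurodyn_config_error")
  }
  sim <- simulate_symbols(config)
  n_s <- config$duration_s
  nsamp <- n_s * fs
  tvec <- (0:(nsamp - 1)) / fs
  sec <- floor(tvec) + 1L
  mat <- matrix(0, nrow = length(config$channels), ncol = nsamp,
                dimnames = list(config$channels, NULL))
  with_seed(config$seed + 1L, {
    for (ci in seq_along(config$channels)) {
      ch <- config$channels[ci]
      sig <- numeric(nsamp)
      for (b in config$bins) {
        key <- paste0("1.", ch, ".", b, "Hz")
        lev <- sim$streams[[key]]$symbols
        amp <- level_amplitudes[match(lev, SYMBOL_ALPHABET)][sec]
        phase <- stats::runif(1, 0, 2 * pi)
        sig <- sig + amp * sin(2 * pi * b * tvec + phase)
      }
      if (is.finite(snr)) {
        psig <- mean(sig^2)
        sig <- sig + stats::rnorm(nsamp, 0, sqrt(psig / snr))
      }
      mat[ci, ] <- sig
    }
  })
  list(raw = raw_eeg(mat, fs, config$channels, max_bin_hz = max(config$bins)),
       levels = sim$streams[grepl("^1\\.", names(sim$streams))],
       truth = sim$truth)
}
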