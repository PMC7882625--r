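SYMBOL_ALPHABET <- c(-1L, 1L, 3L)

#' Ternary symbol stream for one member / channel / frequency bin
#'
#' A per-second sequence of the symbols -1 (low), 1 (average) and 3 (high
#' power), the elementary neurodynamic data stream.  Usually constructed by
#' [symbolize_stream()]; this constructor validates a hand-built one.
#'
#' @param symbols Integer vector over `{-1, 1, 3}`; `NA` marks masked epochs.
#' @param member,channel,bin_hz Stream coordinates (any may be `NA`).
#' @param boundaries Optional numeric length-2 vector: the two tertile cut
#'   points (power units) that produced the symbols.
#' @param t0 Time of the first epoch in seconds (default 1).
#' @return An object of class `symbol_stream`.
#' @export
symbol_stream <- function(symbols, member = NA, channel = NA_character_,
                          bin_hz = NA_real_, boundaries = NULL, t0 = 1) {
  symbols <- as.integer(symbols)
  bad <- !is.na(symbols) & !(symbols %in% SYMBOL_ALPHABET)
  if (any(bad)) {
    stop_neurodyn("symbols must be in {-1, 1, 3} (or NA)",
                  class = "neurodyn_config_error")
  }
  structure(list(symbols = symbols,
                 coords = stream_coords(member, channel, bin_hz),
                 boundaries = boundaries, t0 = t0),
            class = "symbol_stream")
}

#' @export
print.symbol_stream <- function(x, ...) {
  cat(sprintf("<symbol_stream> %s: %d epoch(s), %d masked\n",
              coords_label(x$coords), length(x$symbols), sum(is.na(x$symbols))))
  invisible(x)
}

#' @export
length.symbol_stream <- function(x) length(x$symbols)

#' Equal-occupancy ternary symbolization of a power sequence
#'
#' Splits the whole-performance distribution of per-epoch band power into
#' empirical tertiles and assigns the bottom third the symbol -1, the middle
#' third 1 and the top third 3.  Assignment is rank-based with ties broken by
#' time index, so the three symbol counts differ pairwise by at most one
#' regardless of repeated values — the equal-occupancy construction that makes
#' entropy comparable across streams.  Cut points are computed once over the
#' full unmasked sequence ("performance averaged"), never per window.
#'
#' @param power Numeric vector of per-epoch power (finite; `NA` = masked epoch).
#' @param member,channel,bin_hz Stream coordinates stored on the result.
#' @param t0 Time of the first epoch in seconds.
#' @return A [symbol_stream()] with `boundaries` set to the two cut points.
#' @examples
#' symbolize_stream(1:9)$symbols   # -1 -1 -1  1  1  1  3  3  3
#' @export
symbolize_stream <- function(power, member = NA, channel = NA_character_,
                             bin_hz = NA_real_, t0 = 1) {
  power <- as.numeric(power)
  ok <- !is.na(power)
  if (any(!is.finite(power[ok]))) {
    stop_neurodyn("power values must be finite", class = "neurodyn_config_error")
  }
  n <- sum(ok)
  if (n < 3) {
    stop_neurodyn("need at least 3 unmasked epochs to symbolize (stream ",
                  coords_label(stream_coords(member, channel, bin_hz)), ")",
                  class = "neurodyn_degenerate_error")
  }
  v <- power[ok]
  if (max(v) == min(v)) {
    stop_neurodyn("all power values identical; cannot form three levels (stream ",
                  coords_label(stream_coords(member, channel, bin_hz)), ")",
                  class = "neurodyn_degenerate_error")
  }
  r <- rank(v, ties.method = "first")     # stable: ties broken by time index
  grp <- ceiling(3 * r / n)               # 1, 2, 3 with counts differing by <= 1
  symbols <- rep(NA_integer_, length(power))
  symbols[ok] <- SYMBOL_ALPHABET[grp]
  ord <- order(v)
  lo_size <- sum(grp == 1)
  mid_size <- sum(grp == 2)
  boundaries <- c(v[ord][lo_size], v[ord][lo_size + mid_size])
  symbol_stream(symbols, member, channel, bin_hz, boundaries = boundaries, t0 = t0)
}

#' Symbolize every stream of a PSD tensor
#'
#' Applies [symbolize_stream()] independently to each (channel, bin) power
#' sequence of a [welch_psd()] tensor.
#'
#' @param psd A `psd_tensor`.
#' @param member Member id stored on every resulting stream.
#' @return A list of `symbol_stream`s, named `"<channel>.<bin>Hz"`.
#' @export
symbolize_psd <- function(psd, member = NA) {
  bins <- attr(psd, "bins")
  chs <- attr(psd, "channel_labels")
  out <- list()
  for (ch in seq_along(chs)) {
    for (b in seq_along(bins)) {
      s <- symbolize_stream(psd[, ch, b], member = member, channel = chs[ch],
                            bin_hz = bins[b], t0 = attr(psd, "start_time") + 1)
      out[[paste0(chs[ch], ".", bins[b], "Hz")]] <- s
    }
  }
  out
}

# rank of a ternary symbol: -1 -> 0, 1 -> 1, 3 -> 2
symbol_rank <- function(s) match(s, SYMBOL_ALPHABET) - 1L

#' Compose member symbol streams into a team stream
#'
#' Combines k aligned member streams (k = 1, 2 or 3) into one composite
#' neurodynamic symbol per second over the team state space of `3^k` labels
#' (9 for a dyad, 27 for a triad).  The encoding is lexicographic base-3 in
#' declared member order: label `= 1 + sum_i rank(s_i) * 3^(k-1-i)` with rank
#' -1 -> 0, 1 -> 1, 3 -> 2.  An epoch masked in any member is masked in the
#' composite (intersection semantics).
#'
#' @param members List of [symbol_stream()]s sharing channel, bin and length.
#' @return An object of class `team_stream` with fields `symbols` (labels in
#'   `1:3^k` or `NA`), `member_ids`, `coords`, `k`, and `encoding` (a
#'   data frame giving the full tuple-to-label bijection).
#' @examples
#' a <- symbol_stream(c(-1, 3), member = "G")
#' b <- symbol_stream(c(-1, 3), member = "F")
#' compose_team(list(a, b))$symbols   # 1 9
#' @export
compose_team <- function(members) {
  k <- length(members)
  if (k < 1 || k > 3) {
    stop_neurodyn("1 to 3 members supported", class = "neurodyn_config_error")
  }
  lens <- vapply(members, function(m) length(m$symbols), integer(1))
  if (length(unique(lens)) != 1) {
    stop_neurodyn("member streams differ in length", class = "neurodyn_alignment_error")
  }
  ch <- unique(vapply(members, function(m) as.character(m$coords$channel), character(1)))
  bz <- unique(vapply(members, function(m) as.numeric(m$coords$bin_hz), numeric(1)))
  if (length(ch) != 1 || length(bz) != 1) {
    stop_neurodyn("member streams must share channel and bin",
                  class = "neurodyn_alignment_error")
  }
  ranks <- vapply(members, function(m) symbol_rank(m$symbols), integer(lens[1]))
  ranks <- matrix(ranks, nrow = lens[1])
  weights <- 3L^((k - 1L):0L)
  labels <- 1L + as.integer(ranks %*% weights)
  labels[apply(ranks, 1, anyNA)] <- NA_integer_
  enc <- expand.grid(rev(lapply(seq_len(k), function(i) SYMBOL_ALPHABET)),
                     KEEP.OUT.ATTRS = FALSE)[, k:1, drop = FALSE]
  names(enc) <- paste0("member", seq_len(k))
  enc$label <- 1L + as.integer(as.matrix(
    vapply(enc[seq_len(k)], symbol_rank, integer(nrow(enc)))) %*% weights)
  enc <- enc[order(enc$label), , drop = FALSE]
  rownames(enc) <- NULL
  structure(list(symbols = labels,
                 member_ids = lapply(members, function(m) m$coords$member),
                 coords = stream_coords(NA, ch, bz),
                 k = k, encoding = enc, t0 = members[[1]]$t0),
            class = "team_stream")
}

#' @export
print.team_stream <- function(x, ...) {
  cat(sprintf("<team_stream> %d member(s), %s/%s Hz: %d epoch(s) over %d labels\n",
              x$k, x$coords$channel, x$coords$bin_hz, length(x$symbols), 3L^x$k))
  invisible(x)
}

#' @export
length.team_stream <- function(x) length(x$symbols)

#' Recover member symbol streams from a team stream
#'
#' Inverts the lexicographic base-3 encoding of [compose_team()]; decoding
#' then re-encoding is the identity.
#'
#' @param team A `team_stream`.
#' @return A list of `k` [symbol_stream()]s in declared member order.
#' @export
decode_team <- function(team) {
  stopifnot(inherits(team, "team_stream"))
  k <- team$k
  v <- team$symbols - 1L
  out <- vector("list", k)
  for (i in k:1) {
    r <- v %% 3L
    out[[i]] <- symbol_stream(SYMBOL_ALPHABET[r + 1L],
                              member = team$member_ids[[i]],
                              channel = team$coords$channel,
                              bin_hz = team$coords$bin_hz, t0 = team$t0)
    v <- v %/% 3L
  }
  out
}

# Alphabet size of a stream (3 for members, 3^k for teams).
alphabet_size <- function(stream) {
  if (inherits(stream, "team_stream")) 3L^stream$k else 3L
}

# Integer codes 1..S for a stream's symbols (NA preserved).
symbol_codes <- function(stream) {
  if (inherits(stream, "team_stream")) stream$symbols
  else match(stream$symbols, SYMBOL_ALPHABET)
}

#' Read / write symbol streams as long-format delimited tables
#'
#' Columns: `time`, `member`, `channel`, `bin_hz`, `symbol`.  One file can
#' carry many streams; they are split on (member, channel, bin_hz) when read.
#'
#' @param streams A list of [symbol_stream()]s.
#' @param file Path to a delimited text file.
#' @param sep Field separator.
#' @return `read_symbol_table()` returns a named list of `symbol_stream`s;
#'   `write_symbol_table()` returns `file` invisibly.
#' @export
write_symbol_table <- function(streams, file, sep = ",") {
  if (inherits(streams, "symbol_stream")) streams <- list(streams)
  rows <- lapply(streams, function(s) {
    data.frame(time = s$t0 + seq_along(s$symbols) - 1,
               member = as.character(s$coords$member),
               channel = as.character(s$coords$channel),
               bin_hz = as.numeric(s$coords$bin_hz),
               symbol = s$symbols, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_symbol_table
#' @export
read_symbol_table <- function(file, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("time", "member", "channel", "bin_hz", "symbol")
  if (!all(need %in% names(df))) {
    stop_neurodyn("symbol table needs columns time, member, channel, bin_hz, symbol",
                  class = "neurodyn_io_error")
  }
  key <- paste(df$member, df$channel, df$bin_hz, sep = "|")
  out <- list()
  for (kk in unique(key)) {
    sub <- df[key == kk, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    s <- symbol_stream(sub$symbol, member = sub$member[1], channel = sub$channel[1],
                       bin_hz = sub$bin_hz[1], t0 = min(sub$time))
    out[[paste0(sub$member[1], ".", sub$channel[1], ".", sub$bin_hz[1], "Hz")]] <- s
  }
  out
}
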