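test_that("flat and triangular traces give the textbook peak geometry", {
  expect_equal(nrow(detect_peaks(rep(0, 100), times = 1:100)), 0L)
  # triangular bump 0 -> 0.4 over 20 s -> 0 over 20 s
  bump <- c(seq(0, 0.4, length.out = 21), seq(0.4, 0, length.out = 21)[-1])
  pk <- detect_peaks(c(rep(0, 5), bump, rep(0, 5)), times = seq_len(length(bump) + 10))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$magnitude, 0.4)
  expect_equal(pk$prominence, 0.4)
  expect_equal(pk$duration, 20)           # crossings 10 s either side of apex
  expect_equal(pk$anchor_time, 26)
})

test_that("Gaussian bumps recover the closed-form FWHM", {
  t <- 1:201
  for (sigma in c(8, 15)) {
    x <- 0.5 * exp(-(t - 101)^2 / (2 * sigma^2))
    pk <- detect_peaks(x, times = t, min_prominence = 0.1)
    expect_equal(nrow(pk), 1L)
    expect_equal(pk$duration, sigma * 2 * sqrt(2 * log(2)), tolerance = 1 / pk$duration)
  }
})

test_that("peak widths match the brute-force crossing oracle on rough traces", {
  set.seed(51)
  for (i in 1:25) {
    x <- pmax(stats::filter(rnorm(150), rep(1 / 8, 8), sides = 1), 0)
    x <- as.numeric(x[!is.na(x)])
    pk <- detect_peaks(x, times = seq_along(x), min_prominence = 0.05)
    if (nrow(pk) == 0) next
    for (j in seq_len(nrow(pk))) {
      p <- as.integer(pk$anchor_time[j])
      base <- neurodyn:::peak_prominence(x, p)
      w_oracle <- oracle_half_width(x, p, pk$prominence[j], base$lb, base$rb)
      expect_equal(pk$duration[j], w_oracle, tolerance = 1e-3)
    }
  }
})

test_that("prominence filtering is monotone and intervals contain their anchors", {
  set.seed(52)
  for (i in 1:10) {
    x <- abs(stats::filter(rnorm(300), rep(0.2, 5), circular = TRUE))
    x <- as.numeric(x)
    counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(th)
      nrow(detect_peaks(x, times = seq_along(x), min_prominence = th)), integer(1))
    expect_true(all(diff(counts) <= 0))
    pk <- detect_peaks(x, times = seq_along(x), min_prominence = 0.05)
    if (nrow(pk)) {
      expect_true(all(pk$left_edge < pk$anchor_time & pk$anchor_time < pk$right_edge))
      expect_true(all(pk$prominence <= pk$magnitude + 1e-12))
      expect_true(all(pk$duration > 0))
    }
  }
})

test_that("edge maxima are excluded and masked gaps split the trace", {
  x <- c(5, 1, 0.2, 1, 5)                       # maxima only at the ends
  expect_equal(nrow(detect_peaks(x, times = 1:5, min_prominence = 0.1)), 0L)
  x <- c(0, 1, 0, NA, 0, 2, 0)
  pk <- detect_peaks(x, times = 1:7, min_prominence = 0.5)
  expect_equal(pk$anchor_time, c(2, 6))
  expect_true(all(pk$left_edge >= c(1, 5) & pk$right_edge <= c(3, 7)))
})

test_that("duration-vs-prominence curves follow re-detection", {
  t <- 1:200
  two <- 0.15 * exp(-(t - 60)^2 / 50) + 0.3 * exp(-(t - 150)^2 / 50)
  tab <- duration_vs_magnitude(nd_trace(two, t, window_spec(30), "ni", 3),
                               c(0.05, 0.2, 0.5))
  expect_equal(tab$n_peaks, c(2L, 1L, 0L))
  # rectangular-ish bump: duration stable below its prominence, absent above
  box <- c(rep(0, 50), seq(0, 0.3, length.out = 4), rep(0.3, 40),
           seq(0.3, 0, length.out = 4), rep(0, 50))
  tab <- duration_vs_magnitude(nd_trace(box, seq_along(box), window_spec(30), "ni", 3),
                               c(0.05, 0.1, 0.25, 0.31))
  expect_equal(tab$n_peaks, c(1L, 1L, 1L, 0L))
  durs <- tab$mean_duration[1:3]
  expect_lt(max(durs) - min(durs), 1.5)
  expect_error(duration_vs_magnitude(list(), numeric(0)),
               class = "neurodyn_config_error")
})

test_that("incidence counts peak epochs in the union sense", {
  w <- window_spec(30, 1)
  mk <- function(v) nd_trace(v, seq_along(v), w, "ni", 3)
  # no peaks
  tr <- mk(rep(0, 600))
  expect_equal(incidence(detect_peaks(tr), list(tr))$fraction, 0)
  # one 30-s interval in 600 s -> 0.05 (constructed, then checked vs oracle)
  v <- rep(0, 600)
  v[100:130] <- c(seq(0, 0.4, length.out = 16), seq(0.4, 0, length.out = 16)[-1])
  tr <- mk(v)
  pk <- detect_peaks(tr, min_prominence = 0.1)
  inc <- incidence(pk, list(tr))
  expect_equal(inc$total_epochs, 600L)
  expect_equal(inc$epochs_in_peaks,
               oracle_incidence(tr$time, pk))
  expect_equal(inc$fraction, inc$epochs_in_peaks / 600)
  # ten streams x 600 s with 42 s of peak span each -> 0.07
  fake_pk <- data.frame(anchor_time = 120, magnitude = 0.3, prominence = 0.3,
                        duration = 42, left_edge = 100, right_edge = 141)
  base <- mk(rep(0, 600))
  inc <- incidence(rep(list(fake_pk), 10), rep(list(base), 10))
  expect_equal(inc$fraction, 0.07)
  # overlapping peaks count each second once
  pk2 <- rbind(fake_pk, within(fake_pk, { left_edge <- 120; right_edge <- 161 }))
  inc2 <- incidence(list(pk2), list(base))
  expect_equal(inc2$epochs_in_peaks, length(100:161))
})
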