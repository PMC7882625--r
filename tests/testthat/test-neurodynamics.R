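test_that("windowed entropy matches closed-form histograms", {
  w <- window_spec(60, 1)
  # 60 identical symbols -> H = 0
  expect_equal(windowed_entropy(symbol_stream(rep(3L, 60)), w)$values, 0)
  # 20 of each symbol -> log2(3)
  s <- symbol_stream(rep(c(-1L, 1L, 3L), each = 20))
  expect_equal(windowed_entropy(s, w)$values, log2(3))
  # counts (30, 15, 15) -> 1.5 bits
  s <- symbol_stream(c(rep(-1L, 30), rep(1L, 15), rep(3L, 15)))
  expect_equal(windowed_entropy(s, w)$values, 1.5)
})

test_that("sliding entropy equals the brute-force oracle, masks included", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(80:200, 1)
    L <- sample(c(20, 30, 45), 1)
    sym <- rand_symbols(n)
    sym[sample(n, n %/% 10)] <- NA
    tr <- suppressWarnings(windowed_entropy(symbol_stream(sym), window_spec(L, 1)))
    expect_equal(tr$values, oracle_windowed_entropy(sym, L), tolerance = 1e-12)
  }
})

test_that("NI is maximum entropy minus observed entropy, with bound checks", {
  expect_equal(ni_from_entropy(0, 9), log2(9))          # 3.17 bits
  expect_equal(ni_from_entropy(0, 27), log2(27))        # 4.75 bits
  expect_equal(ni_from_entropy(log2(9), 9), 0)
  expect_equal(ni_from_entropy(log2(3) - 1e-12, 3), 0, tolerance = 1e-9)
  expect_error(ni_from_entropy(2, 3), class = "neurodyn_internal_error")
  expect_error(ni_from_entropy(-0.5, 3), class = "neurodyn_internal_error")
})

test_that("raw NI stays within [0, log2(S)] on random streams", {
  set.seed(32)
  for (i in 1:5) {
    x <- symbol_stream(rand_symbols(400))
    y <- symbol_stream(rand_symbols(400))
    tm <- compose_team(list(x, y))
    for (stream in list(x, tm)) {
      tr <- windowed_ni(stream, window_spec(60, 1))
      S <- if (inherits(stream, "team_stream")) 9 else 3
      expect_true(all(tr$values >= 0 & tr$values <= log2(S) + 1e-12))
    }
  }
})

test_that("randomized baseline is permutation-consistent and reproducible", {
  w <- window_spec(60, 1)
  s <- symbol_stream(rep(1L, 120))
  b <- randomized_baseline(s, w, n_shuffles = 3, seed = 5)
  expect_equal(b$values, windowed_ni(s, w)$values)   # constant stream: invariant
  s2 <- symbol_stream(rand_symbols(300))
  b1 <- randomized_baseline(s2, w, n_shuffles = 4, seed = 9)
  b2 <- randomized_baseline(s2, w, n_shuffles = 4, seed = 9)
  expect_identical(b1$values, b2$values)
  expect_error(randomized_baseline(s2, w, n_shuffles = 0),
               class = "neurodyn_config_error")
})

test_that("baseline of an i.i.d. 3-symbol stream sits at the plug-in bias", {
  # exact expectation 0.0243 bits for S = 3, N = 60 (binomial identity)
  set.seed(33)
  m <- replicate(6, {
    s <- symbol_stream(rand_symbols(900))
    mean(randomized_baseline(s, window_spec(60, 1), n_shuffles = 2)$values)
  })
  expect_lt(abs(mean(m) - oracle_exact_bias(3, 60)), 0.01)
  expect_lt(abs(mean(m) - 0.024), 0.01)
})

test_that("baseline subtraction floors at zero and cancels bias in expectation", {
  w <- window_spec(60, 1)
  set.seed(34)
  s <- symbol_stream(rand_symbols(600))
  raw <- windowed_ni(s, w)
  b <- randomized_baseline(s, w, n_shuffles = 6, seed = 2)
  corr <- subtract_baseline(raw, b)
  expect_true(corr$corrected)
  expect_equal(corr$values, pmax(raw$values - b$values, 0))
  expect_true(all(corr$values >= 0))
  expect_identical(subtract_baseline(raw, raw)$values, rep(0, length(raw$values)))
  # i.i.d. stream: corrected NI averages near zero (floored, so small positive)
  ms <- replicate(5, {
    s <- symbol_stream(rand_symbols(900))
    mean(corrected_ni(s, w, n_shuffles = 6)$values)
  })
  expect_lt(mean(ms), 0.02)
  # mismatched windows refuse to subtract
  raw30 <- suppressWarnings(windowed_ni(s, window_spec(30, 1)))
  expect_error(subtract_baseline(raw30, b), class = "neurodyn_alignment_error")
})

test_that("mean raw NI of i.i.d. uniform windows matches the exact plug-in bias", {
  # independent oracle: E[H] via the binomial identity, every (S, N) cell
  set.seed(35)
  for (S in c(3, 9, 27)) {
    for (N in c(30, 60, 120)) {
      ni <- replicate(150, {
        counts <- tabulate(sample.int(S, N, replace = TRUE), S)
        keep <- counts[counts > 0]
        log2(S) - (log2(N) - sum(keep * log2(keep)) / N)
      })
      se <- sd(ni) / sqrt(length(ni))
      expect_lt(abs(mean(ni) - oracle_exact_bias(S, N)), 4 * se)
    }
  }
})

test_that("shared information decomposes team NI exactly", {
  w <- window_spec(60, 1)
  set.seed(36)
  # identical members: MI equals the member entropy
  v <- rep(c(-1L, 1L, 3L), each = 20)
  x <- symbol_stream(v, member = "G", channel = "C3", bin_hz = 10)
  si <- shared_information(x, symbol_stream(v, member = "F", channel = "C3", bin_hz = 10), window = w)
  expect_equal(si$mi$values, log2(3))
  # independent members: MI within estimator bias of zero
  x <- symbol_stream(rand_symbols(2000), member = "G", channel = "C3", bin_hz = 10)
  y <- symbol_stream(rand_symbols(2000), member = "F", channel = "C3", bin_hz = 10)
  si <- shared_information(x, y, window = w)
  expect_lt(abs(mean(si$mi$values)), 0.15)
  # the identity holds per window to numerical precision
  err <- si$ni_team$values - si$ni_x$values - si$ni_y$values - si$mi$values
  expect_lt(max(abs(err)), 1e-10)
  expect_error(shared_information(x, compose_team(list(x, y))),
               class = "neurodyn_config_error")
})

test_that("NI rises monotonically with symbol persistence", {
  w <- window_spec(60, 1)
  set.seed(37)
  mean_ni <- vapply(c(0.1, 0.5, 0.9), function(pers) {
    cfg <- sim_config(n_members = 1, duration_s = 1200, baseline = "markov",
                      markov_persist = pers, seed = 37)
    s <- simulate_symbols(cfg)$streams[[1]]
    mean(windowed_ni(s, w))
  }, numeric(1))
  expect_true(all(diff(mean_ni) > 0))
})

test_that("aggregation averages the selected stratum and flags empty ones", {
  w <- window_spec(30, 1)
  mk <- function(val, ch, b) nd_trace(rep(val, 5), 30:34, w, "ni", 3,
                                      coords = stream_coords("G", ch, b))
  t1 <- mk(0.1, "C3", 10); t2 <- mk(0.3, "C3", 18); t3 <- mk(0.5, "O1", 10)
  expect_equal(aggregate_ni(list(t1), "scalp")$values, t1$values)
  expect_equal(aggregate_ni(list(t1, t2, t3), "scalp")$values, rep(0.3, 5))
  expect_equal(aggregate_ni(list(t1, t2, t3), "sensor", channel = "C3")$values,
               rep(0.2, 5))
  expect_equal(aggregate_ni(list(t1, t2, t3), "frequency", bin_hz = 10)$values,
               rep(0.3, 5))
  expect_equal(aggregate_ni(list(t1, t2, t3), "region", region = "occipital")$values,
               rep(0.5, 5))
  expect_error(aggregate_ni(list(t1), "sensor", channel = "Pz"),
               class = "neurodyn_config_error")
  # brute-force mean over a 19-channel x 2-bin panel
  set.seed(38)
  chans <- names(region_scheme())
  panel <- list()
  for (ch in chans) for (b in c(10, 18)) {
    panel[[paste(ch, b)]] <- mk(runif(1), ch, b)
  }
  vals <- vapply(panel, function(tr) tr$values[1], numeric(1))
  expect_equal(aggregate_ni(panel, "scalp")$values[1], mean(vals))
})
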