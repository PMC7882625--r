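test_that("tertile symbolization maps equal thirds and is rank-equivariant", {
  expect_equal(symbolize_stream(1:9)$symbols, rep(c(-1L, 1L, 3L), each = 3))
  set.seed(21)
  perm <- sample(9)
  expect_equal(symbolize_stream((1:9)[perm])$symbols,
               rep(c(-1L, 1L, 3L), each = 3)[perm])
  # monotone invariance: any strictly increasing transform gives the same symbols
  set.seed(22)
  x <- rnorm(120)
  expect_equal(symbolize_stream(exp(x))$symbols, symbolize_stream(x)$symbols)
})

test_that("equal occupancy holds exactly, even with heavy ties", {
  set.seed(23)
  x <- exp(rnorm(300))                    # log-normal power
  counts <- table(symbolize_stream(x)$symbols)
  expect_equal(unname(c(counts)), c(100L, 100L, 100L))
  # repeated values: stable time-index tie-break keeps counts within 1
  y <- rep(c(5, 5, 5, 7), length.out = 100)
  counts <- table(symbolize_stream(y)$symbols)
  expect_lte(max(counts) - min(counts), 1L)
  # boundaries are genuine cut points: everything below cut1 is -1 etc.
  s <- symbolize_stream(x)
  expect_true(all(x[s$symbols == -1] <= s$boundaries[1]))
  expect_true(all(x[s$symbols == 3] > s$boundaries[2]))
})

test_that("degenerate and masked inputs are handled", {
  expect_error(symbolize_stream(rep(4, 50)), class = "neurodyn_degenerate_error")
  expect_error(symbolize_stream(c(1, 2)), class = "neurodyn_degenerate_error")
  x <- c(NA, 1:9, NA)
  s <- symbolize_stream(x)
  expect_true(is.na(s$symbols[1]) && is.na(s$symbols[11]))
  expect_equal(s$symbols[2:10], rep(c(-1L, 1L, 3L), each = 3))
})

test_that("team composition follows the base-3 encoding and decodes exactly", {
  mk <- function(v, m) symbol_stream(v, member = m, channel = "C3", bin_hz = 10)
  expect_equal(compose_team(list(mk(-1, "a"), mk(-1, "b")))$symbols, 1L)
  expect_equal(compose_team(list(mk(3, "a"), mk(3, "b")))$symbols, 9L)
  expect_equal(compose_team(list(mk(3, "a"), mk(1, "b")))$symbols, 8L)
  expect_equal(compose_team(list(mk(3, "a"), mk(3, "b"), mk(3, "c")))$symbols, 27L)
  # full enumeration of the dyad bijection against the formula
  alpha <- c(-1L, 1L, 3L)
  for (s1 in alpha) for (s2 in alpha) {
    lab <- compose_team(list(mk(s1, "a"), mk(s2, "b")))$symbols
    expect_equal(lab, 1L + (match(s1, alpha) - 1L) * 3L + (match(s2, alpha) - 1L))
  }
  # encoding table stored on the stream covers all 9 labels once
  tm <- compose_team(list(mk(alpha, "a"), mk(c(3L, -1L, 1L), "b")))
  expect_equal(sort(tm$encoding$label), 1:9)
})

test_that("decoding a team stream recovers each member stream exactly", {
  set.seed(24)
  mk <- function(m) symbol_stream(rand_symbols(200), member = m,
                                  channel = "Fz", bin_hz = 11)
  members <- list(mk("G"), mk("F"), mk("N"))
  for (k in 1:3) {
    tm <- compose_team(members[seq_len(k)])
    dec <- decode_team(tm)
    for (i in seq_len(k)) {
      expect_equal(dec[[i]]$symbols, members[[i]]$symbols)
    }
    expect_equal(sort(unique(tm$symbols[!is.na(tm$symbols)])) %in% 1:(3^k),
                 rep(TRUE, length(unique(tm$symbols[!is.na(tm$symbols)]))))
  }
})

test_that("masked member epochs mask the composite epoch", {
  a <- symbol_stream(c(-1L, NA, 3L, 1L), member = "a", channel = "C3", bin_hz = 10)
  b <- symbol_stream(c(-1L, 1L, NA, 1L), member = "b", channel = "C3", bin_hz = 10)
  tm <- compose_team(list(a, b))
  expect_equal(is.na(tm$symbols), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("misaligned member streams raise alignment errors", {
  a <- symbol_stream(c(-1, 1), channel = "C3", bin_hz = 10)
  b <- symbol_stream(c(-1, 1, 3), channel = "C3", bin_hz = 10)
  expect_error(compose_team(list(a, b)), class = "neurodyn_alignment_error")
  d <- symbol_stream(c(-1, 1), channel = "C4", bin_hz = 10)
  expect_error(compose_team(list(a, d)), class = "neurodyn_alignment_error")
})

test_that("symbol streams round-trip through the long-format table", {
  set.seed(25)
  s1 <- symbol_stream(rand_symbols(50), member = "G", channel = "C3", bin_hz = 10)
  sy <- rand_symbols(50); sy[7] <- NA
  s2 <- symbol_stream(sy, member = "F", channel = "P3", bin_hz = 18)
  f <- tempfile(fileext = ".csv")
  write_symbol_table(list(s1, s2), f)
  back <- read_symbol_table(f)
  expect_equal(length(back), 2L)
  expect_equal(back[["G.C3.10Hz"]]$symbols, s1$symbols)
  expect_equal(back[["F.P3.18Hz"]]$symbols, s2$symbols)
  expect_equal(back[["F.P3.18Hz"]]$coords$bin_hz, 18)
  unlink(f)
})

test_that("symbolizing a PSD tensor yields one stream per channel-bin", {
  fs <- 128
  set.seed(26)
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- rbind(rnorm(length(t)), rnorm(length(t)))
  psd <- welch_psd(raw_eeg(x, fs, c("C3", "C4")), bins = c(10, 18))
  streams <- symbolize_psd(psd, member = "G")
  expect_equal(length(streams), 4L)
  expect_equal(length(streams[["C3.10Hz"]]$symbols), 120L)
  counts <- table(streams[["C4.18Hz"]]$symbols)
  expect_lte(max(counts) - min(counts), 1L)
})
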