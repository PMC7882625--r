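# Independent brute-force oracles, deliberately naive and separate from the
# package's own code paths.

# Histogram -sum(p log2 p) loop.
oracle_entropy <- function(symbols) {
  symbols <- symbols[!is.na(symbols)]
  if (length(symbols) == 0) return(NA_real_)
  h <- 0
  for (u in unique(symbols)) {
    p <- sum(symbols == u) / length(symbols)
    h <- h - p * log2(p)
  }
  h
}

# Windowed entropy by direct per-window recomputation.
oracle_windowed_entropy <- function(symbols, L, min_occ = 0.5) {
  n <- length(symbols)
  out <- numeric(0)
  for (i in seq_len(n - L + 1)) {
    w <- symbols[i:(i + L - 1)]
    w <- w[!is.na(w)]
    out <- c(out, if (length(w) >= ceiling(min_occ * L)) oracle_entropy(w) else NA_real_)
  }
  out
}

# Half-prominence width by dense-grid crossing search around sample p of x
# (uniform unit spacing), bounded by the base interval [lb, rb].
oracle_half_width <- function(x, p, prominence, lb, rb, grid = 1e-4) {
  ref <- x[p] - prominence / 2
  f <- stats::approxfun(seq_along(x), x)
  left <- p
  g <- seq(lb, p, by = grid)
  below <- g[f(g) < ref]
  left <- if (length(below)) max(below) else lb
  g <- seq(p, rb, by = grid)
  below <- g[f(g) < ref]
  right <- if (length(below)) min(below) else rb
  right - left
}

# Interval-union epoch counting.
oracle_incidence <- function(times, intervals) {
  covered <- 0
  for (t in times) {
    inside <- FALSE
    if (nrow(intervals) > 0) {
      for (j in seq_len(nrow(intervals))) {
        if (t >= intervals$left_edge[j] && t <= intervals$right_edge[j]) inside <- TRUE
      }
    }
    covered <- covered + inside
  }
  covered
}

# One-sided raw periodogram density (boxcar), for Parseval cross-checks.
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  ft <- stats::fft(x - mean(x))
  nf <- n %/% 2 + 1
  d <- Mod(ft[1:nf])^2 / (fs * n)
  two <- rep(2, nf); two[1] <- 1
  if (n %% 2 == 0) two[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / n, density = d * two)
}

# Exact expected plug-in NI of an i.i.d. uniform S-symbol window of size N,
# via E[H] = -S * E[(n/N) log2(n/N)], n ~ Binomial(N, 1/S).
oracle_exact_bias <- function(S, N) {
  k <- 0:N
  p <- stats::dbinom(k, N, 1 / S)
  f <- ifelse(k == 0, 0, -(k / N) * log2(k / N))
  log2(S) - S * sum(p * f)
}

# Random ternary stream helper.
rand_symbols <- function(n) sample(c(-1L, 1L, 3L), n, replace = TRUE)
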