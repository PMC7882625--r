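#' @keywords internal
"_PACKAGE"

# Plug-in (maximum-likelihood) Shannon entropy in bits from a count vector.
# Zero counts contribute nothing; n = sum(counts) must be > 0.
entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n <= 0) return(NA_real_)
  c1 <- counts[counts > 0]
  # log2(n) - (1/n) * sum(c * log2(c)) is numerically stabler than -sum(p log p)
  log2(n) - sum(c1 * log2(c1)) / n
}

# Evaluate an expression under a temporary RNG state seeded with `seed`
# (NULL leaves the global stream untouched).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_neurodyn <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "neurodyn_error")))
}

#' Stream coordinate triple
#'
#' The (member, channel, 1-Hz bin) coordinates carried by symbol streams and
#' traces; any field may be `NA` (e.g. aggregates).
#'
#' @param member Member id.
#' @param channel Channel label.
#' @param bin_hz Frequency bin center (Hz).
#' @return A list with fields `member`, `channel`, `bin_hz`.
#' @export
stream_coords <- function(member = NA, channel = NA_character_, bin_hz = NA_real_) {
  list(member = member, channel = channel, bin_hz = bin_hz)
}

coords_label <- function(coords) {
  paste(coords$member, coords$channel, coords$bin_hz, sep = "/")
}
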