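# Independent brute-force oracles. These deliberately share no code with
# the implementation paths they check.

# Exhaustive leftmost suffix/prefix adapter scan on a single read.
oracle_trim_one <- function(bases, adapter, min_overlap, max_mismatch_rate) {
  n <- nchar(bases)
  a <- nchar(adapter)
  for (i in seq_len(n)) {
    o <- min(a, n - i + 1L)
    if (o < min_overlap) next
    mm <- sum(strsplit(substr(bases, i, i + o - 1L), "")[[1]] !=
                strsplit(substr(adapter, 1L, o), "")[[1]])
    if (mm <= max_mismatch_rate * o) return(substr(bases, 1L, i - 1L))
  }
  bases
}

# Naive per-read scan over every transcript (overlapping matches).
oracle_align_one <- function(bases, seq_strings) {
  hits <- list()
  for (g in names(seq_strings)) {
    s <- seq_strings[[g]]
    start <- 1L
    repeat {
      p <- as.integer(regexpr(bases, substr(s, start, nchar(s)), fixed = TRUE))
      if (p == -1L) break
      hits[[length(hits) + 1L]] <- list(gene = g, pos0 = start + p - 2L)
      start <- start + p  # continue after this match start (overlaps allowed)
    }
  }
  hits
}

# Spearman rho by the average-rank formula, from scratch.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Mean-subtracted autocorrelation of a profile at a set of lags.
oracle_autocorr <- function(profile, lags) {
  x <- profile - mean(profile)
  vapply(lags, function(L) {
    n <- length(x) - L
    sum(x[seq_len(n)] * x[seq_len(n) + L]) / n
  }, numeric(1))
}

# Overlapping fixed-string occurrence count.
oracle_count_overlapping <- function(pattern, subject) {
  k <- nchar(pattern)
  n <- nchar(subject)
  if (n < k) return(0L)
  sum(vapply(seq_len(n - k + 1L),
             function(i) substr(subject, i, i + k - 1L) == pattern,
             logical(1)))
}

random_read <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
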