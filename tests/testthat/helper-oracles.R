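# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the implementation they check.

# quantile normalization: explicit sort / average / remap, ties by mean of
# the reference values their sorted positions span
oracle_quantile_normalize <- function(x) {
  n <- nrow(x)
  sorted_cols <- matrix(NA_real_, n, ncol(x))
  for (j in seq_len(ncol(x))) sorted_cols[, j] <- sort(x[, j])
  ref <- numeric(n)
  for (i in seq_len(n)) ref[i] <- mean(sorted_cols[i, ])
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    for (i in seq_len(n)) {
      pos <- which(sort(col) == col[i])  # sorted positions spanned by value
      out[i, j] <- mean(ref[pos])
    }
  }
  out
}

# screen decisions: direct transcription of the two inequalities
oracle_screen <- function(m_s, s_s, m_t, s_t, k = 5, fc_primary = 2.5) {
  n <- length(m_s)
  sel <- logical(n)
  dir <- character(n)
  for (i in seq_len(n)) {
    consistency <- abs(m_t[i] - m_s[i]) >= k * (s_t[i] + s_s[i])
    fc <- m_t[i] / m_s[i]
    fc_ok <- fc >= fc_primary || fc <= 1 / fc_primary
    sel[i] <- m_s[i] > 0 && m_t[i] > 0 && consistency && fc_ok
    dir[i] <- if (!sel[i]) "none" else if (m_t[i] > m_s[i]) "up" else "down"
  }
  list(selected = sel, direction = dir)
}

# worst-case pooled-t p over an SD grid, criterion held at equality
oracle_t_bound_grid <- function(k, n, grid = 100) {
  worst <- 0
  for (a in seq_len(grid)) {
    for (b in seq_len(grid)) {
      s_s <- a / grid
      s_t <- b / grid
      delta <- k * (s_s + s_t)
      sp <- sqrt((s_s^2 + s_t^2) / 2)
      tstat <- delta / (sp * sqrt(2 / n))
      p <- 2 * stats::pt(-tstat, 2 * n - 2)
      if (p > worst) worst <- p
    }
  }
  worst
}

# distinct-algorithm tally by nested loops
oracle_tally <- function(tab) {
  pairs <- unique(tab[c("mirna", "gene")])
  counts <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    hit <- tab$mirna == pairs$mirna[i] & tab$gene == pairs$gene[i]
    counts[i] <- length(unique(tab$algorithm[hit]))
  }
  pairs$n_algorithms <- counts
  pairs[order(pairs$mirna, pairs$gene), ]
}

# threshold interpolation oracle: first crossing, log-linear via approx()
oracle_threshold <- function(forces, freqs, q = 50) {
  if (freqs[1] >= q) return(list(threshold = forces[1], censoring = "left"))
  for (i in seq_along(forces)[-1]) {
    if (freqs[i - 1] < q && freqs[i] >= q) {
      lg <- stats::approx(x = c(freqs[i - 1], freqs[i]),
                          y = log10(c(forces[i - 1], forces[i])),
                          xout = q)$y
      return(list(threshold = 10^lg, censoring = "none"))
    }
  }
  list(threshold = forces[length(forces)], censoring = "right")
}

default_filaments <- c(0.02, 0.07, 0.16, 0.4, 1.0)
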