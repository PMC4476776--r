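# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Optimal string alignment (restricted Damerau-Levenshtein) distance:
# substitutions, insertions, deletions and adjacent transpositions each
# cost 1. Used to verify the typo generator's single-keystroke contract.
osa_distance <- function(a, b) {
  s <- strsplit(a, "")[[1]]
  t <- strsplit(b, "")[[1]]
  n <- length(s); m <- length(t)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- as.integer(s[i] != t[j])
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
      if (i > 1 && j > 1 && s[i] == t[j - 1] && s[i - 1] == t[j])
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
    }
  }
  d[n + 1, m + 1]
}

# Log-likelihood of a two-component normal mixture, direct form.
mixture_loglik <- function(x, p, mu1, sd1, mu2, sd2) {
  sum(log(p * dnorm(x, mu1, sd1) + (1 - p) * dnorm(x, mu2, sd2)))
}

# Brute-force grid search over (pi, mu1, mu2) at fixed SDs: the small-n
# oracle for the EM fit.
mixture_grid_search <- function(x, sd1, sd2) {
  best <- -Inf
  mus <- seq(min(x), max(x), length.out = 25)
  for (p in seq(0.1, 0.9, by = 0.1))
    for (m1 in mus)
      for (m2 in mus) {
        if (m1 >= m2) next
        ll <- mixture_loglik(x, p, m1, sd1, m2, sd2)
        if (ll > best) best <- ll
      }
  best
}

# Closed-form bivariate Gaussian KDE (bandwidth h on both axes) at a point.
kde_at <- function(px, py, xs, ys, h) {
  mean(dnorm(px, xs, h) * dnorm(py, ys, h))
}

# Quick labelled message table builder.
make_messages <- function(vessel_id, speed,
                          lon = 11, lat = 57.6,
                          t0 = as.POSIXct("2024-03-01", tz = "UTC"),
                          interval = 300, label = NULL) {
  n <- max(length(vessel_id), length(speed), length(lon), length(lat))
  out <- data.frame(
    msg_id = sprintf("T%05d", seq_len(n)),
    vessel_id = rep_len(vessel_id, n),
    timestamp = t0 + (seq_len(n) - 1) * interval,
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    speed = rep_len(speed, n), stringsAsFactors = FALSE)
  if (!is.null(label)) out$label <- rep_len(label, n)
  out
}
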