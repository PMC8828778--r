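# Independent brute-force oracles, written from the stated rules directly and
# kept free of any package internals.

# Literal event-rule oracle over a distance vector.
# Formation: earliest f with frames f, f+1, f+2 all defined and <= coloc.
# Disruption after f: the first frame j > f that either exceeds `hard`, or is
# a loss (> coloc, defined) with an earlier loss l such that j - l <= window-1
# (i.e. at least two losses within `window` consecutive frames). After a
# disruption, restart the formation scan at the next frame.
oracle_events <- function(distance, coloc = 0.4, hard = 0.6, window = 4L,
                          min_run = 3L) {
  n <- length(distance)
  is_co <- function(j) !is.na(distance[j]) && distance[j] <= coloc
  is_loss <- function(j) !is.na(distance[j]) && distance[j] > coloc
  formation <- integer(0)
  disruption <- integer(0)
  start <- 1L
  repeat {
    f <- NA_integer_
    for (cand in start:n) {
      if (cand + min_run - 1L > n) break
      if (all(vapply(cand:(cand + min_run - 1L), is_co, TRUE))) {
        f <- cand
        break
      }
    }
    if (is.na(f)) break
    formation <- c(formation, f)
    d <- NA_integer_
    losses <- integer(0)
    if (f < n) {
      for (j in (f + 1L):n) {
        if (!is.na(distance[j]) && distance[j] > hard) { d <- j; break }
        if (is_loss(j)) {
          if (any(j - losses <= window - 1L)) { d <- j; break }
          losses <- c(losses, j)
        }
      }
    }
    if (is.na(d)) break
    disruption <- c(disruption, d)
    start <- d + 1L
    if (start > n) break
  }
  list(formation_frames = formation, disruption_frames = disruption)
}

# run the package's event caller on a bare distance vector
run_machine_on <- function(d, ...) {
  tr <- distance_trace(seq(0, by = 10, length.out = length(d)), d)
  ev <- call_events(tr, ...)
  list(formation_frames = ev$formation_frames,
       disruption_frames = ev$disruption_frames)
}

# analytic CDF of a two-component exponential mixture
mixture_cdf <- function(t, t1, t2, A1) {
  A1 * (1 - exp(-t / t1)) + (1 - A1) * (1 - exp(-t / t2))
}

# Kolmogorov-Smirnov distance of a sample against an analytic CDF
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

# exhaustive minimum cross-pair distance
brute_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    best <- min(best, sqrt((a$x_um[i] - b$x_um[j])^2 + (a$y_um[i] - b$y_um[j])^2))
  }
  best
}

# enumerate all sequences of given length over an alphabet, as a matrix
enumerate_sequences <- function(len, alphabet) {
  as.matrix(expand.grid(rep(list(alphabet), len)))
}
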