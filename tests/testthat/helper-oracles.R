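# Independent oracles used across the suite.  These deliberately re-derive
# results with different code shapes than the package implementations.

# Literal per-interval transcription of the published occupancy rules:
# forward scan with explicit back-scoring of beam-1-only runs and one-step
# lookahead for indeterminate (empty) intervals.  Units: 10-s interval
# indices, 0-based entry / exclusive exit.
oracle_occupancy <- function(masks) {
  n <- length(masks)
  inner <- function(i) bitwAnd(masks[i], 30L) > 0L
  any_beam <- function(i) masks[i] > 0L
  door_only <- function(i) masks[i] == 1L
  inside <- rep(FALSE, n)
  i <- 1L
  while (i <= n) {
    if (!inner(i)) { i <- i + 1L; next }
    # entry: this interval qualifies; back-score an immediately preceding
    # run of beam-1-only intervals
    inside[i] <- TRUE
    j <- i - 1L
    while (j >= 1L && door_only(j) && !inside[j]) {
      inside[j] <- TRUE
      j <- j - 1L
    }
    # continue the bout
    k <- i + 1L
    while (k <= n) {
      if (any_beam(k)) { inside[k] <- TRUE; k <- k + 1L; next }
      if (k == n) { inside[k] <- TRUE; k <- k + 1L; break }  # trailing
      if (any_beam(k + 1L)) {
        inside[k] <- TRUE
        inside[k + 1L] <- TRUE
        k <- k + 2L
        next
      }
      break                                   # two consecutive empties
    }
    i <- k
  }
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(entry = starts[r$values], exit = ends[r$values])
}

# scoring a mask sequence with the package implementation, in index units
score_idx <- function(masks, ...) gaspref:::score_masks(masks, ...)

# brute-force windowed mean
oracle_bin_means <- function(x, times, width) {
  n_bins <- floor((max(times) + (times[2] - times[1])) / width)
  vapply(seq_len(n_bins), function(b) {
    mean(x[times >= (b - 1) * width & times < b * width])
  }, numeric(1))
}

# two-sided Fisher p via the stats hypergeometric distribution
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  d <- stats::dhyper(k, r1, r2, c1)
  sum(d[d <= stats::dhyper(tab[1, 1], r1, r2, c1) * (1 + 1e-7)])
}

# closed-form least squares via the normal equations
oracle_wls <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))

# random valid occupancy interval sets on the 10-s grid (>= 30 s bouts,
# >= 20 s gaps)
random_intervals <- function(session_length, max_bouts = 5) {
  n <- session_length / 10
  iv <- list()
  pos <- 0
  for (b in seq_len(sample(0:max_bouts, 1))) {
    start <- pos + sample(2:6, 1)            # leave >= 20 s gap
    len <- sample(3:12, 1)
    if ((start + len) * 10 > session_length) break
    iv[[length(iv) + 1]] <- data.frame(entry = start * 10,
                                       exit = (start + len) * 10)
    pos <- start + len
  }
  if (!length(iv)) return(data.frame(entry = numeric(0), exit = numeric(0)))
  do.call(rbind, iv)
}

# small deterministic config for fast tests
test_config <- function(...) {
  cohort_config(n_squads = 2L, rats_per_squad = 6L,
                phase_baseline_min = 30, phase_n2o_min = 60,
                phase_recovery_min = 12, ...)
}
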