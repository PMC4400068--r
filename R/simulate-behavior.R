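#' Simulate one dyad's time allocation for one rat
#'
#' Draws the 3-part composition (N2O chamber, control chamber, central tub)
#' for a 44-h dyad from a logistic-normal model on the two log-ratios
#' `log(t_n2o / t_central)` and `log(t_control / t_central)`.  Their contrast
#' (the log preference ratio, which is what the inferential models analyse)
#' has mean
#' `baseline_logratio + group_effect_logratio * 1{II} + dyad_slope * dyad +
#' pref_intercept`, with residual SD `within_rat_sd`; the rat-level intercept
#' carries the within-rat correlation.  The inverse log-ratio transform is
#' then rescaled so the three times close to the fixed dyad total.
#'
#' @param rat one row of [simulate_cohort()] with a `phenotype` of `"IS"` or
#'   `"II"` and a `pref_intercept`.
#' @param dyad dyad index in `1..config$n_dyads`.
#' @param config a [cohort_config()].
#' @return one-row data.frame: `rat_id`, `group`, `dyad`, `t_n2o`,
#'   `t_control`, `t_central` (seconds), `water_location`.
#' @export
simulate_time_allocation <- function(rat, dyad, config) {
  if (length(dyad) != 1L || dyad < 1 || dyad > config$n_dyads)
    stop("'dyad' must lie in 1..n_dyads", call. = FALSE)
  total <- session_totals(config)$dyad_s
  contrast <- config$baseline_logratio +
    config$group_effect_logratio * (rat$phenotype == "II") +
    config$dyad_slope * dyad +
    rat$pref_intercept +
    stats::rnorm(1, 0, config$within_rat_sd)
  lr_control <- stats::rnorm(1, config$control_central_logratio,
                             config$control_central_sd)
  lr_n2o <- lr_control + contrast
  w <- c(exp(lr_n2o), exp(lr_control), 1)
  times <- total * w / sum(w)
  data.frame(rat_id = rat$rat_id,
             group = rat$phenotype,
             dyad = as.integer(dyad),
             t_n2o = times[1], t_control = times[2], t_central = times[3],
             water_location = if (dyad <= 4) "side_chambers" else "central_tub",
             stringsAsFactors = FALSE)
}

#' Simulate the full behavioural dyad table for a cohort
#'
#' @param config a [cohort_config()].
#' @param rats optional cohort data.frame; defaults to a fresh balanced
#'   cohort (2 IS + 2 II per squad).
#' @param dyads dyad indices to generate (default all).
#' @param seed optional integer seed.
#' @return data.frame of dyad compositions, one row per rat per dyad.
#' @export
simulate_dyad_table <- function(config, rats = NULL,
                                dyads = seq_len(config$n_dyads),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rats)) rats <- simulate_cohort(config, "balanced")
  out <- vector("list", nrow(rats) * length(dyads))
  j <- 0L
  for (i in seq_len(nrow(rats))) {
    for (d in dyads) {
      j <- j + 1L
      out[[j]] <- simulate_time_allocation(rats[i, ], d, config)
    }
  }
  do.call(rbind, out)
}

#' Synthesize raw beam-scan records from known occupancy intervals
#'
#' Inverse of [score_chamber_occupancy()]: given ground-truth residence
#' intervals, emits one beam-scan record per 10-s logging interval.  Inside a
#' bout every scan contains at least one of the four inner beams (2-5), so
#' the scoring algorithm recovers the intervals exactly; with probability
#' `dropout_prob` an interior scan of a bout is blanked (never the first or
#' last scan of the bout, never two in a row), which the algorithm's
#' single-interval bridging rule absorbs.
#'
#' @param intervals data.frame with `entry`, `exit` (seconds), non-overlapping,
#'   multiples of 10, each at least 30 s, separated by at least 20 s.
#' @param session_length session length in seconds (multiple of 10).
#' @param dropout_prob per-scan probability of an absorbable blank.
#' @param seed optional integer seed.
#' @return data.frame with `interval_start` and `beams` (5-char bitstring,
#'   beam 1 first), one row per 10-s interval of the session.
#' @export
synthesize_beam_scans <- function(intervals, session_length,
                                  dropout_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(session_length > 0, session_length %% 10 == 0)
  n <- session_length / 10
  masks <- integer(n)
  if (nrow(intervals)) {
    iv <- intervals[order(intervals$entry), , drop = FALSE]
    if (any(iv$entry %% 10 != 0 | iv$exit %% 10 != 0))
      stop("intervals must align to the 10-s grid", call. = FALSE)
    if (any(iv$exit - iv$entry < 30))
      stop("each interval must last at least 30 s", call. = FALSE)
    if (any(iv$entry < 0) || any(iv$exit > session_length))
      stop("intervals must fall within the session", call. = FALSE)
    if (nrow(iv) > 1 && any(iv$entry[-1] - iv$exit[-nrow(iv)] < 20))
      stop("intervals must be separated by at least 20 s", call. = FALSE)
    for (b in seq_len(nrow(iv))) {
      idx <- (iv$entry[b] / 10 + 1):(iv$exit[b] / 10)
      # one inner beam always, door beam sometimes
      inner <- bitwShiftL(1L, sample(1:4, length(idx), replace = TRUE))
      door <- ifelse(stats::runif(length(idx)) < 0.3, 1L, 0L)
      m <- bitwOr(inner, door)
      if (dropout_prob > 0 && length(idx) > 2) {
        interior <- 2:(length(idx) - 1)
        drop <- stats::runif(length(interior)) < dropout_prob
        # never blank two consecutive scans
        for (i in seq_along(interior)[-1])
          if (drop[i] && drop[i - 1]) drop[i] <- FALSE
        m[interior[drop]] <- 0L
      }
      masks[idx] <- m
    }
  }
  data.frame(interval_start = seq(0, session_length - 10, by = 10),
             beams = mask_to_bitstring(masks),
             stringsAsFactors = FALSE)
}

#' Convert between beam bitstrings and integer masks
#'
#' Beam scans are stored as 5-character bitstrings (`"10010"`), beam 1 (the
#' door beam) first.  Internally bit `b - 1` of an integer mask encodes beam
#' `b`.
#'
#' @param beams character vector of 5-char bitstrings.
#' @return integer mask vector.
#' @export
bitstring_to_mask <- function(beams) {
  if (!all(grepl("^[01]{5}$", beams)))
    stop("beam fields must be 5-character bitstrings of 0/1", call. = FALSE)
  m <- integer(length(beams))
  for (b in 1:5)
    m <- m + bitwShiftL(as.integer(substr(beams, b, b) == "1"), b - 1L)
  m
}

#' @rdname bitstring_to_mask
#' @param masks integer mask vector (0-31).
#' @export
mask_to_bitstring <- function(masks) {
  stopifnot(all(masks >= 0 & masks <= 31))
  vapply(masks, function(m)
    paste(ifelse(bitwAnd(m, bitwShiftL(1L, 0:4)) > 0, "1", "0"),
          collapse = ""), character(1))
}
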