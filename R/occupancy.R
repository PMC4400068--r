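#' Score chamber occupancy from beam-scan records
#'
#' Implements the bout-scoring state machine for a five-beam side chamber.
#' Beam 1 sits 4 cm from the door; beams 2-5 are the four beams furthest from
#' the door.  Working over consecutive 10-s logging intervals:
#'
#' * ENTRY: an interval with any inner beam (2-5) broken puts the rat inside,
#'   with entry at that interval's start.  A maximal run of beam-1-only
#'   intervals immediately before it is also scored inside if and only if
#'   that inner-beam interval follows; by default the entry time backs up to
#'   the start of the run (`entry_at_inner_beam = TRUE` restricts entry to
#'   the inner-beam interval instead).
#' * WHILE INSIDE: any beam break keeps the rat inside.  A single empty
#'   interval is indeterminate and resolves inside iff the next interval has
#'   any beam break; two consecutive empty intervals end the bout, with exit
#'   at the end of the last interval that qualified as inside.
#' * A bout still open at session end is closed there; a single trailing
#'   indeterminate interval at session end counts as inside (no next interval
#'   exists to disqualify it).
#'
#' Each bout increments the door-entry count once.
#'
#' @param scans data.frame with `interval_start` (seconds, multiples of 10,
#'   strictly increasing) and `beams` (5-char bitstrings or integer masks
#'   0-31).  Missing logging intervals are treated as empty scans (with a
#'   warning).
#' @param session_length session length in seconds (multiple of 10).
#' @param entry_at_inner_beam if `TRUE`, do not back-date entry over a
#'   preceding beam-1-only run.
#' @return data.frame with `bout`, `entry`, `exit` (seconds); attributes
#'   `door_count` (number of bouts) and `total_s` (summed residence time).
#' @export
score_chamber_occupancy <- function(scans, session_length,
                                    entry_at_inner_beam = FALSE) {
  stopifnot(session_length > 0, session_length %% 10 == 0)
  n <- session_length / 10
  st <- scans$interval_start
  if (any(st %% 10 != 0)) stop("interval_start must be multiples of 10 s",
                               call. = FALSE)
  if (any(st < 0 | st >= session_length))
    stop("interval_start outside the session", call. = FALSE)
  if (anyDuplicated(st)) stop("duplicate interval_start", call. = FALSE)
  if (is.unsorted(st, strictly = TRUE)) stop("scans must be sorted",
                                             call. = FALSE)
  masks <- if (is.character(scans$beams)) bitstring_to_mask(scans$beams)
           else as.integer(scans$beams)
  if (any(masks < 0 | masks > 31)) stop("beam masks must lie in 0..31",
                                        call. = FALSE)
  full <- integer(n)
  full[st / 10 + 1L] <- masks
  if (length(st) < n)
    warning(sprintf("%d missing scan records treated as empty scans",
                    n - length(st)), call. = FALSE)
  iv <- score_masks(full, back_date = !entry_at_inner_beam)
  out <- data.frame(bout = seq_len(nrow(iv)),
                    entry = iv$entry * 10, exit = iv$exit * 10)
  attr(out, "door_count") <- nrow(out)
  attr(out, "total_s") <- sum(out$exit - out$entry)
  out
}

# Core state machine over the run-length encoding of interval classes
# (0 = empty, 1 = beam-1 only, 2 = any inner beam).  Index units are 10-s
# intervals, 0-based start / exclusive end.
score_masks <- function(masks, back_date = TRUE) {
  cls <- ifelse(masks == 0L, 0L, ifelse(bitwAnd(masks, 30L) > 0L, 2L, 1L))
  r <- rle(cls)
  v <- r$values
  l <- r$lengths
  nr <- length(v)
  starts <- cumsum(c(0L, l[-nr]))
  ends <- starts + l
  entry_v <- integer(0)
  exit_v <- integer(0)
  inside <- FALSE
  pending <- NA_integer_                 # start of a candidate beam-1 run
  entry <- NA_integer_
  exit <- NA_integer_
  for (i in seq_len(nr)) {
    if (!inside) {
      if (v[i] == 2L) {
        inside <- TRUE
        entry <- if (back_date && !is.na(pending)) pending else starts[i]
        exit <- ends[i]
        pending <- NA_integer_
      } else if (v[i] == 1L) {
        pending <- starts[i]             # scored inside only if an inner
      } else {                           # beam interval comes next
        pending <- NA_integer_
      }
    } else {
      if (v[i] != 0L) {
        exit <- ends[i]
      } else if (l[i] == 1L && i < nr) {
        exit <- ends[i]                  # indeterminate, bridged by next run
      } else {
        if (l[i] == 1L && i == nr) exit <- ends[i]  # trailing indeterminate
        inside <- FALSE
        entry_v <- c(entry_v, entry)
        exit_v <- c(exit_v, exit)
      }
    }
  }
  if (inside) {
    entry_v <- c(entry_v, entry)
    exit_v <- c(exit_v, exit)
  }
  data.frame(entry = entry_v, exit = exit_v)
}

#' Per-session compartment times
#'
#' Sums residence intervals per side and attributes the remaining session
#' time to the central tub.
#'
#' @param n2o_intervals,control_intervals interval data.frames (`entry`,
#'   `exit`) for the side receiving N2O and the control side.
#' @param session_length session length in seconds.
#' @return named numeric vector `c(t_n2o, t_control, t_central)`.
#' @export
session_times <- function(n2o_intervals, control_intervals, session_length) {
  check_iv <- function(iv) {
    if (!nrow(iv)) return(0)
    if (any(iv$exit <= iv$entry)) stop("exit must exceed entry", call. = FALSE)
    o <- order(iv$entry)
    if (nrow(iv) > 1 && any(iv$entry[o][-1] < iv$exit[o][-nrow(iv)]))
      stop("overlapping intervals within one side", call. = FALSE)
    sum(iv$exit - iv$entry)
  }
  t_n2o <- check_iv(n2o_intervals)
  t_control <- check_iv(control_intervals)
  both <- rbind(n2o_intervals[c("entry", "exit")],
                control_intervals[c("entry", "exit")])
  if (nrow(both) > 1) {
    o <- order(both$entry)
    if (any(both$entry[o][-1] < both$exit[o][-nrow(both)]))
      stop("rat scored in both side chambers at once", call. = FALSE)
  }
  t_central <- session_length - t_n2o - t_control
  if (t_central < 0) stop("side times exceed session length", call. = FALSE)
  c(t_n2o = t_n2o, t_control = t_control, t_central = t_central)
}

#' Assemble 44-h dyad compositions from per-session summaries
#'
#' Pairs consecutive daily sessions (days 1-2 form dyad 1, and so on), maps
#' physical sides to gas conditions using the daily N2O side assignment, and
#' sums compartment times across the two sessions of each dyad.  The N2O side
#' must alternate within a dyad, which equates N2O availability on both sides
#' and cancels any side preference.  Dyads 1-4 are labelled with water in the
#' side chambers, dyads 5-8 with water in the central tub.
#'
#' A dyad with a missing session is emitted with `missing = TRUE` and `NA`
#' times (never zero-filled), and a message is logged.
#'
#' @param sessions data.frame with columns `rat_id`, `day` (1-based),
#'   `n2o_side` (`"left"`/`"right"`), `t_left`, `t_right`, `session_length_s`,
#'   and optionally `group`.
#' @return data.frame of dyad compositions with a `missing` flag.
#' @export
build_dyads <- function(sessions) {
  stopifnot(all(c("rat_id", "day", "n2o_side", "t_left", "t_right",
                  "session_length_s") %in% names(sessions)))
  out <- list()
  for (rid in unique(sessions$rat_id)) {
    ss <- sessions[sessions$rat_id == rid, ]
    grp <- if ("group" %in% names(ss)) ss$group[1] else NA_character_
    for (d in seq_len(ceiling(max(ss$day) / 2))) {
      days <- c(2L * d - 1L, 2L * d)
      pair <- ss[ss$day %in% days, ]
      total <- 2 * pair$session_length_s[1]
      if (nrow(pair) < 2L) {
        message(sprintf("rat %s dyad %d: missing session, composition flagged",
                        rid, d))
        out[[length(out) + 1L]] <- data.frame(
          rat_id = rid, group = grp, dyad = d,
          t_n2o = NA_real_, t_control = NA_real_, t_central = NA_real_,
          water_location = if (d <= 4) "side_chambers" else "central_tub",
          missing = TRUE, stringsAsFactors = FALSE)
        next
      }
      if (pair$n2o_side[1] == pair$n2o_side[2])
        stop(sprintf("rat %s dyad %d: N2O side did not alternate", rid, d),
             call. = FALSE)
      t_n2o <- sum(ifelse(pair$n2o_side == "left", pair$t_left, pair$t_right))
      t_control <- sum(ifelse(pair$n2o_side == "left", pair$t_right,
                              pair$t_left))
      total <- sum(pair$session_length_s)
      out[[length(out) + 1L]] <- data.frame(
        rat_id = rid, group = grp, dyad = d,
        t_n2o = t_n2o, t_control = t_control,
        t_central = total - t_n2o - t_control,
        water_location = if (d <= 4) "side_chambers" else "central_tub",
        missing = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Extreme imputations for missing dyads
#'
#' Sensitivity-analysis device for dyads lost to equipment failure: returns a
#' minimum-preference variant (the missing dyad's N2O time set to the
#' detection floor, the remainder split between control and central) and a
#' maximum-preference variant (N2O time set to the dyad total minus the floor
#' allowances).  Re-fitting the preference model on both variants brackets
#' the influence the missing data could have had.
#'
#' @param dyads dyad table from [build_dyads()] (or with `NA` times).
#' @param total the fixed dyad total in seconds.
#' @param floor detection floor in seconds.
#' @return list with data.frames `min` and `max`; non-missing rows are
#'   untouched, imputed rows keep `missing = TRUE`.
#' @export
impute_missing_extremes <- function(dyads, total, floor = 5) {
  miss <- if ("missing" %in% names(dyads)) dyads$missing | is.na(dyads$t_n2o)
          else is.na(dyads$t_n2o)
  if (all(miss)) stop("no non-missing dyads to anchor imputation",
                      call. = FALSE)
  lo <- hi <- dyads
  lo$t_n2o[miss] <- floor
  lo$t_control[miss] <- total - 2 * floor
  lo$t_central[miss] <- floor
  hi$t_n2o[miss] <- total - 2 * floor
  hi$t_control[miss] <- floor
  hi$t_central[miss] <- floor
  list(min = lo, max = hi)
}
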