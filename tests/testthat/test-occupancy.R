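scan_df <- function(beams) {
  data.frame(interval_start = seq(0, by = 10, length.out = length(beams)),
             beams = beams, stringsAsFactors = FALSE)
}

test_that("hand-traced scan sequences score as the published rules dictate", {
  # inner beam then two empties: 10 s, exit at end of the qualifying interval
  s <- score_chamber_occupancy(scan_df(c("01000", "00000", "00000")), 30)
  expect_equal(s[c("entry", "exit")], data.frame(entry = 0, exit = 10))

  # beam-1-only never followed by an inner beam: no occupancy at all
  s <- score_chamber_occupancy(scan_df(c("10000", "00000", "00000")), 30)
  expect_equal(nrow(s), 0L)
  expect_equal(attr(s, "door_count"), 0L)

  # beam-1 run back-scored; single empty bridged by the next break
  s <- score_chamber_occupancy(scan_df(
    c("10000", "10000", "00100", "00000", "01000", "00000", "00000")), 70)
  expect_equal(s[c("entry", "exit")], data.frame(entry = 0, exit = 50))
  expect_equal(attr(s, "total_s"), 50)
  expect_equal(attr(s, "door_count"), 1L)

  # entry_at_inner_beam drops the back-scored run
  s <- score_chamber_occupancy(scan_df(
    c("10000", "10000", "00100", "00000", "00000")), 50,
    entry_at_inner_beam = TRUE)
  expect_equal(s[c("entry", "exit")], data.frame(entry = 20, exit = 30))

  # bout still open at session end closes there; trailing single empty is in
  s <- score_chamber_occupancy(scan_df(c("00010", "10000", "00000")), 30)
  expect_equal(s[c("entry", "exit")], data.frame(entry = 0, exit = 30))

  # two bouts, counted separately
  s <- score_chamber_occupancy(scan_df(
    c("00100", "00000", "00000", "00000", "10000", "01000", "00100")), 70)
  expect_equal(s$entry, c(0, 40))
  expect_equal(s$exit, c(10, 70))
  expect_equal(attr(s, "door_count"), 2L)
})

test_that("scorer validates its input", {
  expect_error(score_chamber_occupancy(
    data.frame(interval_start = c(0, 0), beams = c("01000", "00100")), 30),
    "duplicate")
  expect_error(score_chamber_occupancy(
    data.frame(interval_start = c(10, 0), beams = c("01000", "00100")), 30),
    "sorted")
  expect_error(score_chamber_occupancy(
    data.frame(interval_start = 5, beams = "01000"), 30), "multiples")
  expect_warning(score_chamber_occupancy(
    data.frame(interval_start = 0, beams = "01000"), 50), "missing")
})

test_that("scorer agrees with the literal-transcription oracle", {
  # exhaustive over the scorer's effective alphabet (empty / door-only /
  # inner) for all sequences up to length 6
  reps <- c(0L, 1L, 6L)
  for (len in 1:6) {
    grids <- do.call(expand.grid, rep(list(reps), len))
    for (r in seq_len(nrow(grids))) {
      masks <- as.integer(grids[r, ])
      expect_equal(score_idx(masks), oracle_occupancy(masks))
    }
  }
  # exhaustive over all 32 beam subsets at shorter lengths
  for (len in 1:2) {
    grids <- do.call(expand.grid, rep(list(0:31), len))
    for (r in seq_len(nrow(grids))) {
      masks <- as.integer(grids[r, ])
      expect_equal(score_idx(masks), oracle_occupancy(masks))
    }
  }
  # random full-mask sequences at lengths 3-6, also checking that scoring
  # depends on a mask only through its empty/door-only/inner class
  set.seed(2024)
  to_class_rep <- function(m) reps[1L + ifelse(m == 0L, 0L,
                                        ifelse(bitwAnd(m, 30L) > 0L, 2L, 1L))]
  for (i in 1:3000) {
    masks <- sample(0:31, sample(3:6, 1), replace = TRUE)
    expect_equal(score_idx(masks), oracle_occupancy(masks))
    expect_equal(score_idx(masks), score_idx(to_class_rep(masks)))
  }
})

test_that("adding beam breaks never decreases total scored time", {
  set.seed(55)
  total_time <- function(masks) {
    iv <- score_idx(masks)
    10 * sum(iv$exit - iv$entry)
  }
  for (i in 1:300) {
    masks <- sample(0:31, 12, replace = TRUE, prob = c(8, rep(1, 31)))
    pos <- sample(12, 1)
    more <- bitwOr(masks[pos], sample(1:31, 1))
    masks2 <- masks
    masks2[pos] <- more
    expect_gte(total_time(masks2), total_time(masks))
  }
})

test_that("session times partition the session", {
  expect_equal(session_times(data.frame(entry = numeric(0),
                                        exit = numeric(0)),
                             data.frame(entry = numeric(0),
                                        exit = numeric(0)), 79200),
               c(t_n2o = 0, t_control = 0, t_central = 79200))
  expect_equal(session_times(data.frame(entry = 0, exit = 10),
                             data.frame(entry = numeric(0),
                                        exit = numeric(0)), 79200),
               c(t_n2o = 10, t_control = 0, t_central = 79190))
  set.seed(9)
  for (i in 1:25) {
    a <- random_intervals(2000)
    st <- session_times(a, data.frame(entry = numeric(0),
                                      exit = numeric(0)), 2000)
    expect_equal(sum(st), 2000)
  }
  expect_error(session_times(data.frame(entry = 0, exit = 100),
                             data.frame(entry = 50, exit = 150), 2000),
               "both side chambers")
})

test_that("dyads sum mapped side times across alternated sessions", {
  base <- data.frame(rat_id = "r1", day = 1:2, n2o_side = c("left", "right"),
                     t_left = c(100, 100), t_right = c(30, 30),
                     session_length_s = 79200)
  d <- build_dyads(base)
  # all time in the left tube, N2O side alternating: half N2O half control
  expect_equal(d$t_n2o, 130)
  expect_equal(d$t_control, 130)
  expect_equal(d$t_n2o + d$t_control + d$t_central, 2 * 79200)
  expect_equal(d$water_location, "side_chambers")

  # two identical sessions double the composition
  same <- base
  same$t_left <- 200
  same$t_right <- 40
  d2 <- build_dyads(same)
  expect_equal(d2$t_n2o, 240)

  # non-alternating N2O side is an error
  bad <- base
  bad$n2o_side <- "left"
  expect_error(build_dyads(bad), "alternate")

  # a missing session yields a flagged, NA composition - never zeros
  expect_message(d3 <- build_dyads(base[1, ]), "missing")
  expect_true(d3$missing)
  expect_true(is.na(d3$t_n2o))
})

test_that("extreme imputation brackets only the missing dyads", {
  dy <- data.frame(rat_id = c("a", "a"), group = "II", dyad = c(1, 2),
                   t_n2o = c(1000, NA), t_control = c(2000, NA),
                   t_central = c(155400, NA),
                   water_location = "side_chambers",
                   missing = c(FALSE, TRUE))
  imp <- impute_missing_extremes(dy, total = 158400, floor = 5)
  expect_equal(imp$min[1, ], imp$max[1, ])       # untouched row
  expect_equal(imp$min$t_n2o[2], 5)
  expect_equal(imp$max$t_n2o[2], 158400 - 10)
  expect_equal(sum(imp$min[2, c("t_n2o", "t_control", "t_central")]), 158400)
  expect_equal(sum(imp$max[2, c("t_n2o", "t_control", "t_central")]), 158400)

  none <- impute_missing_extremes(dy[1, ], total = 158400)
  expect_equal(none$min, none$max)
  expect_error(impute_missing_extremes(dy[2, ], total = 158400),
               "non-missing")
})
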