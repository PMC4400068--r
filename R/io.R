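#' Write / read beam-scan logs
#'
#' CSV dialect: one row per 10-s logging interval per side chamber with
#' columns `rat_id`, `day`, `side` (`left`/`right`), `interval_start_s`,
#' `beams` (5-char bitstring, beam 1 nearest the door first).
#'
#' @param scans data.frame in the dialect above.
#' @param path file path.
#' @export
write_beam_scans <- function(scans, path) {
  stopifnot(all(c("rat_id", "day", "side", "interval_start_s", "beams")
                %in% names(scans)))
  utils::write.csv(scans, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beam_scans
#' @export
read_beam_scans <- function(path) {
  scans <- utils::read.csv(path, colClasses = c(beams = "character"))
  stopifnot(all(c("rat_id", "day", "side", "interval_start_s", "beams")
                %in% names(scans)))
  scans
}

#' Write a calorimetry session as a long-format CSV
#'
#' Columns `timestamp_s`, `channel`, `value`, `phase`; channels are `tc`,
#' `o2_in`, `o2_out`, `vapor_flux_mg_min`, `gradient_mv`.
#'
#' @param session a `calorimetry_session`.
#' @param path file path.
#' @export
write_calorimetry <- function(session, path) {
  sig <- session$signals
  long <- rbind(
    data.frame(timestamp_s = session$tc$time_s, channel = "tc",
               value = session$tc$tc, phase = session$tc$phase),
    data.frame(timestamp_s = sig$time_s, channel = "o2_in",
               value = sig$o2_in, phase = sig$phase),
    data.frame(timestamp_s = sig$time_s, channel = "o2_out",
               value = sig$o2_out, phase = sig$phase),
    data.frame(timestamp_s = sig$time_s, channel = "vapor_flux_mg_min",
               value = sig$vapor_flux_mg_min, phase = sig$phase),
    data.frame(timestamp_s = sig$time_s, channel = "gradient_mv",
               value = sig$gradient_mv, phase = sig$phase))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_dyad_map <- c(rat_id = "rat_id", group = "group", dyad = "dyad",
                      t_n2o = "t_n2o_s", t_control = "t_control_s",
                      t_central = "t_central_s")

#' Read a per-rat per-dyad compartment-time table
#'
#' Reads the deposited-dataset layout (one row per rat per dyad with the
#' three compartment times) from CSV or TSV, using a declarative column
#' mapping rather than hard-coded positions.  Rows whose three times fail
#' closure against the fixed dyad total by more than `tolerance` seconds are
#' rejected with a report (the tolerance absorbs the additive zero-
#' replacement perturbation); rows with `NA` times are kept and flagged
#' missing.
#'
#' @param path CSV or TSV file (auto-detected by extension/sniffing).
#' @param column_map named character vector mapping canonical names
#'   (`rat_id`, `group`, `dyad`, `t_n2o`, `t_control`, `t_central`) to the
#'   file's column names.  Unmapped names fall back to the canonical name
#'   itself, with or without an `_s` suffix.
#' @param total fixed dyad total in seconds (default 158,400: two 22-h
#'   sessions).
#' @param tolerance closure tolerance in seconds.
#' @return validated dyad table as from [build_dyads()].
#' @export
read_dyad_table <- function(path, column_map = NULL, total = 158400,
                            tolerance = 10) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE))
    stop("XLSX input is not supported in this build; export the sheet to CSV",
         call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  map <- default_dyad_map
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  pick <- function(canon) {
    cands <- unique(c(map[[canon]], canon, paste0(canon, "_s")))
    hit <- cands[cands %in% names(raw)]
    if (!length(hit))
      stop(sprintf("column for '%s' not found (tried: %s)", canon,
                   paste(cands, collapse = ", ")), call. = FALSE)
    raw[[hit[1]]]
  }
  out <- data.frame(rat_id = as.character(pick("rat_id")),
                    group = as.character(pick("group")),
                    dyad = pick("dyad"),
                    t_n2o = pick("t_n2o"),
                    t_control = pick("t_control"),
                    t_central = pick("t_central"),
                    stringsAsFactors = FALSE)
  for (nm in c("dyad", "t_n2o", "t_control", "t_central"))
    if (!is.numeric(out[[nm]]))
      stop(sprintf("column '%s' contains non-numeric cells", nm),
           call. = FALSE)
  times <- out[c("t_n2o", "t_control", "t_central")]
  miss <- apply(is.na(times), 1, any)
  neg <- !miss & apply(times < 0, 1, any)
  if (any(neg))
    stop(sprintf("negative times in rows: %s",
                 paste(which(neg), collapse = ", ")), call. = FALSE)
  sums <- rowSums(times)
  bad <- !miss & abs(sums - total) > tolerance
  if (any(bad))
    stop(sprintf("rows failing closure to %g +/- %g s: %s", total, tolerance,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  out$water_location <- ifelse(out$dyad <= 4, "side_chambers", "central_tub")
  out$missing <- miss
  out
}

#' Write a dyad table in the deposited-dataset layout
#'
#' @param dyads dyad table.
#' @param path file path.
#' @export
write_dyad_table <- function(dyads, path) {
  out <- data.frame(rat_id = dyads$rat_id, group = dyads$group,
                    dyad = dyads$dyad, t_n2o_s = dyads$t_n2o,
                    t_control_s = dyads$t_control,
                    t_central_s = dyads$t_central)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
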