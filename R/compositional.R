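#' Closure of a composition
#'
#' Rescales non-negative parts to sum to `total`.
#'
#' @param parts numeric vector (or matrix with compositions in rows).
#' @param total target sum (default 1).
#' @return rescaled parts.
#' @export
closure <- function(parts, total = 1) {
  if (is.matrix(parts)) return(t(apply(parts, 1, closure, total = total)))
  s <- sum(parts)
  if (s <= 0) stop("cannot close a composition with non-positive sum",
                   call. = FALSE)
  parts * total / s
}

#' Replace zero compartment times by a detection floor
#'
#' Zero times are below the 10-s detection limit of the beam-scan logger, and
#' break log-ratios.  Each zero cell is replaced by `floor` seconds (default
#' 5 s, half the detection limit); nonzero cells are untouched and the total
#' is deliberately not re-closed (a 5-s perturbation of a 158,400-s total).
#' The floor is configurable for robustness re-checks with values below the
#' detection limit.
#'
#' @param times numeric vector/matrix of non-negative times.
#' @param floor replacement value in seconds.
#' @return times with zeros replaced.
#' @export
replace_zeros <- function(times, floor = 5) {
  if (any(times < 0)) stop("negative times are invalid", call. = FALSE)
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  times[times == 0] <- floor
  times
}

#' Log preference ratio of a dyad composition
#'
#' Natural log of time in the N2O chamber over time in the control chamber.
#' Being a ratio of two parts, it is invariant to the closure total and does
#' not depend on central-tub time.
#'
#' @param t_n2o,t_control strictly positive times (apply [replace_zeros()]
#'   first).
#' @return log ratio (vectorised).
#' @export
log_preference_ratio <- function(t_n2o, t_control) {
  if (any(t_n2o <= 0 | t_control <= 0))
    stop("times must be strictly positive; replace zeros first",
         call. = FALSE)
  log(t_n2o / t_control)
}

#' Centered geometric mean of compositions
#'
#' The compositional center: component-wise geometric mean across
#' observations, re-closed so the components sum to one.
#'
#' @param compositions matrix (rows = observations, columns = parts) of
#'   strictly positive values.
#' @return proportion vector summing to 1.
#' @export
centered_geometric_mean <- function(compositions) {
  compositions <- as.matrix(compositions)
  if (any(compositions <= 0))
    stop("all parts must be strictly positive (zero-replace first)",
         call. = FALSE)
  g <- exp(colMeans(log(compositions)))
  closure(g, 1)
}

#' Ternary (barycentric) coordinates of a 3-part proportion
#'
#' Maps proportions `(p1, p2, p3)` summing to 1 onto the unit-edge
#' equilateral triangle with vertices `(0,0)` (part 2), `(1,0)` (part 3) and
#' `(1/2, sqrt(3)/2)` (part 1).
#'
#' @param proportions length-3 vector or 3-column matrix, rows summing to 1.
#' @return `c(x, y)` or a 2-column matrix.
#' @export
ternary_coordinates <- function(proportions) {
  if (is.matrix(proportions))
    return(t(apply(proportions, 1, ternary_coordinates)))
  if (length(proportions) != 3)
    stop("proportions must have 3 parts", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1", call. = FALSE)
  x <- proportions[3] + proportions[1] / 2
  y <- proportions[1] * sqrt(3) / 2
  c(x = unname(x), y = unname(y))
}

#' Per-dyad centered geometric means for a dyad table
#'
#' @param dyads dyad table (`group`, `dyad`, `t_n2o`, `t_control`,
#'   `t_central`), zeros replaced.
#' @return data.frame with one row per group x dyad: proportions `p_n2o`,
#'   `p_control`, `p_central` and ternary `x`, `y`.
#' @export
dyad_centers <- function(dyads) {
  d <- dyads[!is.na(dyads$t_n2o), ]
  out <- list()
  for (g in unique(d$group)) for (dy in sort(unique(d$dyad[d$group == g]))) {
    sel <- d$group == g & d$dyad == dy
    cgm <- centered_geometric_mean(
      as.matrix(d[sel, c("t_n2o", "t_control", "t_central")]))
    xy <- ternary_coordinates(cgm)
    out[[length(out) + 1L]] <- data.frame(
      group = g, dyad = dy, p_n2o = cgm[1], p_control = cgm[2],
      p_central = cgm[3], x = xy["x"], y = xy["y"],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}
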