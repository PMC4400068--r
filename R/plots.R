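#' Save a figure as SVG (PDF fallback)
#'
#' @param path output path ending in `.svg` or `.pdf`.
#' @param draw function drawing the plot.
#' @export
save_figure <- function(path, draw) {
  if (grepl("\\.svg$", path) && capabilities("cairo")) {
    grDevices::svg(path, width = 6, height = 6)
  } else {
    path <- sub("\\.svg$", ".pdf", path)
    grDevices::pdf(path, width = 6, height = 6)
  }
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}

#' Ternary diagram of dyad compositional centers
#'
#' Plots per-dyad centered geometric mean compositions inside the unit-edge
#' equilateral triangle; II dyads are circled, IS dyads plain, numbers give
#' the dyad order.  Vertices: top = N2O chamber, bottom-left = control
#' chamber, bottom-right = central tub.
#'
#' @param centers output of [dyad_centers()].
#' @export
plot_ternary <- function(centers) {
  tri_x <- c(0, 1, 0.5, 0)
  tri_y <- c(0, 0, sqrt(3) / 2, 0)
  graphics::plot(tri_x, tri_y, type = "l", asp = 1, axes = FALSE,
                 xlab = "", ylab = "",
                 main = "Time allocation (centered geometric means)")
  graphics::text(c(0.5, -0.04, 1.04), c(sqrt(3) / 2 + 0.04, -0.04, -0.04),
                 c("N2O", "control", "central"), cex = 0.9)
  for (i in seq_len(nrow(centers))) {
    circled <- centers$group[i] == "II"
    graphics::text(centers$x[i], centers$y[i], labels = centers$dyad[i],
                   col = if (circled) "black" else "red", cex = 0.9)
    if (circled)
      graphics::points(centers$x[i], centers$y[i], cex = 2.2)
  }
  invisible(centers)
}

#' Preference-ratio plot by dyad and group
#'
#' Geometric mean N2O:control time ratios with pointwise 95% confidence
#' intervals on a log scale.
#'
#' @param dyad_ratios the `dyad_ratios` element of [summarize_fit()].
#' @export
plot_preference <- function(dyad_ratios) {
  stopifnot(!is.null(dyad_ratios))
  off <- ifelse(dyad_ratios$group == "II", 0.08, -0.08)
  x <- dyad_ratios$dyad + off
  graphics::plot(x, dyad_ratios$ratio, log = "y",
                 ylim = range(c(dyad_ratios$lo, dyad_ratios$hi)),
                 pch = ifelse(dyad_ratios$group == "II", 16, 17),
                 col = ifelse(dyad_ratios$group == "II", "black", "red"),
                 xlab = "dyad", ylab = "N2O : control time ratio")
  graphics::segments(x, dyad_ratios$lo, x, dyad_ratios$hi,
                     col = ifelse(dyad_ratios$group == "II", "black", "red"))
  graphics::abline(h = 1, lty = 2)
  graphics::legend("topleft", legend = c("II", "IS"), pch = c(16, 17),
                   col = c("black", "red"), bty = "n")
  invisible(dyad_ratios)
}

#' Group-mean thermal profiles
#'
#' Draws baseline-referenced mean Tc (and optionally HP) trajectories by
#' group across 6-min bins.
#'
#' @param profiles list of `thermal_profile` objects.
#' @param groups character vector of group labels, one per profile.
#' @param channel `"dtc"` or `"dhp"`.
#' @export
plot_thermal_profiles <- function(profiles, groups, channel = c("dtc", "dhp")) {
  channel <- match.arg(channel)
  mats <- lapply(profiles, function(p) delta_from_baseline(p)$bins[[channel]])
  m <- do.call(cbind, mats)
  t_min <- profiles[[1]]$bin_start / 60 + 3
  cols <- ifelse(groups == "II", "black", "red")
  ylab <- if (channel == "dtc") "delta Tc (degC)" else "delta HP (W)"
  graphics::matplot(t_min, m, type = "l", lty = 1, col = grDevices::adjustcolor(cols, 0.35),
                    xlab = "time (min)", ylab = ylab)
  for (g in unique(groups))
    graphics::lines(t_min, rowMeans(m[, groups == g, drop = FALSE]),
                    col = if (g == "II") "black" else "red", lwd = 2)
  graphics::abline(h = 0, lty = 2)
  invisible(m)
}
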