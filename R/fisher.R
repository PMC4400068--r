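#' Exact two-sided Fisher test for a 2x2 table
#'
#' Conditions on both margins and enumerates every table consistent with
#' them under the hypergeometric null.  The two-sided p-value is the sum of
#' the point probabilities of all tables no more probable than the observed
#' one (the sum-of-small-p rule; a relative tolerance of 1e-7 guards the
#' comparison against floating-point ties).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.  An empty margin returns 1 by convention.
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  r1 <- sum(table[1, ])
  r2 <- sum(table[2, ])
  c1 <- sum(table[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  pr <- exp(logp)
  p_obs <- pr[support == table[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
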