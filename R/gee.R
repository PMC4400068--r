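#' Build preference records from a dyad table
#'
#' Applies the zero-replacement floor to the side-chamber times, computes the
#' log preference ratio, codes the group factor with IS as reference (so the
#' group coefficient is the II effect), and drops missing dyads
#' (complete-available analysis).
#'
#' @param dyads dyad table (`rat_id`, `group`, `dyad`, `t_n2o`, `t_control`).
#' @param floor zero-replacement floor in seconds.
#' @return data.frame with `rat_id`, `group` (factor IS/II), `dyad` (numeric),
#'   `log_ratio`.
#' @export
preference_records <- function(dyads, floor = 5) {
  d <- dyads[!is.na(dyads$t_n2o) & !is.na(dyads$t_control), ]
  t_n2o <- replace_zeros(d$t_n2o, floor)
  t_control <- replace_zeros(d$t_control, floor)
  data.frame(rat_id = d$rat_id,
             group = factor(d$group, levels = c("IS", "II")),
             dyad = as.numeric(d$dyad),
             log_ratio = log_preference_ratio(t_n2o, t_control),
             stringsAsFactors = FALSE)
}

#' Gaussian GEE with identity link and cluster-robust covariance
#'
#' Fits marginal linear models for clustered continuous outcomes by
#' generalized estimating equations: iterated generalized least squares
#' under an independence or exchangeable working correlation, with the
#' exchangeable parameter updated by the moment estimator, and the
#' Liang-Zeger sandwich (robust) covariance
#' \deqn{B^{-1}\Big[\sum_i X_i'V_i^{-1} r_i r_i' V_i^{-1} X_i\Big]B^{-1},
#'   \quad B = \sum_i X_i'V_i^{-1}X_i.}
#'
#' The intended model is the log preference ratio on a group indicator plus
#' dyad as a linear continuous covariate, clustered on rat, optionally with a
#' group-by-dyad interaction.
#'
#' @param data data.frame of records (one row per rat per dyad).
#' @param formula model formula, default `log_ratio ~ group + dyad`.
#' @param id name of the cluster column (default `"rat_id"`).
#' @param corstr working correlation, `"exchangeable"` or `"independence"`.
#' @param fixed_alpha optional fixed exchangeable correlation (bypasses the
#'   moment update).
#' @param tol convergence tolerance on the coefficient vector.
#' @param maxit maximum iterations.
#' @return object of class `gee_fit`: coefficients, `alpha`, `sigma2`,
#'   robust and naive covariance, cluster count, and the fitting frame.
#' @export
fit_gee <- function(data, formula = log_ratio ~ group + dyad, id = "rat_id",
                    corstr = c("exchangeable", "independence"),
                    fixed_alpha = NULL, tol = 1e-10, maxit = 100L) {
  corstr <- match.arg(corstr)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  keep <- stats::complete.cases(X, y)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  cl <- data[[id]][keep]
  if (is.null(cl)) stop(sprintf("cluster column '%s' not found", id),
                        call. = FALSE)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  groups <- split(seq_along(y), cl)
  K <- length(groups)
  if (K < 2) stop("need at least 2 clusters", call. = FALSE)
  N <- length(y)

  rinv <- function(n, alpha) {
    # inverse of (1 - a) I + a J in closed form
    if (n == 1) return(matrix(1, 1, 1))
    a <- alpha
    diag(n) / (1 - a) - matrix(a / ((1 - a) * (1 + (n - 1) * a)), n, n)
  }

  beta <- qr.solve(X, y)                       # OLS start
  alpha <- if (is.null(fixed_alpha)) 0 else fixed_alpha
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- as.numeric(y - X %*% beta)
    sigma2 <- sum(e^2) / (N - p)
    if (corstr == "exchangeable" && is.null(fixed_alpha) && sigma2 > 0) {
      num <- 0
      npairs <- 0
      for (g in groups) {
        ni <- length(g)
        if (ni < 2) next
        r <- e[g] / sqrt(sigma2)
        num <- num + (sum(r)^2 - sum(r^2)) / 2
        npairs <- npairs + ni * (ni - 1) / 2
      }
      denom <- max(npairs - p, 1)
      alpha <- num / denom
      nmax <- max(lengths(groups))
      alpha <- min(max(alpha, -1 / (nmax - 1) + 1e-8), 1 - 1e-8)
    }
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (g in groups) {
      Xi <- X[g, , drop = FALSE]
      Ri <- rinv(length(g), if (corstr == "independence") 0 else alpha)
      XtR <- crossprod(Xi, Ri)
      A <- A + XtR %*% Xi
      b <- b + XtR %*% y[g]
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) break
    if (iter >= maxit)
      stop(sprintf("GEE failed to converge in %d iterations", maxit),
           call. = FALSE)
  }

  e <- as.numeric(y - X %*% beta)
  sigma2 <- sum(e^2) / (N - p)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (g in groups) {
    Xi <- X[g, , drop = FALSE]
    Ri <- rinv(length(g), if (corstr == "independence") 0 else alpha)
    XtR <- crossprod(Xi, Ri)
    B <- B + XtR %*% Xi
    u <- XtR %*% e[g]
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  vcov_robust <- Binv %*% M %*% Binv
  vcov_robust <- (vcov_robust + t(vcov_robust)) / 2
  beta <- as.numeric(beta)
  names(beta) <- colnames(X)
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = beta,
    alpha = if (corstr == "independence") 0 else alpha,
    sigma2 = sigma2,
    vcov = vcov_robust,
    vcov_naive = sigma2 * Binv,
    n_clusters = K,
    n_obs = N,
    corstr = corstr,
    formula = formula,
    iterations = iter,
    frame = data.frame(cluster = cl, y = y, check.names = FALSE)
  ), class = "gee_fit")
}

#' GEE with a group-by-dyad interaction
#'
#' Convenience wrapper adding the interaction term used to ask whether the
#' preference trajectory over dyads differs between groups.
#'
#' @inheritParams fit_gee
#' @export
fit_interaction <- function(data, id = "rat_id",
                            corstr = c("exchangeable", "independence"),
                            ...) {
  fit_gee(data, formula = log_ratio ~ group * dyad, id = id,
          corstr = match.arg(corstr), ...)
}

#' Coefficient table with fold changes
#'
#' @param fit a `gee_fit`.
#' @param level confidence level (normal-approximation z intervals).
#' @return data.frame: per-coefficient estimate, robust SE, z, two-sided p,
#'   fold change `exp(beta)` and its CI.
#' @export
coef_table <- function(fit, level = 0.95) {
  est <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  z <- est / se
  data.frame(term = names(est), estimate = est, se_robust = se, z = z,
             p = 2 * stats::pnorm(-abs(z)),
             fold = exp(est),
             fold_lo = exp(est - zc * se), fold_hi = exp(est + zc * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group fold-change summary of a preference-ratio fit
#'
#' @param fit a `gee_fit` whose design contains a `group` term.
#' @return one-row data.frame: fold change `exp(beta_group)`, 95% CI,
#'   two-sided p.
#' @export
group_fold_change <- function(fit) {
  tab <- coef_table(fit)
  row <- tab[tab$term == "groupII", ]
  if (!nrow(row)) stop("no group coefficient in this fit", call. = FALSE)
  data.frame(fold = row$fold, lo = row$fold_lo, hi = row$fold_hi, p = row$p,
             row.names = NULL)
}

#' Full report rows for a fitted preference model
#'
#' Combines the coefficient table, the group fold-change summary, and
#' per-dyad geometric-mean preference ratios with pointwise 95% confidence
#' intervals (the content of a dyad-by-group preference plot).
#'
#' @param fit a `gee_fit`.
#' @param records the preference records used for the fit (for per-dyad
#'   summaries); defaults to none.
#' @return list with `coefficients`, `group` (may be `NULL` if no group
#'   term), `label` (plain-language call), and `dyad_ratios`.
#' @export
summarize_fit <- function(fit, records = NULL) {
  tab <- coef_table(fit)
  grp <- if ("groupII" %in% tab$term) group_fold_change(fit) else NULL
  label <- if (is.null(grp)) "no group term" else if
    (grp$p < 0.05 && grp$fold > 1) "II group prefers N2O more" else if
    (grp$p < 0.05 && grp$fold < 1) "IS group prefers N2O more" else
    "no significant group preference difference"
  dyad_ratios <- NULL
  if (!is.null(records)) {
    dyad_ratios <- do.call(rbind, lapply(split(
      records, list(records$group, records$dyad), drop = TRUE),
      function(s) {
        m <- mean(s$log_ratio)
        se <- stats::sd(s$log_ratio) / sqrt(nrow(s))
        data.frame(group = as.character(s$group[1]), dyad = s$dyad[1],
                   ratio = exp(m), lo = exp(m - 1.96 * se),
                   hi = exp(m + 1.96 * se), n = nrow(s),
                   stringsAsFactors = FALSE)
      }))
    dyad_ratios <- dyad_ratios[order(dyad_ratios$group, dyad_ratios$dyad), ]
    rownames(dyad_ratios) <- NULL
  }
  list(coefficients = tab, group = grp, label = label,
       dyad_ratios = dyad_ratios)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("<gee_fit> %s working correlation, %d clusters, %d obs\n",
              x$corstr, x$n_clusters, x$n_obs))
  if (x$corstr == "exchangeable")
    cat(sprintf("  alpha = %.4f\n", x$alpha))
  print(coef_table(x), digits = 4)
  invisible(x)
}
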