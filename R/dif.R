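# Differential item functioning (Mantel-Haenszel, Breslow-Day) and
# differential test functioning (tau-squared variance of DIF effects).

# Build the per-stratum 2x2 tables (group x item response) for one item,
# stratifying persons by total raw score on all items (or the rest score when
# purify = TRUE). Strata with a zero margin are uninformative and dropped.
dif_tables <- function(X, item, group, purify = FALSE) {
  score <- rowSums(X)
  if (purify) score <- score - X[, item]
  x <- X[, item]
  out <- list()
  for (s in sort(unique(score))) {
    idx <- score == s
    a <- sum(x[idx] == 1 & group[idx] == 1)   # focal endorses
    b <- sum(x[idx] == 0 & group[idx] == 1)
    c_ <- sum(x[idx] == 1 & group[idx] == 0)  # reference endorses
    d <- sum(x[idx] == 0 & group[idx] == 0)
    n1 <- a + b; n0 <- c_ + d; m1 <- a + c_; m0 <- b + d
    if (n1 == 0 || n0 == 0 || m1 == 0 || m0 == 0) next
    out[[length(out) + 1L]] <- c(a = a, b = b, c = c_, d = d)
  }
  out
}

#' Mantel-Haenszel test of uniform DIF
#'
#' Tests whether an item is uniformly harder for one group than the other at
#' equal trait level, by stratifying persons on their total raw score and
#' combining the per-stratum 2x2 (group x response) tables with the
#' Mantel-Haenszel chi-square (with continuity correction). The common odds
#' ratio is estimated by the Mantel-Haenszel estimator, and the variance of
#' its logarithm by the Robins-Breslow-Greenland formula; both feed the
#' differential-test-functioning summary [dtf_tau2()]. Strata with a zero
#' margin carry no information and are dropped.
#'
#' @param data a [response_matrix()] with the covariate attached, or a 0/1
#'   matrix.
#' @param item item label or column index.
#' @param group binary person covariate: a name (looked up in
#'   `covariates(data)`) or a vector of length `n_persons(data)`.
#' @param correct apply the continuity correction (default `TRUE`).
#' @param purify stratify on the rest score (total minus the studied item)
#'   instead of the total score.
#' @return A list with `mh_chi2`, `mh_p`, `mh_or`, `mh_log_or`,
#'   `mh_log_or_var`, `n_strata`.
#' @export
dif_mh <- function(data, item, group, correct = TRUE, purify = FALSE) {
  X <- if (inherits(data, "response_matrix")) resp(data) else data
  if (is.character(item)) item <- match(item, colnames(X))
  group <- resolve_group(data, group)
  tabs <- dif_tables(X, item, group, purify)
  if (length(tabs) == 0)
    stop_raschval(sprintf("DIF untestable for item '%s': no informative strata",
                          colnames(X)[item]))
  a <- vapply(tabs, `[[`, 0, "a"); b <- vapply(tabs, `[[`, 0, "b")
  cc <- vapply(tabs, `[[`, 0, "c"); d <- vapply(tabs, `[[`, 0, "d")
  N <- a + b + cc + d
  n1 <- a + b; n0 <- cc + d; m1 <- a + cc; m0 <- b + d
  E <- n1 * m1 / N
  V <- n1 * n0 * m1 * m0 / (N^2 * (N - 1))
  dev <- abs(sum(a) - sum(E))
  if (correct) dev <- max(dev - 0.5, 0)
  chi2 <- dev^2 / sum(V)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  # Mantel-Haenszel common odds ratio and RBG variance of its log
  R <- a * d / N; S <- b * cc / N
  or <- sum(R) / sum(S)
  P <- (a + d) / N; Q <- (b + cc) / N
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  list(mh_chi2 = chi2, mh_p = p, mh_or = or, mh_log_or = log(or),
       mh_log_or_var = v, n_strata = length(tabs))
}

#' Breslow-Day test of non-uniform DIF
#'
#' Tests homogeneity of the group odds ratio across score strata — the
#' signature of non-uniform (crossing) DIF, where one group is favoured at
#' low trait levels and the other at high levels. Uses the Breslow-Day
#' statistic evaluated at the Mantel-Haenszel common odds ratio, with
#' Tarone's correction, on (informative strata - 1) degrees of freedom.
#'
#' @inheritParams dif_mh
#' @return A list with `bd_chi2`, `bd_df`, `bd_p`, `n_strata`; all `NA` (with
#'   a warning) when fewer than two informative strata exist.
#' @export
dif_bd <- function(data, item, group, purify = FALSE) {
  X <- if (inherits(data, "response_matrix")) resp(data) else data
  if (is.character(item)) item <- match(item, colnames(X))
  group <- resolve_group(data, group)
  tabs <- dif_tables(X, item, group, purify)
  if (length(tabs) < 2) {
    warning(sprintf("Breslow-Day untestable for item '%s': %d informative stratum",
                    colnames(X)[item], length(tabs)))
    return(list(bd_chi2 = NA_real_, bd_df = NA_integer_, bd_p = NA_real_,
                n_strata = length(tabs)))
  }
  a <- vapply(tabs, `[[`, 0, "a"); b <- vapply(tabs, `[[`, 0, "b")
  cc <- vapply(tabs, `[[`, 0, "c"); d <- vapply(tabs, `[[`, 0, "d")
  N <- a + b + cc + d
  or <- sum(a * d / N) / sum(b * cc / N)
  # expected a under the common OR: root of the stratum quadratic
  stat <- 0; resid_sum <- 0; var_sum <- 0
  for (s in seq_along(a)) {
    n1 <- a[s] + b[s]; m1 <- a[s] + cc[s]; m0 <- b[s] + d[s]
    if (abs(or - 1) < 1e-12) {
      at <- n1 * m1 / N[s]
    } else {
      A <- or - 1
      B <- -((n1 + m1) * or + (m0 - n1))
      C <- or * n1 * m1
      disc <- sqrt(max(B^2 - 4 * A * C, 0))
      at <- (-B - disc) / (2 * A)
      if (at < max(0, n1 - m0) || at > min(n1, m1)) at <- (-B + disc) / (2 * A)
    }
    v <- 1 / (1 / at + 1 / (n1 - at) + 1 / (m1 - at) + 1 / (m0 - n1 + at))
    stat <- stat + (a[s] - at)^2 / v
    resid_sum <- resid_sum + (a[s] - at)
    var_sum <- var_sum + v
  }
  stat <- stat - resid_sum^2 / var_sum   # Tarone correction
  df <- length(a) - 1L
  list(bd_chi2 = stat, bd_df = df,
       bd_p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       n_strata = length(a))
}

resolve_group <- function(data, group) {
  if (is.character(group) && length(group) == 1) {
    cv <- covariates(data)
    if (is.null(cv) || is.null(cv[[group]]))
      stop_raschval(sprintf("covariate '%s' not found", group))
    group <- cv[[group]]
  }
  lv <- sort(unique(group))
  if (length(lv) != 2) stop_raschval("group must have exactly two levels present")
  as.integer(group == lv[2])
}

#' Combined DIF flag rule
#'
#' An item shows differential functioning when either the uniform
#' (Mantel-Haenszel) or the non-uniform (Breslow-Day) test is significant at
#' level `alpha` (strict inequality). An untestable component (`NA` p-value)
#' is treated as non-significant, with a warning.
#'
#' @param mh_p,bd_p p-values from [dif_mh()] and [dif_bd()].
#' @param alpha significance level.
#' @return Logical flag.
#' @export
dif_decision <- function(mh_p, bd_p, alpha = 0.05) {
  ps <- c(mh = mh_p, bd = bd_p)
  if (anyNA(ps)) {
    warning("untestable DIF component treated as non-significant")
    ps <- ps[!is.na(ps)]
  }
  any(ps < alpha)
}

#' Differential test functioning: the variance of DIF effects
#'
#' Summarises item-level DIF into a scale-level effect: the between-item
#' variance \eqn{\hat\tau^2} of the Mantel-Haenszel log odds ratios
#' \eqn{\lambda_i}, estimated by the weighted method of moments with weights
#' \eqn{w_i = 1/v_i}:
#' \deqn{\hat\tau^2 = \frac{\sum w_i^2 (\lambda_i - \bar\lambda)^2 -
#'   \sum w_i}{\sum w_i^2}, \qquad
#'   \bar\lambda = \sum w_i \lambda_i / \sum w_i.}
#' The estimator is deliberately not truncated at zero — small negative
#' values indicate less dispersion than expected from sampling error alone.
#' Effect bands follow the conventional cut-offs: small below 0.07, medium
#' between 0.07 and 0.14, large above 0.14 (boundary values fall in the
#' lower band).
#'
#' @param log_or numeric vector of per-item MH log odds ratios
#'   \eqn{\lambda_i}.
#' @param var numeric vector of their sampling variances \eqn{v_i}.
#' @return A list with `tau2` and `effect_band` (one of `"small"`,
#'   `"medium"`, `"large"`).
#' @examples
#' dtf_tau2(c(0, 1), c(1, 1))  # tau2 = -0.75, small
#' @export
dtf_tau2 <- function(log_or, var) {
  ok <- is.finite(log_or) & is.finite(var) & var > 0
  log_or <- log_or[ok]; var <- var[ok]
  if (length(log_or) < 2)
    stop_raschval("tau-squared needs at least 2 items with finite DIF effects")
  w <- 1 / var
  lbar <- sum(w * log_or) / sum(w)
  tau2 <- (sum(w^2 * (log_or - lbar)^2) - sum(w)) / sum(w^2)
  band <- if (tau2 <= 0.07) "small" else if (tau2 <= 0.14) "medium" else "large"
  list(tau2 = tau2, effect_band = band)
}

#' DIF assessment of every item against one covariate
#'
#' Runs the Mantel-Haenszel and Breslow-Day tests for each item against a
#' binary person covariate, applies the combined flag rule, and summarises
#' differential test functioning by [dtf_tau2()]. No multiplicity adjustment
#' is applied across items.
#'
#' @inheritParams dif_mh
#' @param items item labels or indices to test (default: all).
#' @param alpha significance level for the flag rule.
#' @return Object of class `dif_result`: a list with a per-item data frame
#'   `table` (`item`, `mh_chi2`, `mh_p`, `mh_log_or`, `mh_log_or_var`,
#'   `bd_chi2`, `bd_df`, `bd_p`, `flagged`), the covariate name, `tau2` and
#'   `effect_band`.
#' @export
dif_test <- function(data, group, items = NULL, alpha = 0.05,
                     correct = TRUE, purify = FALSE) {
  X <- if (inherits(data, "response_matrix")) resp(data) else data
  if (is.null(items)) items <- colnames(X)
  if (is.numeric(items)) items <- colnames(X)[items]
  rows <- lapply(items, function(it) {
    mh <- dif_mh(data, it, group, correct = correct, purify = purify)
    bd <- suppressWarnings(dif_bd(data, it, group, purify = purify))
    data.frame(item = it, mh_chi2 = mh$mh_chi2, mh_p = mh$mh_p,
               mh_log_or = mh$mh_log_or, mh_log_or_var = mh$mh_log_or_var,
               bd_chi2 = bd$bd_chi2, bd_df = bd$bd_df, bd_p = bd$bd_p,
               flagged = suppressWarnings(dif_decision(mh$mh_p, bd$bd_p, alpha)))
  })
  tab <- do.call(rbind, rows)
  dtf <- dtf_tau2(tab$mh_log_or, tab$mh_log_or_var)
  structure(list(table = tab,
                 covariate = if (is.character(group) && length(group) == 1)
                   group else "group",
                 alpha = alpha, tau2 = dtf$tau2,
                 effect_band = dtf$effect_band),
            class = "dif_result")
}

#' @export
print.dif_result <- function(x, digits = 3, ...) {
  cat(sprintf("DIF by '%s' (flag if MH or BD p < %.2f):\n", x$covariate, x$alpha))
  tab <- x$table
  tab$decision <- ifelse(tab$flagged, "Flag", "Ok")
  print(format(tab[c("item", "mh_chi2", "mh_p", "bd_chi2", "bd_p", "decision")],
               digits = digits), row.names = FALSE)
  cat(sprintf("Differential test functioning: tau^2 = %.3f (%s effect)\n",
              x$tau2, x$effect_band))
  invisible(x)
}
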