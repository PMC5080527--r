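#' Cronbach's alpha for binary items
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i \sigma^2_i / \sigma^2_{total})}, with
#' item and total-score variances computed with denominator n-1.
#'
#' @param data a [response_matrix()] or 0/1 matrix with >= 2 items.
#' @return The alpha coefficient (<= 1; can be negative).
#' @export
cronbach_alpha <- function(data) {
  X <- if (inherits(data, "response_matrix")) resp(data) else data
  k <- ncol(X)
  if (k < 2) stop_raschval("alpha needs at least 2 items")
  vt <- stats::var(rowSums(X))
  if (vt == 0) stop_raschval("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / vt)
}

#' Person Separation Index
#'
#' The Rasch analogue of reliability: the proportion of observed variance in
#' person measures not attributable to estimation error,
#' \deqn{\mathrm{PSI} = \frac{\mathrm{var}(\hat\theta) -
#'   \overline{se^2}}{\mathrm{var}(\hat\theta)}.}
#' Weighted-likelihood estimates give finite measures and standard errors for
#' extreme (zero and perfect) scorers, so by default all persons enter the
#' computation; set `include_extreme = FALSE` to drop them. The index can be
#' negative when error variance exceeds observed variance and is reported
#' unclipped.
#'
#' @param persons an [ability_wle()] result.
#' @param include_extreme keep persons with extreme raw scores (default
#'   `TRUE`).
#' @return The PSI coefficient (<= 1, possibly negative).
#' @export
person_separation_index <- function(persons, include_extreme = TRUE) {
  stopifnot(is.data.frame(persons), all(c("theta", "se") %in% names(persons)))
  if (!include_extreme) {
    k <- max(persons$raw_score)
    persons <- persons[persons$raw_score > 0 & persons$raw_score < k, ,
                       drop = FALSE]
  }
  if (nrow(persons) < 2) stop_raschval("PSI needs at least 2 persons")
  v <- stats::var(persons$theta)
  if (v == 0) stop_raschval("person measures have zero variance; PSI undefined")
  (v - mean(persons$se^2)) / v
}

#' Reliability summary of an item set
#'
#' Fits the Rasch model to the given item subset and reports both reliability
#' coefficients with their conventional acceptance thresholds (strict
#' inequalities).
#'
#' @param data a [response_matrix()].
#' @param items item labels or indices (default: all items).
#' @param alpha_threshold,psi_threshold pass thresholds.
#' @param include_extreme passed to [person_separation_index()].
#' @return A list of class `reliability_result`: `alpha`, `psi`, `n_items`,
#'   `n_persons_used`, `pass_alpha`, `pass_psi`.
#' @export
scale_reliability <- function(data, items = NULL, alpha_threshold = 0.8,
                              psi_threshold = 0.7, include_extreme = TRUE) {
  if (!is.null(items)) data <- subset_responses(data, items = items)
  fit <- rasch_cml(data)
  persons <- ability_wle(fit)
  psi <- person_separation_index(persons, include_extreme = include_extreme)
  alpha <- cronbach_alpha(data)
  structure(list(alpha = alpha, psi = psi, n_items = n_items(data),
                 n_persons_used = n_persons(data),
                 pass_alpha = alpha > alpha_threshold,
                 pass_psi = psi > psi_threshold),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Reliability (%d items, %d persons): alpha = %.3f (%s), PSI = %.3f (%s)\n",
              x$n_items, x$n_persons_used,
              x$alpha, if (x$pass_alpha) "pass" else "fail",
              x$psi, if (x$pass_psi) "pass" else "fail"))
  invisible(x)
}
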