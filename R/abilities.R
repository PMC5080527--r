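#' Person ability estimates by Warm's weighted likelihood
#'
#' Estimates each person's latent-trait location \eqn{\theta_v} (logits) given
#' calibrated item difficulties, using Warm's weighted likelihood estimator
#' (WLE). Unlike the maximum likelihood estimator, the WLE is finite for
#' perfect (k) and zero raw scores, which makes it usable for reliability
#' computations over all persons. Under the Rasch model the raw score is
#' sufficient for \eqn{\theta}, so persons sharing a raw score share an
#' estimate; the estimating equation
#' \deqn{r - \sum_i P_i(\theta) + J(\theta)/(2 I(\theta)) = 0}
#' (with \eqn{I} the test information and \eqn{J} its derivative ingredient
#' \eqn{\sum_i P_i Q_i (1 - 2P_i)}) is solved once per observed raw score.
#' The asymptotic standard error is \eqn{1/\sqrt{I(\hat\theta)}}.
#'
#' @param object a [rasch_cml()] fit, or a numeric vector of item
#'   difficulties.
#' @param data responses to score; defaults to the data the model was fitted
#'   to. Ignored when `raw_scores` is given.
#' @param raw_scores optional integer vector of raw scores to score directly.
#' @return An object of class `rasch_ability`: a data frame with columns
#'   `raw_score`, `theta`, `se`, one row per person (or per element of
#'   `raw_scores`).
#' @export
ability_wle <- function(object, data = NULL, raw_scores = NULL) {
  beta <- if (inherits(object, "rasch_cml")) object$beta else object
  k <- length(beta)
  if (is.null(raw_scores)) {
    if (is.null(data)) {
      if (!inherits(object, "rasch_cml"))
        stop_raschval("supply `data` or `raw_scores` when scoring from difficulties")
      data <- object$data
    }
    X <- if (inherits(data, "response_matrix")) resp(data) else data
    if (ncol(X) != k) stop_raschval("data and difficulties disagree on item count")
    raw_scores <- rowSums(X)
  }
  tab <- wle_table(beta)
  out <- data.frame(raw_score = as.integer(raw_scores),
                    theta = tab$theta[raw_scores + 1L],
                    se = tab$se[raw_scores + 1L])
  class(out) <- c("rasch_ability", "data.frame")
  out
}

# solve the WLE estimating equation for every raw score 0..k
wle_table <- function(beta) {
  k <- length(beta)
  est <- function(r) {
    f <- function(th) {
      P <- stats::plogis(th - beta)
      W <- P * (1 - P)
      I <- sum(W)
      J <- sum(W * (1 - 2 * P))
      r - sum(P) + J / (2 * I)
    }
    lo <- -20; hi <- 20
    # f is decreasing in theta; widen bracket defensively
    while (f(lo) < 0 && lo > -50) lo <- lo - 10
    while (f(hi) > 0 && hi < 50) hi <- hi + 10
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  theta <- vapply(0:k, est, numeric(1))
  se <- vapply(theta, function(th) {
    P <- stats::plogis(th - beta)
    1 / sqrt(sum(P * (1 - P)))
  }, numeric(1))
  list(theta = theta, se = se)
}

#' @export
print.rasch_ability <- function(x, ...) {
  cat(sprintf("WLE person measures for %d persons (theta in logits)\n", nrow(x)))
  tab <- unique(as.data.frame(x)[order(x$raw_score), , drop = FALSE])
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}
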