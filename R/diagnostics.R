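#' Parallel analysis for dimensionality of binary items
#'
#' Horn-style parallel analysis on the Pearson (phi) correlation matrix of
#' the binary item columns. The reference (null) eigenvalue distribution is
#' built by independently permuting each column of the observed data, which
#' preserves the item margins — the feature of dichotomous data that inflates
#' eigenvalues — while destroying all inter-item structure. A component is
#' retained while its observed eigenvalue exceeds the 95th percentile (or
#' `quantile`) of the corresponding null eigenvalues; counting stops at the
#' first failure. Adjusted eigenvalues are reported as
#' `observed - (null mean - 1)`.
#'
#' @param data a [response_matrix()] or 0/1 matrix with >= 2 items.
#' @param n_sims number of permuted null datasets (>= 100).
#' @param seed integer seed for the permutations.
#' @param quantile retention quantile of the null distribution.
#' @return An object of class `parallel_analysis`: list with
#'   `observed_eigenvalues`, `random_mean`, `random_p95`,
#'   `adjusted_eigenvalues`, `n_retained`, `n_sims`, `seed`.
#' @export
parallel_analysis <- function(data, n_sims = 5000, seed = NULL,
                              quantile = 0.95) {
  X <- if (inherits(data, "response_matrix")) resp(data) else data
  k <- ncol(X)
  if (k < 2) stop_raschval("need at least 2 items")
  if (n_sims < 100) stop_raschval("n_sims must be at least 100")
  if (any(apply(X, 2, stats::sd) == 0))
    stop_raschval(sprintf("constant column '%s': correlation undefined",
                          colnames(X)[which(apply(X, 2, stats::sd) == 0)[1]]))
  evals <- function(M) eigen(stats::cor(M), symmetric = TRUE,
                             only.values = TRUE)$values
  obs <- evals(X)
  sims <- with_seed(seed, vapply(seq_len(n_sims), function(s) {
    evals(apply(X, 2, sample))
  }, numeric(k)))
  rmean <- rowMeans(sims)
  rp95 <- apply(sims, 1, stats::quantile, probs = quantile, names = FALSE)
  n_ret <- 0L
  for (j in seq_len(k)) {
    if (obs[j] > rp95[j]) n_ret <- j else break
  }
  structure(list(observed_eigenvalues = obs, random_mean = rmean,
                 random_p95 = rp95,
                 adjusted_eigenvalues = obs - (rmean - 1),
                 n_retained = n_ret, n_sims = n_sims, seed = seed),
            class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("Parallel analysis (%d column permutations): %d component%s retained\n",
              x$n_sims, x$n_retained, if (x$n_retained == 1) "" else "s"))
  tab <- data.frame(observed = x$observed_eigenvalues,
                    null_mean = x$random_mean, null_p95 = x$random_p95,
                    adjusted = x$adjusted_eigenvalues)
  print(round(utils::head(tab, max(3, x$n_retained + 1)), digits))
  invisible(x)
}

#' Item infit mean squares
#'
#' Information-weighted (infit) mean-square fit statistics per item. The
#' numerator is the squared-residual sum \eqn{\sum_v (x_{vi} - \hat
#' P_{vi})^2} over non-extreme persons, with \eqn{\hat P_{vi}} the model
#' probability at the WLE ability and CML difficulty. Because the ability
#' estimate is a function of the person's own raw score, the naive
#' denominator \eqn{\sum_v \hat P_{vi}(1-\hat P_{vi})} is biased upward: the
#' statistic would centre near \eqn{1 - 1/k} rather than 1 for a k-item
#' test. The denominator used here is instead the exact null expectation of
#' the numerator given each person's raw score,
#' \deqn{\sum_v \left[\pi_{r_v i}(1-\pi_{r_v i}) +
#'   (\pi_{r_v i} - \hat P_{vi})^2\right],}
#' where \eqn{\pi_{ri}} is the conditional probability of endorsing item i
#' given raw score r under the Rasch model (computed from the elementary
#' symmetric functions), so that the mean square has expectation 1 under
#' model fit for any test length. Values near 1 indicate consistency with
#' the probabilistic Guttman pattern; values above the upper bound flag
#' noisy, under-discriminating items and values below the lower bound
#' overly deterministic, redundant ones.
#'
#' A standardised form (`infit_t`) is obtained through the Wilson–Hilferty
#' cube-root transformation, using the exact conditional variance of the
#' numerator in the scale factor.
#'
#' @param data a [response_matrix()]; defaults to the data `fit` was fitted
#'   to.
#' @param fit a [rasch_cml()] fit on `data`.
#' @param abilities optional [ability_wle()] result for `data`.
#' @param bounds acceptance band for the mean square; items outside it are
#'   flagged.
#' @return Object of class `item_fit`: data frame with columns `item`,
#'   `infit_msq`, `infit_t`, `flagged`, plus a `bounds` attribute.
#' @export
item_infit <- function(fit, data = fit$data, abilities = NULL,
                       bounds = c(0.91, 1.09)) {
  X <- if (inherits(data, "response_matrix")) resp(data) else data
  if (is.null(abilities)) abilities <- ability_wle(fit, data)
  r <- rowSums(X)
  k <- ncol(X)
  nonext <- r > 0 & r < k
  Xn <- X[nonext, , drop = FALSE]
  rn <- r[nonext]
  P <- expected_prob(matrix(abilities$theta[nonext], sum(nonext), k),
                     matrix(fit$beta, sum(nonext), k, byrow = TRUE))
  # conditional endorsement probabilities given raw score, P(x_i = 1 | r)
  PI <- esf_item_prob(-fit$beta)[rn + 1L, , drop = FALSE]
  # E[(x - Phat)^2 | r] and Var[(x - Phat)^2 | r], exact Bernoulli moments
  m2 <- PI * (1 - P)^2 + (1 - PI) * P^2
  m4 <- PI * (1 - P)^4 + (1 - PI) * P^4
  denom <- colSums(m2)
  num <- colSums((Xn - P)^2)
  msq <- num / denom
  # variance of the mean square, for the Wilson-Hilferty standardisation
  q2 <- colSums(m4 - m2^2) / denom^2
  q <- sqrt(pmax(q2, 1e-12))
  infit_t <- (msq^(1 / 3) - 1) * (3 / q) + q / 3
  out <- data.frame(item = colnames(X), infit_msq = msq, infit_t = infit_t,
                    flagged = msq < bounds[1] | msq > bounds[2],
                    row.names = NULL)
  attr(out, "bounds") <- bounds
  class(out) <- c("item_fit", "data.frame")
  out
}

#' @export
print.item_fit <- function(x, digits = 3, ...) {
  b <- attr(x, "bounds")
  cat(sprintf("Item infit mean squares (acceptance band %.2f-%.2f):\n", b[1], b[2]))
  print(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Local independence by Q3 residual correlations
#'
#' Yen's Q3 check of the local-independence assumption: Pearson correlations
#' between the columns of standardised residuals
#' \eqn{z_{vi} = (x_{vi}-\hat P_{vi})/\sqrt{\hat P_{vi}(1-\hat P_{vi})}}
#' computed over non-extreme persons. Each pair's correlation is tested with
#' the score-type statistic \eqn{\chi^2 = n r^2} on 1 degree of freedom, and
#' p-values are Holm-adjusted over all \eqn{k(k-1)/2} pairs as one family.
#' A pair is flagged when both the magnitude criterion (`r > r_threshold`)
#' and the significance criterion (`p_holm <= alpha`) hold.
#'
#' @inheritParams item_infit
#' @param r_threshold residual-correlation magnitude above which a pair can
#'   be flagged.
#' @param alpha familywise significance level after Holm adjustment.
#' @return Object of class `local_dependence`: list with the full correlation
#'   matrix `pair_correlations`, a per-pair data frame `pairs` (`item_i`,
#'   `item_j`, `r`, `chi2`, `p_raw`, `p_holm`, `flagged`) and `flagged_pairs`.
#' @export
residual_correlations <- function(fit, data = fit$data, abilities = NULL,
                                  r_threshold = 0.2, alpha = 0.05) {
  X <- if (inherits(data, "response_matrix")) resp(data) else data
  if (is.null(abilities)) abilities <- ability_wle(fit, data)
  r <- rowSums(X)
  k <- ncol(X)
  nonext <- r > 0 & r < k
  Xn <- X[nonext, , drop = FALSE]
  n_eff <- nrow(Xn)
  P <- expected_prob(matrix(abilities$theta[nonext], n_eff, k),
                     matrix(fit$beta, n_eff, k, byrow = TRUE))
  Z <- (Xn - P) / sqrt(P * (1 - P))
  R <- stats::cor(Z)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  rv <- R[ut]
  chi2 <- n_eff * rv^2
  p_raw <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p_holm <- stats::p.adjust(p_raw, method = "holm")
  pairs <- data.frame(item_i = colnames(X)[ut[, 1]],
                      item_j = colnames(X)[ut[, 2]],
                      r = rv, chi2 = chi2, p_raw = p_raw, p_holm = p_holm,
                      flagged = rv > r_threshold & p_holm <= alpha,
                      row.names = NULL)
  structure(list(pair_correlations = R, pairs = pairs,
                 flagged_pairs = pairs[pairs$flagged, , drop = FALSE],
                 n_persons_used = n_eff,
                 r_threshold = r_threshold, alpha = alpha),
            class = "local_dependence")
}

#' @export
print.local_dependence <- function(x, digits = 3, ...) {
  cat(sprintf("Q3 residual correlations over %d pairs (flag: r > %.2f & Holm p <= %.2f)\n",
              nrow(x$pairs), x$r_threshold, x$alpha))
  if (nrow(x$flagged_pairs) == 0) {
    cat("No locally dependent pairs flagged.\n")
  } else {
    print(format(x$flagged_pairs, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
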