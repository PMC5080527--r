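#' Elementary symmetric functions of item easiness parameters
#'
#' Computes the elementary symmetric polynomials \eqn{\gamma_0, \ldots,
#' \gamma_k} of the item easiness terms \eqn{\epsilon_i = \exp(-\beta_i)},
#' the normalising constants of the conditional likelihood of the Rasch
#' model: \eqn{\gamma_r} sums, over all subsets of r items, the product of
#' their easiness terms. The summation (recursive) algorithm is run in log
#' space, which keeps the recursion stable for tests of up to ~50 items.
#'
#' @param eps positive numeric vector of easiness terms \eqn{\exp(-\beta_i)}.
#' @param log if `TRUE` return \eqn{\log\gamma_r} instead of \eqn{\gamma_r}.
#' @return Numeric vector of length `length(eps) + 1`, orders 0..k.
#' @examples
#' elementary_symmetric(c(1, 2, 3))  # 1, 6, 11, 6
#' @export
elementary_symmetric <- function(eps, log = FALSE) {
  if (any(!is.finite(eps)) || any(eps <= 0))
    stop_raschval("easiness terms must be positive and finite")
  lg <- esf_log(base::log(eps))
  if (log) lg else exp(lg)
}

# log gamma_0..gamma_k from log easiness terms, by the summation algorithm:
# after absorbing item i, lg[r] <- logaddexp(lg[r], lg[r-1] + le_i)
esf_log <- function(le) {
  k <- length(le)
  lg <- c(0, rep(-Inf, k))
  for (i in seq_len(k)) {
    # descend so lg[r-1] is still the value without item i
    for (r in seq(min(i, k), 1L)) {
      a <- lg[r + 1L]; b <- lg[r] + le[i]
      m <- max(a, b)
      lg[r + 1L] <- if (is.finite(m)) m + log(exp(a - m) + exp(b - m)) else m
    }
  }
  lg
}

# Conditional P(X_i = 1 | raw score r) for all items and r = 0..k:
# pi[r+1, i] = eps_i * gamma_{r-1}^{(i)} / gamma_r.
# Returns a (k+1) x k matrix. Also used for conditional covariances.
esf_item_prob <- function(le) {
  k <- length(le)
  lg <- esf_log(le)
  pi_ri <- matrix(0, k + 1L, k)
  for (i in seq_len(k)) {
    lgi <- esf_log(le[-i])                 # orders 0..k-1 without item i
    r <- seq_len(k)                        # scores 1..k
    pi_ri[r + 1L, i] <- pmin(exp(le[i] + lgi[r] - lg[r + 1L]), 1)
  }
  pi_ri
}

# Conditional E(X_i X_j | r) for one pair i < j:
# eps_i eps_j gamma_{r-2}^{(ij)} / gamma_r, vector over r = 0..k
esf_pair_prob <- function(le, i, j, lg = esf_log(le)) {
  k <- length(le)
  lgij <- esf_log(le[-c(i, j)])            # orders 0..k-2
  out <- numeric(k + 1L)
  r <- 2:k
  out[r + 1L] <- exp(le[i] + le[j] + lgij[r - 1L] - lg[r + 1L])
  out
}
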