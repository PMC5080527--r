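#' Fit a dichotomous Rasch model by conditional maximum likelihood
#'
#' Estimates item difficulties \eqn{\beta_i} (in logits) by maximising the
#' likelihood of the responses conditional on each person's raw score, which
#' eliminates the person parameters through the elementary symmetric
#' functions. Persons with extreme raw scores (0 or k) carry no information
#' about item difficulties and are excluded from estimation. Difficulties are
#' identified by the sum-to-zero constraint \eqn{\sum_i \beta_i = 0}, so that
#' easy (commonly endorsed) items get negative and hard (rare) items positive
#' values around a zero centre.
#'
#' Optimisation is Newton–Raphson on the conditional log-likelihood with step
#' halving, iterated until the gradient norm falls below `tol`. Standard
#' errors come from the conditional (Fisher) information matrix; because the
#' conditional likelihood is invariant to a common shift of all difficulties
#' the information matrix is singular in that direction and its Moore–Penrose
#' inverse is used, which corresponds to the sum-to-zero identification.
#'
#' @param data a [response_matrix()] (or plain 0/1 matrix) with at least two
#'   items; every item must be endorsed by some, but not all, of the
#'   non-extreme persons, otherwise its difficulty is inestimable.
#' @param tol convergence tolerance on the maximum absolute gradient
#'   component.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `rasch_cml` with components `beta` (named
#'   difficulty estimates), `se`, `vcov`, `logLik`, `converged`,
#'   `n_iterations`, `n_persons_used` (non-extreme persons), `item_labels`,
#'   and the `data` it was fitted to.
#' @seealso [ability_wle()] for person measures, [item_infit()] for fit
#'   assessment, [simulate.rasch_cml()] for model-based simulation.
#' @examples
#' sim <- simulate_responses(sim_config(n_persons = 200, seed = 1))
#' fit <- rasch_cml(sim)
#' coef(fit)
#' @export
rasch_cml <- function(data, tol = 1e-8, max_iter = 100L) {
  if (!inherits(data, "response_matrix")) data <- response_matrix(data)
  X <- resp(data)
  k <- ncol(X)
  if (k < 2) stop_raschval("need at least 2 items")
  r <- rowSums(X)
  nonext <- r > 0 & r < k
  Xn <- X[nonext, , drop = FALSE]
  s <- colSums(Xn)                       # item scores among non-extreme persons
  n_used <- nrow(Xn)
  if (n_used == 0) stop_raschval("no non-extreme persons; model inestimable")
  bad <- which(s == 0 | s == n_used)
  if (length(bad))
    stop_raschval(sprintf(
      "item '%s' is inestimable: endorsed by %d of %d non-extreme persons",
      colnames(X)[bad[1]], s[bad[1]], n_used))
  n_r <- tabulate(r[nonext], nbins = k - 1L)   # counts of scores 1..k-1

  # conditional log-likelihood and derivatives in the full beta space
  cll <- function(beta) {
    lg <- esf_log(-beta)
    -sum(beta * s) - sum(n_r * lg[2:k])
  }
  derivs <- function(beta) {
    le <- -beta
    pi_ri <- esf_item_prob(le)           # (k+1) x k
    rows <- 2:k                          # scores 1..k-1
    exp_s <- colSums(n_r * pi_ri[rows, , drop = FALSE])
    grad <- exp_s - s                    # d l / d beta_i = -s_i + E s_i
    info <- matrix(0, k, k)              # Fisher info = sum_r n_r Cov_r(x)
    lg <- esf_log(le)
    for (i in seq_len(k)) {
      info[i, i] <- sum(n_r * pi_ri[rows, i] * (1 - pi_ri[rows, i]))
      if (i < k) for (j in seq((i + 1L), k)) {
        pij <- esf_pair_prob(le, i, j, lg)[rows]
        cv <- sum(n_r * (pij - pi_ri[rows, i] * pi_ri[rows, j]))
        info[i, j] <- info[j, i] <- cv
      }
    }
    list(grad = grad, info = info)
  }

  # start from centred log-odds of the item scores
  beta <- log((n_used - s) / s)
  beta <- beta - mean(beta)
  ll <- cll(beta)
  converged <- FALSE
  iter <- 0L
  # reduced parameterisation: free b = beta[1..k-1], beta_k = -sum(b)
  D <- rbind(diag(k - 1L), -1)           # beta = D %*% b
  repeat {
    iter <- iter + 1L
    d <- derivs(beta)
    g_red <- crossprod(D, d$grad)        # chain rule
    if (max(abs(g_red)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    I_red <- crossprod(D, d$info %*% D)
    step <- tryCatch(solve(I_red, g_red), error = function(e) NULL)
    if (is.null(step)) step <- MASS::ginv(I_red) %*% g_red
    # d l / d beta = -grad's sign convention: grad here is dll/dbeta
    # Newton ascent: b <- b + solve(I, g)  (info = -Hessian)
    h <- 1
    repeat {
      beta_new <- drop(D %*% (beta[seq_len(k - 1L)] + h * step))
      ll_new <- cll(beta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      h <- h / 2
      if (h < 1e-10) { beta_new <- beta; ll_new <- ll; break }
    }
    beta <- beta_new
    ll <- ll_new
  }
  if (!converged)
    stop_raschval(sprintf(
      "CML did not converge in %d iterations (gradient norm %.3g)",
      max_iter, sqrt(sum(derivs(beta)$grad^2))))
  info <- derivs(beta)$info
  V <- MASS::ginv(info)
  se <- sqrt(pmax(diag(V), 0))
  names(beta) <- names(se) <- colnames(X)
  structure(list(beta = beta, se = se, vcov = V, logLik = ll,
                 converged = converged, n_iterations = iter,
                 n_persons_used = n_used, item_labels = colnames(X),
                 data = data),
            class = "rasch_cml")
}

#' @export
coef.rasch_cml <- function(object, ...) object$beta

#' @export
vcov.rasch_cml <- function(object, ...) object$vcov

#' @export
logLik.rasch_cml <- function(object, ...) {
  structure(object$logLik, df = length(object$beta) - 1L,
            class = "logLik")
}

#' @export
print.rasch_cml <- function(x, digits = 3, ...) {
  cat("Rasch model, conditional maximum likelihood\n")
  cat(sprintf("  %d items, %d non-extreme persons, %d iterations\n",
              length(x$beta), x$n_persons_used, x$n_iterations))
  cat("Item difficulties (logits, sum-to-zero):\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' @export
summary.rasch_cml <- function(object, ...) {
  tab <- data.frame(item = object$item_labels,
                    beta = unname(object$beta),
                    se = unname(object$se),
                    row.names = NULL)
  structure(list(table = tab, logLik = object$logLik,
                 n_persons_used = object$n_persons_used,
                 n_iterations = object$n_iterations),
            class = "summary.rasch_cml")
}

#' @export
print.summary.rasch_cml <- function(x, digits = 3, ...) {
  cat("Rasch model (CML)\n")
  cat(sprintf("Conditional log-likelihood: %.3f on %d non-extreme persons\n",
              x$logLik, x$n_persons_used))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Rasch model response probability
#'
#' The item response function of the dichotomous Rasch model,
#' \eqn{P(X = 1) = 1 / (1 + \exp(-(\theta - \beta)))}. Vectorised over both
#' arguments with the usual recycling.
#'
#' @param theta person ability in logits.
#' @param beta item difficulty in logits.
#' @return Endorsement probability in (0, 1).
#' @examples
#' expected_prob(1, 0)  # 0.731
#' @export
expected_prob <- function(theta, beta) {
  stopifnot(is.numeric(theta), is.numeric(beta))
  stats::plogis(theta - beta)
}

#' Predicted endorsement probabilities from a fitted Rasch model
#'
#' @param object a [rasch_cml()] fit.
#' @param theta person abilities; defaults to the weighted-likelihood
#'   estimates for the fitting data.
#' @param ... unused.
#' @return Matrix of expected probabilities, persons x items.
#' @export
predict.rasch_cml <- function(object, theta = NULL, ...) {
  if (is.null(theta)) theta <- ability_wle(object)$theta
  P <- expected_prob(outer(theta, rep(0, length(object$beta)), "+"),
                     outer(rep(0, length(theta)), object$beta, "+"))
  colnames(P) <- object$item_labels
  P
}

#' Residuals of a fitted Rasch model
#'
#' Response residuals \eqn{x - \hat P} or standardised residuals
#' \eqn{(x - \hat P)/\sqrt{\hat P(1-\hat P)}} with \eqn{\hat P} evaluated at
#' the weighted-likelihood person abilities.
#'
#' @param object a [rasch_cml()] fit.
#' @param type `"standardized"` (default) or `"response"`.
#' @param ... unused.
#' @return Persons x items residual matrix.
#' @export
residuals.rasch_cml <- function(object, type = c("standardized", "response"),
                                ...) {
  type <- match.arg(type)
  X <- resp(object$data)
  P <- predict(object)
  R <- X - P
  if (type == "standardized") R <- R / sqrt(P * (1 - P))
  R
}

#' Simulate responses from a fitted Rasch model
#'
#' Draws new response matrices at the fitted item difficulties, with person
#' abilities sampled from a normal latent-trait distribution.
#'
#' @param object a [rasch_cml()] fit.
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param n_persons persons per dataset; defaults to the fitting sample size.
#' @param theta_mean,theta_sd latent trait distribution.
#' @param ... unused.
#' @return A list of `response_matrix` objects of length `nsim` (a single
#'   object if `nsim = 1`).
#' @export
simulate.rasch_cml <- function(object, nsim = 1, seed = NULL,
                               n_persons = n_persons(object$data),
                               theta_mean = 0, theta_sd = 1, ...) {
  sims <- with_seed(seed, lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(n_persons = n_persons,
                      item_difficulties = object$beta,
                      theta_mean = theta_mean, theta_sd = theta_sd,
                      seed = NULL)
    simulate_responses(cfg)
  }))
  if (nsim == 1) sims[[1]] else sims
}

#' @export
plot.rasch_cml <- function(x, ...) {
  ab <- ability_wle(x)
  plot_wright(ab$theta, x$beta, ...)
}
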