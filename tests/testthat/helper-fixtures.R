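# shared fixtures and independent oracles

# difficulties of the 7-item retained symptom set (logits)
retained_difficulties <- function() {
  c(sad = 0.06, no_interest = 1.57, sleep = 0.18, cognition = 0.39,
    suicidal_ideas = 1.13, mood_instability = 2.29, irritability = -0.75)
}

# the 10-item planted scenario: 7 well-behaved items, two weakly
# discriminating items (slope 0.3) and one near-duplicate of 'cognition'
planted_scenario_config <- function(seed, n_persons = 1200) {
  beta <- c(retained_difficulties(), bad1 = 0.5, bad2 = 1.0, dup = 0.39)
  sim_config(n_persons = n_persons, item_difficulties = beta,
             slopes = c(rep(1, 7), 0.3, 0.3, 1),
             dependence = list(list("cognition", "dup", 0.9)),
             seed = seed)
}

# fixed set of estimable 5-person x 3-item response matrices
tiny_fixture_matrices <- function() {
  raw <- list(
    c(1,1,0,1,1, 1,1,0,1,1, 0,1,1,0,0),
    c(1,1,0,0,1, 1,0,1,1,0, 1,0,1,0,1),
    c(1,1,1,1,0, 1,1,1,0,1, 1,0,0,1,1),
    c(1,1,0,1,1, 0,0,0,1,1, 1,0,1,0,0),
    c(1,1,0,0,0, 1,1,0,1,1, 0,0,1,1,0),
    c(1,0,0,0,0, 0,0,0,0,1, 1,0,1,1,0),
    c(0,1,0,0,1, 0,0,0,0,1, 0,0,0,1,0),
    c(1,0,1,1,1, 1,0,0,1,1, 0,1,0,1,1))
  lapply(raw, matrix, nrow = 5, ncol = 3)
}

# brute-force elementary symmetric functions by subset enumeration
bf_esf <- function(eps) {
  k <- length(eps)
  g <- numeric(k + 1)
  g[1] <- 1
  for (r in seq_len(k)) {
    cmb <- utils::combn(k, r)
    g[r + 1] <- sum(apply(cmb, 2, function(ix) prod(eps[ix])))
  }
  g
}

# direct numerical maximisation of the enumerated conditional likelihood,
# independent of the package's estimation path
bf_cml <- function(X) {
  k <- ncol(X)
  r <- rowSums(X)
  keep <- r > 0 & r < k
  Xn <- X[keep, , drop = FALSE]
  rn <- r[keep]
  nll <- function(b) {
    beta <- c(b, -sum(b))
    g <- bf_esf(exp(-beta))
    -sum(-Xn %*% beta - log(g[rn + 1]))
  }
  o <- stats::optim(rep(0, k - 1), nll, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 1000))
  c(o$par, -sum(o$par))
}

# simulate plain Rasch responses outside the package generator (independent
# path for cross-checks)
bf_rasch_data <- function(n, beta, theta_sd = 1, seed = 1) {
  set.seed(seed)
  theta <- rnorm(n, 0, theta_sd)
  P <- stats::plogis(outer(theta, beta, "-"))
  matrix(rbinom(n * length(beta), 1, P), n, length(beta),
         dimnames = list(NULL, names(beta)))
}
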