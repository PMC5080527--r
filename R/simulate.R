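#' Default symptom item difficulties
#'
#' Named vector of the 11 depression-symptom difficulties (logits) used as
#' the generator default: nine standard diagnostic symptoms plus mood
#' instability and irritability, spanning roughly -0.8 (irritability, the
#' most commonly endorsed) to +2.3 logits (mood instability, the rarest).
#'
#' @return Named numeric vector of length 11.
#' @export
default_item_difficulties <- function() {
  c(sad = 0.05, no_interest = 1.60, weight_appetite = 0.72, sleep = 0.17,
    agitation = 2.23, fatigue = -0.25, self_blame = 2.23, cognition = 0.39,
    suicidal_ideas = 1.14, mood_instability = 2.33, irritability = -0.77)
}

#' Configuration for the synthetic response generator
#'
#' Describes a generating model for dichotomous item responses: a Rasch model
#' by default, with optional planted violations of each assumption the
#' validation pipeline tests. The defaults emulate an epidemiological symptom
#' survey: 11 binary depression-symptom indicators with difficulties spanning
#' about -0.8 to +2.3 logits and a unimodal standard-normal latent trait,
#' sampled 500 persons at a time.
#'
#' @param n_persons number of persons to generate.
#' @param item_difficulties numeric vector of \eqn{\beta_i} in logits (named
#'   vector supplies item labels).
#' @param theta_mean,theta_sd latent-trait normal distribution (logits).
#' @param slopes per-item discrimination \eqn{a_i}; the default 1 for every
#'   item is the Rasch model, other values plant misfit (a two-parameter
#'   mechanism used only for generation, never estimated).
#' @param dif optional list of DIF specifications, each a list with elements
#'   `item` (label or index), `covariate` (name), `delta` (uniform shift in
#'   logits, split symmetrically as \eqn{\beta_i \pm \delta/2} so the pooled
#'   difficulty is unchanged) and optional `slope_ratio` (non-uniform DIF:
#'   the focal group's slope is multiplied by this ratio).
#' @param dependence optional list of local-dependence specifications, each
#'   `list(item_i, item_j, rho)`: after generation, person v's response to
#'   `item_j` is overwritten by the response to `item_i` with probability
#'   `rho`.
#' @param second_dim optional `list(items, loading, sd)`: the listed items
#'   additionally load (`loading` \eqn{= \lambda_2}) on an independent second
#'   latent trait with standard deviation `sd`.
#' @param covariate_names names of balanced random binary person covariates to
#'   generate (covariates referenced by `dif` are added automatically).
#' @param seed integer seed; fully determines the generated data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 500,
                       item_difficulties = default_item_difficulties(),
                       theta_mean = 0, theta_sd = 1,
                       slopes = rep(1, length(item_difficulties)),
                       dif = NULL, dependence = NULL, second_dim = NULL,
                       covariate_names = character(), seed = NULL) {
  beta <- item_difficulties
  if (any(!is.finite(beta))) stop_raschval("item difficulties must be finite")
  if (is.null(names(beta))) names(beta) <- paste0("item", seq_along(beta))
  if (length(slopes) == 1) slopes <- rep(slopes, length(beta))
  if (length(slopes) != length(beta))
    stop_raschval("slopes must have one value per item")
  if (any(slopes < 0)) stop_raschval("slopes must be non-negative")
  if (theta_sd < 0) stop_raschval("theta_sd must be non-negative")
  canon_item <- function(it) {
    if (is.character(it)) it <- match(it, names(beta))
    if (is.na(it) || it < 1 || it > length(beta))
      stop_raschval("unknown item in specification")
    as.integer(it)
  }
  if (!is.null(dif)) {
    dif <- lapply(dif, function(d) {
      d$item <- canon_item(d$item)
      d$delta <- d$delta %||% 0
      d$slope_ratio <- d$slope_ratio %||% 1
      if (is.null(d$covariate)) stop_raschval("dif entries need a covariate name")
      d
    })
    covariate_names <- union(covariate_names,
                             vapply(dif, `[[`, "", "covariate"))
  }
  if (!is.null(dependence)) {
    dependence <- lapply(dependence, function(d) {
      names(d)[seq_len(3)] <- c("item_i", "item_j", "rho")[seq_len(length(d))]
      d$item_i <- canon_item(d$item_i); d$item_j <- canon_item(d$item_j)
      if (!is.numeric(d$rho) || d$rho < 0 || d$rho > 1)
        stop_raschval("copy probability rho must be in [0, 1]")
      d
    })
  }
  if (!is.null(second_dim)) {
    second_dim$items <- vapply(second_dim$items, canon_item, integer(1))
    second_dim$loading <- second_dim$loading %||% 1
    second_dim$sd <- second_dim$sd %||% 1
  }
  structure(list(n_persons = n_persons, item_difficulties = beta,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 slopes = slopes, dif = dif, dependence = dependence,
                 second_dim = second_dim, covariate_names = covariate_names,
                 seed = seed),
            class = "sim_config")
}

#' Generate synthetic dichotomous responses
#'
#' Draws a persons-by-items binary response matrix from the generating model
#' described by a [sim_config()]. Cell v,i is Bernoulli with
#' \deqn{logit P_{vi} = a_{vi} (\theta_v + \lambda_2 \theta_{2v}
#'   1[i \in \mathrm{dim2}] - \beta_{vi})}
#' where \eqn{\beta_{vi}} includes any uniform DIF shift (\eqn{\pm\delta/2}
#' by group) and \eqn{a_{vi}} any group-specific slope ratio; afterwards each
#' planted dependence pair copies item i's response onto item j with
#' probability \eqn{\rho}. A fixed seed yields byte-identical output.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return A [response_matrix()] carrying a `truth` attribute: a list with
#'   the generating `theta`, `theta2`, per-cell expectation inputs and the
#'   config itself, for use in method-checking assertions.
#' @examples
#' rm <- simulate_responses(sim_config(n_persons = 100, seed = 42))
#' colMeans(rm)
#' @export
simulate_responses <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$n_persons
    beta <- config$item_difficulties
    k <- length(beta)
    theta <- stats::rnorm(n, config$theta_mean, config$theta_sd)
    theta2 <- if (!is.null(config$second_dim))
      stats::rnorm(n, 0, config$second_dim$sd) else NULL
    cov <- NULL
    if (length(config$covariate_names)) {
      cov <- lapply(config$covariate_names,
                    function(nm) sample(rep(0:1, length.out = n)))
      names(cov) <- config$covariate_names
    }
    B <- matrix(beta, n, k, byrow = TRUE)
    A <- matrix(config$slopes, n, k, byrow = TRUE)
    for (d in config$dif %||% list()) {
      g <- cov[[d$covariate]]
      B[, d$item] <- B[, d$item] + ifelse(g == 1, d$delta / 2, -d$delta / 2)
      if (d$slope_ratio != 1)
        A[, d$item] <- A[, d$item] * ifelse(g == 1, d$slope_ratio, 1)
    }
    L <- theta
    if (!is.null(config$second_dim)) {
      L2 <- matrix(0, n, k)
      L2[, config$second_dim$items] <- config$second_dim$loading * theta2
      L <- L + L2
    }
    P <- stats::plogis(A * (L - B))
    X <- matrix(stats::rbinom(n * k, 1L, P), n, k)
    for (d in config$dependence %||% list()) {
      copy <- stats::runif(n) < d$rho
      X[copy, d$item_j] <- X[copy, d$item_i]
    }
    out <- response_matrix(X, item_labels = names(beta), covariates = cov)
    attr(out, "truth") <- list(theta = theta, theta2 = theta2, config = config)
    out
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic response config: %d persons, %d items, theta ~ N(%g, %g^2)\n",
              x$n_persons, length(x$item_difficulties), x$theta_mean, x$theta_sd))
  planted <- c(if (any(x$slopes != 1)) "misfit slopes",
               if (!is.null(x$dif)) "DIF",
               if (!is.null(x$dependence)) "local dependence",
               if (!is.null(x$second_dim)) "second dimension")
  cat("Planted violations:",
      if (length(planted)) paste(planted, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' The YAML schema mirrors [sim_config()] field for field, so a config can be
#' stored alongside generated data and round-trips losslessly.
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # named vectors must serialise as YAML maps, not bare sequences
  x$item_difficulties <- as.list(x$item_difficulties)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  beta <- unlist(x$item_difficulties)
  do.call(sim_config, c(list(n_persons = x$n_persons, item_difficulties = beta,
                             theta_mean = x$theta_mean, theta_sd = x$theta_sd,
                             slopes = unlist(x$slopes)),
                        x[c("dif", "dependence", "second_dim")],
                        list(covariate_names = as.character(unlist(x$covariate_names)),
                             seed = x$seed)))
}
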