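test_that("parallel analysis reports coherent eigenvalue tables", {
  rm <- simulate_responses(sim_config(n_persons = 400, theta_sd = 1.5,
                                      seed = 31))
  pa <- parallel_analysis(rm, n_sims = 200, seed = 1)
  k <- n_items(rm)
  expect_length(pa$observed_eigenvalues, k)
  expect_length(pa$random_p95, k)
  expect_equal(pa$adjusted_eigenvalues,
               pa$observed_eigenvalues - (pa$random_mean - 1))
  expect_gte(pa$n_retained, 1)
  # observed eigenvalues are invariant to person and item order
  perm <- raschval:::subset_responses(rm, persons = sample(400),
                                      items = sample(k))
  pa2 <- parallel_analysis(perm, n_sims = 200, seed = 1)
  expect_equal(sort(pa2$observed_eigenvalues), sort(pa$observed_eigenvalues))
  expect_equal(pa2$n_retained, pa$n_retained)
})

test_that("parallel analysis rejects unusable input", {
  x <- cbind(a = rep(1L, 50), b = rbinom(50, 1, 0.5))
  expect_error(parallel_analysis(x, n_sims = 100, seed = 1), "constant column")
  expect_error(parallel_analysis(matrix(0:1, 10, 2), n_sims = 10, seed = 1),
               "at least 100")
})

test_that("infit flags planted discrimination misfit in the right direction", {
  slopes <- rep(1, 11)
  slopes[1] <- 0.3   # noisy, under-discriminating
  slopes[4] <- 3     # deterministic, over-discriminating
  rm <- simulate_responses(sim_config(n_persons = 800, slopes = slopes,
                                      seed = 32))
  fit <- rasch_cml(rm)
  inf <- item_infit(fit)
  expect_gt(inf$infit_msq[1], 1.09)
  expect_lt(inf$infit_msq[4], 0.91)
  expect_true(inf$flagged[1] && inf$flagged[4])
  expect_identical(inf$flagged,
                   inf$infit_msq < 0.91 | inf$infit_msq > 1.09)
  expect_true(all(inf$infit_msq > 0))
  # the standardised statistic points the same way as the mean square
  expect_gt(inf$infit_t[1], 0)
  expect_lt(inf$infit_t[4], 0)
})

test_that("an item's infit does not depend on how other items are arranged", {
  rm <- simulate_responses(sim_config(n_persons = 300, seed = 33))
  fit <- rasch_cml(rm)
  inf <- item_infit(fit)
  perm <- c(5, 3, 1, 2, 4, 6:11)
  rmp <- raschval:::subset_responses(rm, items = perm)
  infp <- item_infit(rasch_cml(rmp))
  expect_equal(infp$infit_msq[match(inf$item, infp$item)], inf$infit_msq,
               tolerance = 1e-8)
})

test_that("Q3 residual correlations detect a planted dependent pair", {
  cfg <- sim_config(n_persons = 500, seed = 34,
                    dependence = list(list("fatigue", "cognition", 0.9)))
  rm <- simulate_responses(cfg)
  fit <- rasch_cml(rm)
  q3 <- residual_correlations(fit)
  R <- q3$pair_correlations
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 11))
  fp <- q3$flagged_pairs
  expect_equal(nrow(fp), 1)
  expect_setequal(c(fp$item_i, fp$item_j), c("fatigue", "cognition"))
  expect_gt(fp$r, 0.2)
  expect_lte(fp$p_holm, 0.05)
})

test_that("Holm adjustment treats all pairs as one family", {
  rm <- simulate_responses(sim_config(n_persons = 250, seed = 35))
  fit <- rasch_cml(rm)
  q3 <- residual_correlations(fit)
  p <- q3$pairs
  expect_equal(nrow(p), 11 * 10 / 2)
  # step-down definition applied by hand to the package's raw p-values
  m <- nrow(p)
  o <- order(p$p_raw)
  hand <- cummax(pmin((m - seq_len(m) + 1) * p$p_raw[o], 1))
  expect_equal(p$p_holm[o], hand)
  expect_true(all(p$p_holm >= p$p_raw))
})
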