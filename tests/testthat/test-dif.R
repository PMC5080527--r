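test_that("Mantel-Haenszel test agrees with the reference implementation", {
  cfg <- sim_config(n_persons = 400, seed = 41, covariate_names = "sex")
  rm <- simulate_responses(cfg)
  g <- covariates(rm)$sex
  ours <- dif_mh(rm, "sleep", "sex")

  # independent oracle: stats::mantelhaen.test on the same score strata
  X <- raschval:::resp(rm)
  score <- rowSums(X)
  keep <- score %in% names(which(table(score) > 0))
  tab <- table(group = factor(g, c(1, 0)),
               response = factor(X[, "sleep"], c(1, 0)),
               stratum = score)
  ok <- apply(tab, 3, function(t2) all(rowSums(t2) > 0) && all(colSums(t2) > 0))
  ref <- stats::mantelhaen.test(tab[, , ok], correct = TRUE, exact = FALSE)
  expect_equal(ours$mh_chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$mh_p, ref$p.value, tolerance = 1e-10)
  expect_equal(ours$mh_or, unname(ref$estimate), tolerance = 1e-8)

  # swapping the group labels leaves the statistic unchanged
  rm2 <- response_matrix(X, covariates = list(sex = 1 - g))
  swapped <- dif_mh(rm2, "sleep", "sex")
  expect_equal(swapped$mh_chi2, ours$mh_chi2, tolerance = 1e-10)
  expect_equal(swapped$mh_log_or, -ours$mh_log_or, tolerance = 1e-10)
})

test_that("single-stratum MH reduces to the continuity-corrected 2x2 test", {
  # one informative stratum by construction: 2 items, scores restricted to 1
  x <- c(rep(1, 30), rep(0, 50))
  X <- cbind(a = x, b = 1 - x)  # every raw score is exactly 1
  g <- rep(c(0, 1), 40)
  rm <- response_matrix(X, covariates = list(g = g))
  ours <- dif_mh(rm, "a", "g")
  ref <- stats::chisq.test(table(g, x), correct = TRUE)
  expect_equal(ours$mh_chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$n_strata, 1)
})

test_that("Breslow-Day is zero for identical strata and detects crossing DIF", {
  # two identical informative strata: perfect odds-ratio homogeneity.
  # Raw score = a + (1 - a) + stratum = 1 + stratum, so the third column
  # splits persons into exactly two score strata with the same 2x2 table.
  one <- list(x = c(rep(1, 10), rep(0, 5), rep(1, 6), rep(0, 9)),
              g = c(rep(1, 15), rep(0, 15)))
  x <- rep(one$x, 2)
  g <- rep(one$g, 2)
  stratum <- rep(c(0L, 1L), each = 30)
  rm <- response_matrix(cbind(a = x, b = 1L - x, c = stratum),
                        covariates = list(g = g))
  bd <- dif_bd(rm, "a", "g")
  expect_equal(bd$n_strata, 2)
  expect_equal(bd$bd_chi2, 0, tolerance = 1e-8)
  expect_equal(bd$bd_df, bd$n_strata - 1L)

  # strong crossing DIF is detected even though the groups share marginal
  # difficulty
  cfg <- sim_config(n_persons = 2000, seed = 42,
                    dif = list(list(item = "sleep", covariate = "sex",
                                    delta = 0, slope_ratio = 4)))
  rmx <- simulate_responses(cfg)
  bd2 <- dif_bd(rmx, "sleep", "sex")
  expect_lt(bd2$bd_p, 0.05)
})

test_that("the combined decision rule flags on either significant test", {
  expect_false(dif_decision(0.28, 0.55))
  expect_true(dif_decision(0.00, 0.54))
  expect_true(dif_decision(0.66, 0.01))
  expect_false(dif_decision(0.05, 0.05))  # strict inequality at the boundary
  expect_warning(f <- dif_decision(0.2, NA), "untestable")
  expect_false(f)
})

test_that("tau-squared matches hand evaluation of the weighted moments formula", {
  d <- dtf_tau2(c(0, 1), c(1, 1))
  expect_equal(d$tau2, -0.75)
  expect_identical(d$effect_band, "small")

  # zero dispersion forces the estimator to its negative floor -sum(w)/sum(w^2)
  d0 <- dtf_tau2(c(0.4, 0.4, 0.4), c(1, 2, 4))
  w <- 1 / c(1, 2, 4)
  expect_equal(d0$tau2, -sum(w) / sum(w^2))
  expect_lt(d0$tau2, 0)

  # large dispersion: ((2 * 100^2 * 1) - 200) / (2 * 100^2) = 0.99
  d1 <- dtf_tau2(c(-1, 1), c(0.01, 0.01))
  expect_equal(d1$tau2, 0.99)
  expect_identical(d1$effect_band, "large")

  # shift invariance
  d2 <- dtf_tau2(c(-1, 1) + 5, c(0.01, 0.01))
  expect_equal(d2$tau2, d1$tau2)
  expect_error(dtf_tau2(1, 1), "at least 2")
})

test_that("effect bands split at 0.07 and 0.14 with boundaries in the lower band", {
  # lambda = (0, x), v = (1, 1) gives tau2 = x^2/4 - 1
  tau_at <- function(t) dtf_tau2(c(0, 2 * sqrt(1 + t)), c(1, 1))$effect_band
  expect_identical(tau_at(0.0699), "small")
  expect_identical(tau_at(0.0701), "medium")
  expect_identical(tau_at(0.1399), "medium")
  expect_identical(tau_at(0.1401), "large")
})

test_that("dif_test assembles a per-item report with a tau-squared summary", {
  cfg <- sim_config(n_persons = 500, seed = 43,
                    dif = list(list(item = "irritability", covariate = "sex",
                                    delta = 1.2)))
  rm <- simulate_responses(cfg)
  res <- dif_test(rm, "sex")
  expect_equal(nrow(res$table), 11)
  expect_true(res$table$flagged[res$table$item == "irritability"])
  expect_identical(res$table$flagged,
                   res$table$mh_p < 0.05 | res$table$bd_p < 0.05)
  expect_true(res$effect_band %in% c("small", "medium", "large"))
})

test_that("MH log odds ratio converges to the planted uniform shift", {
  cfg <- sim_config(n_persons = 5000, seed = 44,
                    dif = list(list(item = "sleep", covariate = "sex",
                                    delta = 1)))
  rm <- simulate_responses(cfg)
  mh <- dif_mh(rm, "sleep", "sex")
  # group 1 faces the harder variant, so its endorsement odds are lower
  expect_equal(mh$mh_log_or, -1, tolerance = 0.15)
})
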