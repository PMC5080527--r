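test_that("a fixed seed fully determines the generated data", {
  cfg <- sim_config(n_persons = 120, seed = 99,
                    dif = list(list(item = "sad", covariate = "sex",
                                    delta = 0.5)),
                    dependence = list(list("fatigue", "cognition", 0.3)))
  a <- simulate_responses(cfg)
  b <- simulate_responses(cfg)
  expect_identical(unclass(a), unclass(b))
  c <- simulate_responses(cfg, seed = 100)
  expect_false(identical(unclass(a), unclass(c)))
})

test_that("degenerate configurations produce the forced patterns", {
  # beta = 0, theta degenerate at 0: every cell is Bernoulli(0.5)
  cfg <- sim_config(n_persons = 600, item_difficulties = rep(0, 11),
                    theta_sd = 0, seed = 21)
  x <- simulate_responses(cfg)
  se <- 0.5 / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.5), 3 * se)

  # copy probability 1 duplicates the source column
  cfg2 <- sim_config(n_persons = 200, seed = 22,
                     dependence = list(list(6, 8, 1)))
  x2 <- simulate_responses(cfg2)
  expect_identical(x2[, 6], x2[, 8])
})

test_that("endorsement decreases with difficulty under the default survey profile", {
  beta <- default_item_difficulties()
  p <- colMeans(simulate_responses(sim_config(n_persons = 4000, seed = 23)))
  expect_gt(cor(p, -beta, method = "spearman"), 0.95)
  expect_identical(names(which.max(p)), "irritability")
  expect_identical(names(which.min(p)), "mood_instability")
})

test_that("invalid generator settings are rejected", {
  expect_error(sim_config(dependence = list(list(1, 2, 1.2))), "rho")
  expect_error(sim_config(item_difficulties = c(0, Inf)), "finite")
  expect_error(sim_config(dif = list(list(item = "nope", covariate = "g",
                                          delta = 1))), "unknown item")
  expect_error(sim_config(slopes = c(1, 1)), "per item")
})

test_that("uniform DIF splits difficulty symmetrically by group", {
  cfg <- sim_config(n_persons = 6000, seed = 24,
                    dif = list(list(item = "sleep", covariate = "sex",
                                    delta = 1)))
  x <- simulate_responses(cfg)
  g <- covariates(x)$sex
  expect_equal(sum(g), 3000)  # balanced assignment
  p1 <- mean(x[g == 1, "sleep"])
  p0 <- mean(x[g == 0, "sleep"])
  expect_gt(p0, p1)  # group 1 faces the harder variant
  # pooled endorsement stays close to the no-DIF rate
  x0 <- simulate_responses(sim_config(n_persons = 6000, seed = 24))
  expect_lt(abs(mean(x[, "sleep"]) - mean(x0[, "sleep"])), 0.03)
})

test_that("generator configs round-trip through YAML", {
  cfg <- sim_config(n_persons = 77, theta_mean = 0.2, theta_sd = 1.3,
                    slopes = c(rep(1, 10), 0.5),
                    dif = list(list(item = 2L, covariate = "sex",
                                    delta = 0.4, slope_ratio = 2)),
                    dependence = list(list(1L, 3L, 0.25)),
                    second_dim = list(items = c(4L, 5L), loading = 1.1,
                                      sd = 0.9),
                    seed = 12)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  expect_equal(cfg2, cfg)
  out1 <- simulate_responses(cfg)
  out2 <- simulate_responses(cfg2)
  expect_identical(unclass(out1), unclass(out2))
})
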