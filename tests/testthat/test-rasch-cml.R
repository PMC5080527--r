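test_that("CML difficulties match direct maximisation of the enumerated
           conditional likelihood on small matrices", {
  for (X in tiny_fixture_matrices()) {
    fit <- rasch_cml(response_matrix(X))
    expect_equal(unname(coef(fit)), bf_cml(X), tolerance = 1e-4)
  }
})

test_that("identification and symmetry properties of the CML fit hold", {
  X <- bf_rasch_data(300, c(a = -1, b = 0, c = 0.5, d = 1.5), seed = 2)
  fit <- rasch_cml(X)
  expect_lt(abs(sum(coef(fit))), 1e-8)
  expect_true(all(fit$se > 0))

  # two items with identical response columns get identical difficulties
  Xdup <- cbind(X, e = X[, "c"])
  fdup <- rasch_cml(Xdup)
  expect_equal(unname(coef(fdup)["c"]), unname(coef(fdup)["e"]),
               tolerance = 1e-6)

  # duplicating every person leaves the estimate unchanged
  fstack <- rasch_cml(rbind(X, X))
  expect_equal(coef(fstack), coef(fit), tolerance = 1e-6)
})

test_that("inestimable items and degenerate inputs are rejected", {
  X <- bf_rasch_data(50, c(a = 0, b = 0.5, c = 1), seed = 3)
  X[, "b"] <- 0L
  expect_error(rasch_cml(X), "'b' is inestimable")
  expect_error(rasch_cml(X[, 1, drop = FALSE]), "at least 2 items")
})

test_that("fitted probabilities reproduce item endorsement rates", {
  # persons and items share one scale: the model-implied mean endorsement at
  # the estimated person measures tracks the observed item means
  X <- bf_rasch_data(800, retained_difficulties(), seed = 4)
  fit <- rasch_cml(X)
  P <- predict(fit)
  expect_lt(max(abs(colMeans(P) - colMeans(X))), 0.05)
})

test_that("the logistic response function evaluates correctly", {
  expect_equal(expected_prob(0, 0), 0.5)
  expect_equal(expected_prob(1, 0), 0.7310586, tolerance = 1e-6)
  expect_equal(expected_prob(40, 0), 1)
  expect_equal(expected_prob(c(0, 1), c(0, 1)), c(0.5, 0.5))
})

test_that("simulate method reproduces the fitted difficulty profile", {
  X <- bf_rasch_data(400, retained_difficulties(), seed = 5)
  fit <- rasch_cml(X)
  sims <- simulate(fit, nsim = 2, seed = 9, n_persons = 2000)
  expect_length(sims, 2)
  refit <- rasch_cml(sims[[1]])
  expect_gt(cor(coef(refit), coef(fit), method = "spearman"), 0.95)
})
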