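test_that("Cronbach's alpha matches hand computation and its limits", {
  # hand oracle: X = [[1,1],[0,0],[1,0]]; item variances 1/3 each, total
  # score variance 1, so alpha = 2 * (1 - (2/3)/1) = 2/3
  X <- matrix(c(1, 0, 1, 1, 0, 0), 3, 2)
  expect_equal(cronbach_alpha(X), 2 / 3)

  # identical columns are perfectly consistent
  col <- rbinom(100, 1, 0.5)
  expect_equal(cronbach_alpha(cbind(col, col, col, col)), 1)

  expect_error(cronbach_alpha(matrix(c(1, 1, 0, 0), 2, 2)), "zero variance")
  expect_error(cronbach_alpha(matrix(0:1, 10, 1)), "at least 2")

  # row order is irrelevant
  rm <- simulate_responses(sim_config(n_persons = 200, seed = 51))
  expect_equal(cronbach_alpha(rm),
               cronbach_alpha(raschval:::resp(rm)[sample(200), ]))
})

test_that("person separation index obeys its defining limits", {
  ab <- data.frame(raw_score = c(1L, 2L, 3L), theta = c(-1, 0, 1),
                   se = c(0, 0, 0))
  expect_equal(person_separation_index(ab), 1)

  v <- stats::var(c(-1, 0, 1))
  ab2 <- data.frame(raw_score = c(1L, 2L, 3L), theta = c(-1, 0, 1),
                    se = rep(sqrt(v), 3))
  expect_equal(person_separation_index(ab2), 0)

  ab3 <- data.frame(raw_score = 1:2, theta = c(0, 0), se = c(1, 1))
  expect_error(person_separation_index(ab3), "zero variance")
})

test_that("more items of the same kind separate persons better", {
  beta7 <- retained_difficulties()
  beta14 <- c(beta7, stats::setNames(beta7, paste0(names(beta7), "_b")))
  psi_of <- function(beta, seed) {
    X <- bf_rasch_data(600, beta, seed = seed)
    person_separation_index(ability_wle(rasch_cml(X)))
  }
  expect_lt(psi_of(beta7, 52), psi_of(beta14, 52))
})

test_that("scale_reliability reports both coefficients with pass flags", {
  rm <- simulate_responses(sim_config(n_persons = 500, seed = 53))
  r <- scale_reliability(rm)
  expect_identical(r$pass_alpha, r$alpha > 0.8)
  expect_identical(r$pass_psi, r$psi > 0.7)
  expect_lte(r$alpha, 1)
  expect_lte(r$psi, 1)
  r7 <- scale_reliability(rm, items = names(retained_difficulties()))
  expect_equal(r7$n_items, 7)
  expect_lt(r7$psi, r$psi)  # dropping items loses separation
})
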