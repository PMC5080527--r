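test_that("response_matrix validates cells, labels and covariates", {
  x <- response_matrix(matrix(c(1, 0, 1, 1, 0, 0), 3, 2),
                       item_labels = c("a", "b"))
  expect_s3_class(x, "response_matrix")
  expect_equal(n_items(x), 2)
  expect_equal(n_persons(x), 3)

  m <- matrix(c(1, 0, 2, 1), 2, 2)
  expect_error(response_matrix(m), "row 1, column 2")
  expect_error(response_matrix(matrix(0:1, 2, 2), item_labels = c("a", "a")),
               "duplicate item label")
  expect_error(response_matrix(matrix(0:1, 2, 2), item_labels = c("a", "b"),
                               covariates = list(g = c(0, 1, 2))),
               "length")
  expect_error(response_matrix(matrix(0:1, 4, 2), item_labels = c("a", "b"),
                               covariates = list(g = c(0, 1, 2, 3))),
               "more than 2 distinct")
})

test_that("read_responses drops incomplete rows and rejects non-binary cells", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,a,b", "1,1,0", "2,0,1", "3,1,1", "4,0,0"), p)
  x <- read_responses(p, c("a", "b"))
  expect_equal(dim(x), c(4L, 2L))
  expect_equal(attr(x, "n_dropped"), 0L)

  writeLines(c("id,a,b", "1,1,0", "2,,1", "3,1,1", "4,0,0", "5,1,1"), p)
  expect_message(x <- read_responses(p, c("a", "b")), "dropped 1 of 5")
  expect_equal(nrow(x), 4L)
  expect_equal(attr(x, "n_dropped"), 1L)

  writeLines(c("id,a,b", "1,1,0", "2,2,1"), p)
  expect_error(read_responses(p, c("a", "b")), "non-binary value 2")
  expect_error(read_responses(p, c("a", "zz")), "zz")
  expect_error(read_responses("no/such/file.csv", "a"), "not found")
})

test_that("writing and reloading a response matrix reproduces it exactly", {
  x <- simulate_responses(sim_config(n_persons = 40, seed = 3,
                                     covariate_names = c("sex", "age_group")))
  p <- withr::local_tempfile(fileext = ".csv")
  write_responses(x, p)
  y <- read_responses(p, colnames(x), c("sex", "age_group"))
  bare <- function(z) {
    z <- raschval:::resp(z)
    matrix(as.integer(z), nrow(z), dimnames = list(NULL, colnames(z)))
  }
  expect_identical(bare(y), bare(x))
  expect_identical(lapply(covariates(y), as.integer),
                   lapply(covariates(x), as.integer))
})

test_that("split_samples draws disjoint deterministic samples", {
  x <- simulate_responses(sim_config(n_persons = 1000, seed = 5))
  sp <- split_samples(x, 500, seed = 1)
  expect_length(intersect(sp$calibration_idx, sp$validation_idx), 0)
  expect_setequal(c(sp$calibration_idx, sp$validation_idx), 1:1000)
  expect_equal(n_persons(sp$calibration), 500)

  sp7a <- split_samples(x, 400, seed = 7)
  sp7b <- split_samples(x, 400, seed = 7)
  expect_identical(sp7a$calibration_idx, sp7b$calibration_idx)
  expect_identical(sp7a$validation_idx, sp7b$validation_idx)

  sp8 <- split_samples(x, 400, seed = 8)
  expect_false(identical(sp7a$calibration_idx, sp8$calibration_idx))

  small <- simulate_responses(sim_config(n_persons = 999, seed = 1))
  expect_error(split_samples(small, 500, seed = 1), "too small")
})

test_that("covariates follow person subsets", {
  x <- simulate_responses(sim_config(n_persons = 100, seed = 2,
                                     covariate_names = "sex"))
  sub <- raschval:::subset_responses(x, persons = 11:30)
  expect_length(covariates(sub)$sex, 20)
  expect_identical(covariates(sub)$sex, covariates(x)$sex[11:30])
})
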