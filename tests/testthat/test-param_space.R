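test_that("parameter definitions enforce their invariants", {
  d <- parameter_def("PAT", 0.5)
  expect_equal(d$lower, 1e-12)
  expect_equal(d$upper, 1)
  expect_error(parameter_def("x", 2, kind = "probability"), "outside")
  expect_error(parameter_def("x", 0.5, kind = "probability", upper = 2),
               "upper bound")
  expect_error(parameter_def("x", 0.5, lower = 0.6, upper = 0.4), "lower")
  expect_error(parameter_def("x", NaN), "non-finite")

  defs <- parameter_defs(parameter_def("a", 0.1), parameter_def("b", 0.2))
  expect_named(defs, c("a", "b"))
  expect_equal(initial_values(defs), c(a = 0.1, b = 0.2))
  expect_error(parameter_defs(parameter_def("a", 0.1),
                              parameter_def("a", 0.2)), "duplicate")
})

test_that("clamp moves out-of-bounds values to the nearest bound and warns", {
  d <- parameter_def("p", 0.5)
  expect_identical(clamp(0.5, d), 0.5)
  expect_warning(v <- clamp(1.08, d), "upper")
  expect_identical(v, 1)
  d2 <- parameter_def("q", 0.5, lower = 1e-12, upper = 1)
  expect_warning(v2 <- clamp(-0.2, d2), "lower")
  expect_identical(v2, 1e-12)
  expect_error(clamp(Inf, d), "corrupted")
})

test_that("clamp is idempotent over random finite inputs", {
  d <- parameter_def("p", 0.5)
  set.seed(42)
  for (x in c(runif(50, -2, 3), 0, 1, 1e-12)) {
    once <- suppressWarnings(clamp(x, d))
    expect_identical(suppressWarnings(clamp(once, d)), once)
  }
})
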