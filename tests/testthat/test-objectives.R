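test_that("the synthetic objective has its maximum at the optimum", {
  opt <- c(a = 0.3, b = 2)
  obj <- synthetic_objective(opt, weights = c(1, 4))
  expect_equal(obj$fn(opt, 1), 0)
  # one coordinate displaced by factor e^k costs w * k^2
  v <- opt
  v[["b"]] <- opt[["b"]] * exp(1.5)
  expect_equal(obj$fn(v, 1), -4 * 1.5^2)
  expect_error(obj$fn(c(a = -1, b = 2), 1), "positive")
})

test_that("synthetic observation noise is centered at the true value", {
  opt <- c(a = 1, b = 1)
  obj <- synthetic_objective(opt, noise_sd = 0.5)
  vals <- vapply(1:800, function(s) obj$fn(opt, derive_seed(99, s)),
                 numeric(1))
  # mean of n draws of N(0, 0.5) has sd 0.5/sqrt(n)
  expect_lt(abs(mean(vals)), 3 * 0.5 / sqrt(length(vals)))
  expect_equal(sd(vals), 0.5, tolerance = 0.15)
})

test_that("evaluate averages replicates under matched child streams", {
  opt <- c(a = 1)
  obj <- synthetic_objective(opt, noise_sd = 1)
  r <- 7L
  avg <- evaluate(obj, opt, seed = 123, replicates = r)
  manual <- mean(vapply(seq_len(r), function(k)
    obj$fn(opt, derive_seed(123, k)), numeric(1)))
  expect_identical(avg, manual)
})

test_that("readouts extract the final-step counts", {
  series <- data.frame(step = c(10, 20), nsr_count = c(2, 5),
                       ctrl_count = c(1, 2), population = c(3, 7),
                       mean_length = c(4, 6))
  expect_equal(readout_nsr_count(series), 5)
  expect_equal(readout_diff(series), 3)
  expect_equal(readout_diff(transform(series, ctrl_count = nsr_count)), 0)
  expect_equal(readout_mean_length(series), 6)
  empty <- data.frame(step = 1, population = 0, mean_length = 5)
  expect_equal(readout_mean_length(empty, fallback = 5), 5)
})

test_that("an NSR objective with nothing inoculated and inert chemistry is 0", {
  wc <- tiny_nsr_config()
  obj <- nsr_objective("nsr_count", wc, reference_step = 50,
                       inoculations = data.frame(species = character(0),
                                                 copies = integer(0),
                                                 step = integer(0)))
  zero <- setNames(rep(0, 8), names(nsr_start_unfavorable()))
  expect_equal(evaluate(obj, zero, seed = 1), 0)
})

test_that("derive_seed is deterministic, path-sensitive and in range", {
  expect_identical(derive_seed(1, 2, 3), derive_seed(1, 2, 3))
  expect_false(derive_seed(1, 2, 3) == derive_seed(1, 3, 2))
  set.seed(1)
  s <- replicate(200, derive_seed(sample.int(1e6, 1), sample.int(100, 1)))
  expect_true(all(s >= 0 & s < 2^31))
})
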