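test_that("probe reproduces hand-computed deltas for a linear objective", {
  obj <- fn_objective("linear", function(v) v[["p1"]] + 2 * v[["p2"]])
  defs <- wide_defs(c(p1 = 1, p2 = 1))
  d <- probe(obj, c(p1 = 1, p2 = 1), defs, e = 0.1, directions = c(1, 1),
             round = 1, seed = 1)
  expect_equal(d$base, 3)
  expect_equal(unname(d$deltas), c(0.1, 0.2))
  expect_equal(d$max_abs, 0.2)
  expect_equal(d$evaluations, 3L)

  # constant objective: all deltas zero
  d0 <- probe(fn_objective("const", function(v) 7), c(p1 = 1, p2 = 1),
              defs, e = 0.1, directions = c(1, 1), round = 1, seed = 1)
  expect_equal(unname(d0$deltas), c(0, 0))
  expect_equal(d0$max_abs, 0)
})

test_that("probe aborts with a diagnostic on a non-finite objective", {
  obj <- objective("bad", function(values, seed) NaN)
  defs <- wide_defs(c(p1 = 1))
  expect_error(probe(obj, c(p1 = 1), defs, 0.1, 1, 1, 1), "non-finite")
})

test_that("gradient_update matches hand-applied examples", {
  defs <- wide_defs(c(a = 0.4, b = 0.2, c = 0.1))
  delta <- list(deltas = c(a = 2, b = -1, c = 0),
                directions = c(a = 1, b = 1, c = 1), max_abs = 2)
  out <- gradient_update(c(a = 0.4, b = 0.2, c = 0.1), defs, delta,
                         e = 0.5, step_form = "additive")
  expect_equal(unname(unclass(out)[1:3]), c(0.6, 0.15, 0.1),
               ignore_attr = TRUE)

  # all deltas equal and positive: every parameter takes the full factor
  d2 <- list(deltas = c(a = 1, b = 1, c = 1),
             directions = c(a = 1, b = 1, c = 1), max_abs = 1)
  out2 <- gradient_update(c(a = 0.4, b = 0.2, c = 0.1), defs, d2, e = 0.25)
  expect_equal(unname(unclass(out2)[1:3]), c(0.4, 0.2, 0.1) * 1.25)

  # zero gradient: parameters unchanged
  d3 <- list(deltas = c(a = 0, b = 0, c = 0),
             directions = c(a = 1, b = 1, c = 1), max_abs = 0)
  expect_equal(unclass(gradient_update(c(a = 0.4, b = 0.2, c = 0.1), defs,
                                       d3, e = 0.5))[1:3],
               c(a = 0.4, b = 0.2, c = 0.1))

  # multiplicative downward form at full scale divides by (1 + e)
  defs1 <- wide_defs(c(a = 0.4))
  d4 <- list(deltas = c(a = -2), directions = c(a = 1), max_abs = 2)
  out4 <- gradient_update(c(a = 0.4), defs1, d4, e = 0.5,
                          step_form = "multiplicative")
  expect_equal(unname(out4[["a"]]), 0.4 / 1.5)
})

test_that("next_directions follows the sign of the realized movement", {
  d <- list(deltas = c(a = 3, b = -2), directions = c(a = 1, b = 1))
  expect_equal(unname(next_directions(d)), c(1, -1))
  # downward probe that helped: keep probing downward
  d2 <- list(deltas = c(a = 5), directions = c(a = -1))
  expect_equal(unname(next_directions(d2)), -1)
  # unchanged objective: configured zero-change direction
  d3 <- list(deltas = c(a = 0), directions = c(a = 1))
  expect_equal(unname(next_directions(d3, "up")), 1)
  expect_equal(unname(next_directions(d3, "down")), -1)
})

test_that("a constant objective leaves parameters untouched in a full run", {
  obj <- fn_objective("const", function(v) 1)
  defs <- wide_defs(c(a = 0.3, b = 0.8))
  tr <- run_gradient_ascent(obj, defs, learning_config(0.3, rounds = 5))
  expect_true(all(tr$rounds$a == 0.3))
  expect_true(all(tr$rounds$b == 0.8))
})

test_that("a monotone 1-parameter objective iterates the closed form", {
  obj <- fn_objective("identity", function(v) v[["p"]])
  defs <- parameter_defs(parameter_def("p", 0.1, lower = 1e-12, upper = 1))
  tr <- run_gradient_ascent(obj, defs, learning_config(0.5, rounds = 8))
  expect_equal(tr$rounds$p, pmin(1, 0.1 * 1.5^(1:8)))
})

test_that("identical config and seed give identical traces", {
  pr <- recovery_problem(noise_sd = 0.1)
  cfg <- learning_config(0.2, rounds = 6, seed = 33)
  t1 <- run_gradient_ascent(pr$objective, pr$defs, cfg, start = pr$start)
  t2 <- run_gradient_ascent(pr$objective, pr$defs, cfg, start = pr$start)
  expect_identical(t1$rounds, t2$rounds)
  expect_identical(t1$deltas, t2$deltas)
})

test_that("descent on O equals ascent on -O identically", {
  pr <- recovery_problem(noise_sd = 0.05)
  neg <- objective("neg", function(values, seed)
    -pr$objective$fn(values, seed))
  cfg_d <- learning_config(0.2, rounds = 6, seed = 5, direction = "descent")
  cfg_a <- learning_config(0.2, rounds = 6, seed = 5, direction = "ascent")
  td <- run_gradient_ascent(neg, pr$defs, cfg_d, start = pr$start)
  ta <- run_gradient_ascent(pr$objective, pr$defs, cfg_a, start = pr$start)
  expect_equal(td$rounds[, -1], ta$rounds[, -1])
})

test_that("coordinate candidates list the seven-point geometric grid", {
  d <- parameter_def("p", 0.2)
  expect_equal(coordinate_candidates(0.2, 0.5, d),
               c(0.2, 0.3, 0.45, 0.675, 0.1, 0.05, 0.025))
  # candidates above a probability bound are dropped
  expect_equal(coordinate_candidates(0.9, 0.5, d),
               c(0.9, 0.45, 0.225, 0.1125))
  # the current value always survives
  expect_true(0.33 %in% coordinate_candidates(0.33, 0.17, d))
})

test_that("coordinate ascent installs the exact optimum among candidates", {
  obj <- fn_objective("quad", function(v) -(v[["p1"]] - 0.3)^2)
  defs <- parameter_defs(parameter_def("p1", 0.2))
  cfg <- learning_config(0.5, rounds = 1, strategy = "coordinate")
  tr <- run_coordinate_ascent(obj, defs, cfg)
  expect_equal(tr$rounds$p1[1], 0.3)
  expect_equal(tr$evaluations[1], 7L)
})

test_that("coordinate ascent retains the incumbent under ties", {
  obj <- fn_objective("const", function(v) 2)
  defs <- parameter_defs(parameter_def("p1", 0.2), parameter_def("p2", 0.6))
  cfg <- learning_config(0.5, rounds = 3, strategy = "coordinate")
  tr <- run_coordinate_ascent(obj, defs, cfg)
  expect_true(all(tr$rounds$p1 == 0.2))
  expect_true(all(tr$rounds$p2 == 0.6))
  # 7 candidates for p1 = 0.2; two up-candidates of p2 = 0.6 exceed the
  # probability bound and are dropped, leaving 5
  expect_equal(tr$evaluations, rep(12L, 3))
})

test_that("progressive schedules warm-start each stage from the last", {
  pr <- recovery_problem()
  sched <- lapply(c(1, 2, 3), function(k)
    list(objective = pr$objective, rounds = 4L))
  cfg <- learning_config(0.2, rounds = 12, seed = 9)
  tr <- run_progressive(sched, pr$defs, cfg, start = pr$start)
  expect_equal(nrow(tr$rounds), 12L)
  expect_equal(tr$stage_boundaries, c(4L, 8L))
  expect_equal(tr$rounds$round, 1:12)
  expect_equal(tr$rounds$stage, rep(1:3, each = 4))

  # a single-stage schedule is exactly a plain gradient run
  tr1 <- run_progressive(list(list(objective = pr$objective, rounds = 6L)),
                         pr$defs, learning_config(0.2, rounds = 6, seed = 9),
                         start = pr$start)
  tr2 <- run_gradient_ascent(pr$objective, pr$defs,
                             learning_config(0.2, rounds = 6, seed = 9),
                             start = pr$start)
  expect_equal(tr1$rounds[, names(tr2$rounds)], tr2$rounds)
})

test_that("trace utilities expose rounds, final values and TSV output", {
  pr <- recovery_problem()
  tr <- run_gradient_ascent(pr$objective, pr$defs,
                            learning_config(0.2, rounds = 3, seed = 2),
                            start = pr$start)
  fv <- final_values(tr)
  expect_named(fv, names(pr$start))
  path <- tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(back), 3)
  expect_equal(names(back), c("round", "objective", names(pr$start)))
  s <- summary(tr)
  expect_equal(s$rounds, 3)
  expect_equal(s$parameters$final, unname(fv))
})
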