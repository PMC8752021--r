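test_that("activity follows the saturating, length-penalized curve", {
  # half-saturation: l = gamma with no length penalty gives beta/2
  expect_equal(replicator_activity(200, 200, 0, 3, 200), 1.5)
  # no devoted monomers, no activity
  expect_equal(replicator_activity(0, 10, 0.1, 3, 200), 0)
  # hand evaluation at the favorable reference values
  expect_equal(replicator_activity(5, 5, 0.1, 3, 200),
               3 * (5 / 205) * exp(-0.5))
  # C++ and R compute the same curve
  set.seed(3)
  for (i in 1:20) {
    l <- sample(0:30, 1); L <- l + sample(0:10, 1)
    a <- runif(1, 0, 0.3); b <- runif(1, 0.5, 4); g <- runif(1, 1, 300)
    expect_equal(evoxplore:::.rep_activity(l, L, a, b, g),
                 replicator_activity(l, L, a, b, g))
  }
})

test_that("lengths stay >= 1 and sites hold at most one replicator", {
  set.seed(14)
  w <- replicator_world(replicator_world_config(lattice_side = 12))
  s <- replicator_run(w, replicator_reference_favorable(), n_steps = 2000,
                      record_every = 200)
  expect_true(all(s$population <= 144))
  sn <- replicator_snapshot(w)
  expect_true(all(sn$l_A + sn$l_B + sn$l_C + sn$l_N >= 1))
  expect_true(!anyDuplicated(sn$site))
  expect_true(all(sn$l_A >= 0 & sn$l_B >= 0 & sn$l_C >= 0 & sn$l_N >= 0))
})

test_that("vanishing replicase activity lets the population decay away", {
  set.seed(8)
  p <- replicator_reference_favorable()
  p[["beta_A"]] <- 1e-9  # the beta -> 0 limit (parameters must stay > 0)
  w <- replicator_world(replicator_world_config(lattice_side = 15))
  s <- replicator_run(w, p, n_steps = 400, record_every = 400)
  expect_equal(s$population, 0)
  expect_equal(s$mean_length, 5)  # extinction fallback
})

test_that("an isolated replicator never replicates (trans-acting replicase)", {
  cfg <- replicator_world_config(lattice_side = 10, decay_prob = 0,
                                 dispersal_prob = 0)
  w <- replicator_world_from_snapshot(
    data.frame(site = 45L, l_A = 2L, l_B = 1L, l_C = 2L, l_N = 0L), cfg)
  set.seed(2)
  s <- replicator_run(w, replicator_reference_favorable(), n_steps = 500,
                      record_every = 500)
  expect_equal(s$population, 1)
  expect_identical(replicator_snapshot(w)$site, 45L)
})

test_that("an empty lattice reports the fallback mean length exactly", {
  w <- replicator_world_from_snapshot(
    data.frame(site = integer(0), l_A = integer(0), l_B = integer(0),
               l_C = integer(0), l_N = integer(0)),
    replicator_world_config(lattice_side = 10))
  set.seed(1)
  s <- replicator_run(w, replicator_reference_favorable(), n_steps = 10,
                      record_every = 5, fallback = 5)
  expect_identical(s$mean_length, c(5, 5))
  expect_identical(s$population, c(0, 0))
})

test_that("equal seeds give identical lattice trajectories", {
  run_once <- function() {
    set.seed(19)
    w <- replicator_world(replicator_world_config(lattice_side = 15))
    replicator_run(w, replicator_reference_favorable(), n_steps = 800,
                   record_every = 100)
  }
  expect_identical(run_once(), run_once())
})

test_that("well-mixed dispersal does not beat limited dispersal", {
  # one-sided comparison over replicate pairs: long-run mean length under
  # full mixing (D = 1) must not exceed the limited-dispersal result
  mean_len <- function(D, seeds, steps = 4000) {
    vapply(seeds, function(sd) {
      set.seed(sd)
      w <- replicator_world(replicator_world_config(lattice_side = 20,
                                                    dispersal_prob = D))
      s <- replicator_run(w, replicator_reference_favorable(),
                          n_steps = steps, record_every = steps)
      s$mean_length[1]
    }, numeric(1))
  }
  lim <- mean_len(0.01, 1:20)
  mix <- mean_len(1, 1:20)
  expect_lte(mean(mix), mean(lim))
})
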