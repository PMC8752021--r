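zero_params <- setNames(rep(0, 8), names(nsr_start_unfavorable()))

test_that("a fresh world holds all material as evenly split precursors", {
  w <- nsr_world(nsr_world_config(grid_side = 10, total_material = 10000))
  ct <- nsr_counts(w)
  expect_equal(ct$precursors, 10000)
  expect_equal(ct$molecules, 0)
  expect_equal(ct$free_nucleotides, 0)
  expect_equal(ct$material, ct$ledger)
  sn <- evoxplore:::.nsr_world_snapshot(w$ptr)
  expect_true(all(sn$rooms$precursors == 100))
  expect_error(nsr_world(nsr_world_config(grid_side = 1)), "grid_side")
})

test_that("inoculation adds exact motif copies and extends the ledger", {
  wc <- tiny_nsr_config()
  set.seed(4)
  w <- nsr_world(wc)
  nsr_inoculate(w, "nsr", 100)
  ct <- nsr_counts(w)
  expect_equal(ct$nsr, 100)
  expect_equal(ct$ctrl, 0)
  expect_equal(ct$ledger, 2000 + 100 * nchar(wc$nsr_motif))
  expect_equal(ct$material, ct$ledger)
  nsr_inoculate(w, "ctrl", 25)
  expect_equal(nsr_counts(w)$ctrl, 25)
  # single-molecule inoculation
  set.seed(4)
  w1 <- nsr_world(wc)
  nsr_inoculate(w1, "nsr", 1)
  expect_equal(nsr_counts(w1)$nsr, 1)
  expect_error(nsr_inoculate(w1, "nsr", 0), "copies")
})

test_that("motif classification is by containment; the complement differs", {
  wc <- tiny_nsr_config()
  motif <- wc$nsr_motif
  expect_true(nsr_is_nsr(motif, wc))
  expect_true(nsr_is_nsr(paste0("GG", motif, "AA"), wc))
  revcomp <- paste(rev(chartr("AUCG", "UAGC",
                              strsplit(motif, "")[[1]])), collapse = "")
  expect_false(nsr_is_nsr(revcomp, wc))
  expect_false(nsr_is_ctrl(motif, wc))
  # knockout: identity retained, function lost
  wck <- tiny_nsr_config(knockout = TRUE)
  expect_true(nsr_is_nsr(motif, wck))
  expect_false(nsr_is_functional(motif, wck))
  expect_true(nsr_is_functional(motif, wc))
})

test_that("all-zero probabilities freeze the world", {
  set.seed(9)
  w <- nsr_world(tiny_nsr_config())
  nsr_inoculate(w, "nsr", 10)
  before <- evoxplore:::.nsr_world_snapshot(w$ptr)
  nsr_step(w, zero_params, 50)
  after <- evoxplore:::.nsr_world_snapshot(w$ptr)
  expect_identical(before$rooms, after$rooms)
  expect_identical(before$molecules, after$molecules)
  expect_identical(before$ledger, after$ledger)
  expect_equal(after$step, 50)
})

test_that("certain formation converts every precursor in one step", {
  set.seed(2)
  w <- nsr_world(tiny_nsr_config())
  p <- zero_params
  p[["PNF"]] <- 1
  nsr_step(w, p, 1)
  ct <- nsr_counts(w)
  expect_equal(ct$precursors, 0)
  expect_equal(ct$free_nucleotides, 2000)
  expect_equal(ct$material, ct$ledger)
})

test_that("nucleotide decay matches its binomial expectation", {
  # fill a world with 2000 free nucleotides, then measure one decay step
  # (PND = 0.01) repeatedly from the same restored state
  wc <- tiny_nsr_config()
  set.seed(6)
  w <- nsr_world(wc)
  p <- zero_params
  p[["PNF"]] <- 1
  nsr_step(w, p, 1)
  snap <- tempfile(fileext = ".tsv")
  write_nsr_snapshot(w, snap)
  pd <- zero_params
  pd[["PND"]] <- 0.01
  set.seed(7)
  decays <- vapply(1:200, function(i) {
    wi <- read_nsr_snapshot(snap, wc)
    nsr_step(wi, pd, 1)
    nsr_counts(wi)$precursors
  }, numeric(1))
  expected <- 2000 * 0.01
  se <- sqrt(2000 * 0.01 * 0.99 / 200)
  expect_lt(abs(mean(decays) - expected), 3 * se)
})

test_that("snapshots round-trip through the plain-text format", {
  wc <- tiny_nsr_config()
  set.seed(11)
  w <- nsr_world(wc)
  nsr_inoculate(w, "nsr", 30)
  nsr_inoculate(w, "ctrl", 10)
  nsr_step(w, nsr_start_unfavorable(), 200)
  path <- tempfile(fileext = ".tsv")
  write_nsr_snapshot(w, path)
  w2 <- read_nsr_snapshot(path, wc)
  expect_equal(nsr_counts(w2), nsr_counts(w))
  expect_equal(evoxplore:::.nsr_world_snapshot(w2$ptr),
               evoxplore:::.nsr_world_snapshot(w$ptr))
})

test_that("equal seeds give identical trajectories", {
  wc <- tiny_nsr_config()
  run_once <- function() {
    set.seed(21)
    w <- nsr_world(wc)
    nsr_run(w, nsr_start_unfavorable(), n_steps = 500,
            inoculations = data.frame(species = "nsr", copies = 20L,
                                      step = 50L),
            record_every = 100)
  }
  expect_identical(run_once(), run_once())
})

test_that("material is conserved along recorded trajectories", {
  wc <- tiny_nsr_config()
  set.seed(31)
  w <- nsr_world(wc)
  s <- nsr_run(w, nsr_reference_favorable(), n_steps = 2000,
               inoculations = data.frame(species = "nsr", copies = 5L,
                                         step = 100L),
               record_every = 250)
  expect_true(all(s$material == nsr_counts(w)$ledger))
  expect_error(
    nsr_run(w, zero_params, n_steps = 10,
            inoculations = data.frame(species = "nsr", copies = 1L,
                                      step = 500L)),
    "outside the run window")
})

test_that("knockout is symmetric under motif exchange with matched seeds", {
  base <- tiny_nsr_config(knockout = TRUE)
  swapped <- nsr_world_config(grid_side = 10, total_material = 2000,
                              nsr_motif = base$ctrl_motif,
                              ctrl_motif = base$nsr_motif,
                              knockout = TRUE)
  run_with <- function(wc, species) {
    set.seed(77)
    w <- nsr_world(wc)
    nsr_run(w, nsr_start_unfavorable(), n_steps = 1500,
            inoculations = data.frame(species = species, copies = 50L,
                                      step = 100L),
            record_every = 300)
  }
  a <- run_with(base, "nsr")
  b <- run_with(swapped, "ctrl")  # physically identical world, labels swapped
  expect_equal(a$nsr_count, b$ctrl_count)
  expect_equal(a$ctrl_count, b$nsr_count)
  expect_equal(a$molecule_count, b$molecule_count)
})

test_that("expected free nucleotides rise with the enzymatic rate", {
  wc <- nsr_world_config(grid_side = 2, total_material = 400)
  mean_free <- function(pnfr, seeds) {
    mean(vapply(seeds, function(sd) {
      set.seed(sd)
      w <- nsr_world(wc)
      nsr_inoculate(w, "nsr", 4)
      p <- zero_params
      p[["PNFR"]] <- pnfr
      p[["PND"]] <- 0.05
      nsr_step(w, p, 40)
      nsr_counts(w)$free_nucleotides
    }, numeric(1)))
  }
  expect_gt(mean_free(0.9, 1:15), mean_free(0.05, 101:115))
})
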