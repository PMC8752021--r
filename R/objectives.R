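#' Construct an objective from an evaluation function
#'
#' An objective binds a simulator (or closed form) to the scalar readout
#' the explorer maximizes. The evaluation contract is
#' `fn(values, seed) -> finite numeric scalar`: one simulation (replicate)
#' at the given named parameter values under the given child seed.
#' Replicate averaging is handled by the explorer via
#' `replicates_per_evaluation`.
#'
#' @param id Short identifier used in traces and messages.
#' @param fn Evaluation function `function(values, seed)`.
#' @param meta Optional list of descriptive fields.
#' @return An `objective` object.
#' @export
objective <- function(id, fn, meta = list()) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fn))
  structure(list(id = id, fn = fn, meta = meta), class = "objective")
}

#' @export
print.objective <- function(x, ...) {
  cat("<objective> ", x$id, "\n", sep = "")
  invisible(x)
}

#' Evaluate an objective (replicate-averaged)
#'
#' Runs `replicates` independent evaluations under child seeds derived from
#' `seed` and returns their mean. With `replicates = 1` this is a single
#' simulation under `derive_seed(seed, 1)`.
#'
#' @param obj An [objective()].
#' @param values Named parameter values.
#' @param seed Seed for this evaluation slot.
#' @param replicates Number of replicates averaged.
#' @return Numeric scalar.
#' @export
evaluate <- function(obj, values, seed, replicates = 1L) {
  stopifnot(inherits(obj, "objective"))
  v <- mean(vapply(seq_len(replicates), function(r)
    obj$fn(values, derive_seed(seed, r)), numeric(1)))
  if (!is.finite(v)) stop("objective '", obj$id, "' returned non-finite value")
  v
}

#' Closed-form concave synthetic objective for optimizer validation
#'
#' `-sum_i w_i (log p_i - log p*_i)^2` plus optional Gaussian observation
#' noise. The global maximum is 0, attained exactly at the optimum, which
#' makes parameter-recovery checks self-evident. Log-space curvature
#' matches the explorer's multiplicative steps, so recovery quality is
#' comparable across parameters of very different magnitudes.
#'
#' @param optimum Named vector of optimal (strictly positive) values.
#' @param weights Per-parameter curvature weights (recycled).
#' @param noise_sd Standard deviation of additive Gaussian noise (0 for a
#'   deterministic objective).
#' @return An [objective()].
#' @export
synthetic_objective <- function(optimum, weights = 1, noise_sd = 0) {
  stopifnot(all(optimum > 0), all(weights > 0), noise_sd >= 0)
  w <- rep_len(weights, length(optimum))
  log_opt <- log(optimum)
  objective(
    id = "synthetic",
    fn = function(values, seed) {
      if (any(values <= 0))
        stop("synthetic objective requires strictly positive parameters")
      v <- -sum(w * (log(values) - log_opt)^2)
      if (noise_sd > 0) v <- v + with_seed(seed, function() stats::rnorm(1, 0, noise_sd))
      v
    },
    meta = list(optimum = optimum, weights = w, noise_sd = noise_sd)
  )
}

#' NSR-count readout of a recorded series
#'
#' @param series Data frame from [nsr_run()].
#' @return NSR count at the final recorded step.
#' @export
readout_nsr_count <- function(series) {
  series$nsr_count[nrow(series)]
}

#' NSR-minus-control readout of a recorded series
#'
#' The difference between NSR and control counts at the final recorded
#' step; may be negative.
#'
#' @param series Data frame from [nsr_run()].
#' @return Integer-valued difference.
#' @export
readout_diff <- function(series) {
  n <- nrow(series)
  series$nsr_count[n] - series$ctrl_count[n]
}

#' Mean replicator length readout
#'
#' @param series Data frame from [replicator_run()].
#' @param fallback Value already applied by the simulator for extinct
#'   populations; retained here for explicitness when reading arbitrary
#'   series.
#' @return Mean length at the final recorded step (the fallback when the
#'   population is extinct — the "odd point" convention).
#' @export
readout_mean_length <- function(series, fallback = 5) {
  n <- nrow(series)
  if (series$population[n] == 0) fallback else series$mean_length[n]
}

#' Objective over the NSR testbed
#'
#' Each evaluation initializes a fresh world under the evaluation's child
#' seed, applies the inoculation schedule, runs to `reference_step` and
#' reads a single-snapshot count — no time averaging.
#'
#' @param readout `"nsr_count"` or `"nsr_minus_ctrl"`.
#' @param world_config An [nsr_world_config()].
#' @param reference_step Step at which the readout is taken; must be at or
#'   after every inoculation.
#' @param inoculations Data frame with columns `species`, `copies`, `step`.
#' @return An [objective()] over the eight NSR parameters.
#' @export
nsr_objective <- function(readout = c("nsr_count", "nsr_minus_ctrl"),
                          world_config = nsr_world_config(),
                          reference_step = 3000,
                          inoculations = data.frame(species = "nsr",
                                                    copies = 100L,
                                                    step = 300L)) {
  readout <- match.arg(readout)
  stopifnot(all(inoculations$step <= reference_step))
  read_fn <- if (readout == "nsr_count") readout_nsr_count else readout_diff
  objective(
    id = readout,
    fn = function(values, seed) {
      with_seed(seed, function() {
        w <- nsr_world(world_config)
        series <- nsr_run(w, values, n_steps = reference_step,
                          inoculations = inoculations,
                          record_every = reference_step)
        read_fn(series)
      })
    },
    meta = list(testbed = "nsr", readout = readout,
                reference_step = reference_step,
                inoculations = inoculations, world_config = world_config)
  )
}

#' Objective over the replicator testbed
#'
#' Each evaluation initializes a fresh lattice under the evaluation's child
#' seed, runs to `reference_step` and reads the mean replicator length,
#' substituting `extinction_fallback` (by convention the initial mean
#' length) when the population has died out — the "odd point" rule.
#'
#' @param world_config A [replicator_world_config()].
#' @param reference_step Sweeps to run before the readout.
#' @param extinction_fallback Mean length reported on extinction.
#' @return An [objective()] over the eight activity-curve parameters.
#' @export
replicator_objective <- function(world_config = replicator_world_config(),
                                 reference_step = 20000,
                                 extinction_fallback = 5) {
  objective(
    id = paste0("mean_replicator_length@", reference_step),
    fn = function(values, seed) {
      with_seed(seed, function() {
        w <- replicator_world(world_config)
        series <- replicator_run(w, values, n_steps = reference_step,
                                 record_every = reference_step,
                                 fallback = extinction_fallback)
        readout_mean_length(series, extinction_fallback)
      })
    },
    meta = list(testbed = "replicator", readout = "mean_replicator_length",
                reference_step = reference_step,
                extinction_fallback = extinction_fallback,
                world_config = world_config)
  )
}
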