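#' The eight explored activity-curve parameters of the replicator model
#'
#' Each activity class X follows
#' `beta_X * l_X / (l_X + gamma_X) * exp(-alpha_X * L)`: `beta` scales the
#' activity, `gamma` half-saturates it in the number of devoted monomers
#' `l_X`, and `alpha` penalizes total length `L`. Class C (metabolic) has
#' no length penalty — there is no `alpha_C`.
#'
#' @param alpha_A,beta_A,gamma_A Replicase (A) curve parameters.
#' @param alpha_B,beta_B,gamma_B Fidelity (B) curve parameters.
#' @param beta_C,gamma_C Metabolic (C) curve parameters.
#' @return Named numeric vector in canonical order.
#' @export
replicator_params <- function(alpha_A, beta_A, gamma_A, alpha_B, beta_B,
                              gamma_B, beta_C, gamma_C) {
  v <- c(alpha_A = alpha_A, beta_A = beta_A, gamma_A = gamma_A,
         alpha_B = alpha_B, beta_B = beta_B, gamma_B = gamma_B,
         beta_C = beta_C, gamma_C = gamma_C)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all replicator parameters must be positive")
  v
}

#' Reference parameter settings for the replicator model
#'
#' `replicator_reference_favorable()` supports the evolution of longer
#' replicators; `replicator_start_unfavorable()` (a doubled length penalty
#' and weakened activities) does not, and is the learning start.
#'
#' @return Named parameter vector (see [replicator_params()]).
#' @export
replicator_reference_favorable <- function() {
  replicator_params(alpha_A = 0.1, beta_A = 3, gamma_A = 200,
                    alpha_B = 0.1, beta_B = 3, gamma_B = 200,
                    beta_C = 2, gamma_C = 5)
}

#' @rdname replicator_reference_favorable
#' @export
replicator_start_unfavorable <- function() {
  replicator_params(alpha_A = 0.2, beta_A = 2, gamma_A = 200,
                    alpha_B = 0.2, beta_B = 2, gamma_B = 200,
                    beta_C = 1, gamma_C = 5)
}

#' Parameter definitions for exploring the replicator model
#'
#' @param initial Named vector of starting values (defaults to the
#'   unfavorable reference setting).
#' @return A `parameter_defs` of eight positive reals.
#' @export
replicator_parameter_defs <- function(initial = replicator_start_unfavorable()) {
  parameter_defs(lapply(names(initial), function(nm)
    parameter_def(nm, initial[[nm]], kind = "positive-real")))
}

#' Configure a replicator lattice
#'
#' @param lattice_side Sites per side of the toroidal lattice (>= 3).
#' @param initial_occupancy Probability that a site starts occupied.
#' @param initial_length Founder replicator length in monomers; founders
#'   carry one monomer of each activity class and neutral filler.
#' @param decay_prob Per-replicator removal probability per step (`d`).
#' @param dispersal_prob Per-replicator probability per step of swapping
#'   with a random von Neumann neighbor site (`D`); small values are the
#'   limited-dispersal regime.
#' @param base_error Per-monomer copy error rate before fidelity activity
#'   (`eps0`); the effective rate is `eps0 / (1 + S_B)`.
#' @param indel_fraction Fraction of copy errors that are single-monomer
#'   insertions or deletions (equal odds) rather than substitutions.
#' @param claim_scale `K`: an empty site is filled with probability
#'   `min(1, total_claim_weight / K)`.
#' @param copy_cost_scale Length scale of the copy-speed penalty
#'   `1 / (1 + L / copy_cost_scale)` on a template's claim weight.
#' @param random_composition Use uniformly random founder compositions
#'   instead of the deterministic one.
#' @return A `replicator_world_config` list.
#' @export
replicator_world_config <- function(lattice_side = 30, initial_occupancy = 0.5,
                                    initial_length = 5, decay_prob = 0.07,
                                    dispersal_prob = 0.01, base_error = 0.05,
                                    indel_fraction = 0.2, claim_scale = 0.2,
                                    copy_cost_scale = 25,
                                    random_composition = FALSE) {
  stopifnot(lattice_side >= 3, initial_length >= 1,
            initial_occupancy >= 0, initial_occupancy <= 1,
            dispersal_prob >= 0, dispersal_prob <= 1,
            decay_prob >= 0, decay_prob <= 1, claim_scale > 0,
            copy_cost_scale > 0)
  structure(list(lattice_side = as.integer(lattice_side),
                 initial_occupancy = initial_occupancy,
                 initial_length = as.integer(initial_length),
                 decay_prob = decay_prob, dispersal_prob = dispersal_prob,
                 base_error = base_error, indel_fraction = indel_fraction,
                 claim_scale = claim_scale,
                 copy_cost_scale = copy_cost_scale,
                 random_composition = isTRUE(random_composition)),
            class = "replicator_world_config")
}

#' Initialize a replicator lattice (consumes random numbers for occupancy)
#'
#' @param config A [replicator_world_config()].
#' @return A `replicator_world` handle.
#' @export
replicator_world <- function(config = replicator_world_config()) {
  stopifnot(inherits(config, "replicator_world_config"))
  ptr <- .rep_world_create(config$lattice_side, config$initial_occupancy,
                           config$initial_length, config$decay_prob,
                           config$dispersal_prob, config$base_error,
                           config$indel_fraction, config$claim_scale,
                           config$copy_cost_scale, config$random_composition)
  structure(list(ptr = ptr, config = config), class = "replicator_world")
}

#' Activity of one class of a replicator
#'
#' `beta * l / (l + gamma) * exp(-alpha * L)`; zero when no monomer is
#' devoted to the class.
#'
#' @param l Monomers devoted to the class.
#' @param L Total replicator length.
#' @param alpha,beta,gamma Curve parameters (`alpha = 0` for class C).
#' @return Activity value.
#' @export
replicator_activity <- function(l, L, alpha, beta, gamma) {
  stopifnot(all(beta > 0), all(gamma > 0), all(alpha >= 0))
  ifelse(l <= 0, 0, beta * (l / (l + gamma)) * exp(-alpha * L))
}

#' Advance a replicator lattice
#'
#' Each step fires, in order: replication (a lottery at every empty site
#' among its Moore-neighbor replicators, claims weighted by trans-acting
#' activities and a copy-speed penalty on length, copying with
#' fidelity-modulated per-monomer errors), decay, and dispersal.
#'
#' @param world A `replicator_world`.
#' @param params Named parameter vector (see [replicator_params()]).
#' @param n Number of whole-lattice sweeps.
#' @return The world, invisibly.
#' @export
replicator_step <- function(world, params, n = 1L) {
  stopifnot(inherits(world, "replicator_world"))
  .rep_world_step(world$ptr, params, as.integer(n))
  invisible(world)
}

#' Current summary of a replicator lattice
#'
#' @param world A `replicator_world`.
#' @param params Parameter vector (activities are parameter-dependent).
#' @param fallback Mean length reported when the population is extinct.
#' @return List with `step`, `population`, `mean_length`, `mean_aA`,
#'   `mean_aB`, `mean_aC`.
#' @export
replicator_counts <- function(world, params, fallback = 5) {
  stopifnot(inherits(world, "replicator_world"))
  .rep_world_counts(world$ptr, params, fallback)
}

#' Run a replicator lattice and record a time series
#'
#' @inheritParams replicator_step
#' @param n_steps Sweeps to run (>= 1).
#' @param record_every Recording stride; the final step is always recorded.
#' @param fallback Mean length recorded when the population is extinct.
#' @return Data frame: `step`, `population`, `mean_length`, `mean_aA`,
#'   `mean_aB`, `mean_aC`.
#' @export
replicator_run <- function(world, params, n_steps, record_every = n_steps,
                           fallback = 5) {
  stopifnot(inherits(world, "replicator_world"))
  .rep_world_run(world$ptr, params, as.integer(n_steps),
                 as.integer(record_every), fallback)
}

#' Snapshot of a replicator lattice
#'
#' @param world A `replicator_world`.
#' @return Data frame with one row per occupied site: `site`, `l_A`,
#'   `l_B`, `l_C`, `l_N`.
#' @export
replicator_snapshot <- function(world) {
  stopifnot(inherits(world, "replicator_world"))
  .rep_world_snapshot(world$ptr)
}

#' @export
print.replicator_world <- function(x, ...) {
  sn <- replicator_snapshot(x)
  cat("<replicator_world> ", x$config$lattice_side, "x",
      x$config$lattice_side, " lattice, ", nrow(sn), " replicators\n",
      sep = "")
  if (nrow(sn))
    cat("  mean length ",
        round(mean(sn$l_A + sn$l_B + sn$l_C + sn$l_N), 2), "\n", sep = "")
  invisible(x)
}

#' Build a replicator lattice from an explicit site table
#'
#' Places the listed replicators on an otherwise empty lattice — the
#' restore side of [replicator_snapshot()], also convenient for
#' constructing exact fixtures.
#'
#' @param snapshot Data frame with columns `site`, `l_A`, `l_B`, `l_C`,
#'   `l_N` (0-based site indices).
#' @param config A [replicator_world_config()].
#' @param step Step counter to resume from.
#' @return A `replicator_world`.
#' @export
replicator_world_from_snapshot <- function(snapshot,
                                           config = replicator_world_config(),
                                           step = 0) {
  stopifnot(inherits(config, "replicator_world_config"))
  ptr <- .rep_world_restore(config$lattice_side, config$initial_occupancy,
                            config$initial_length, config$decay_prob,
                            config$dispersal_prob, config$base_error,
                            config$indel_fraction, config$claim_scale,
                            config$copy_cost_scale,
                            as.integer(snapshot$site),
                            as.integer(snapshot$l_A),
                            as.integer(snapshot$l_B),
                            as.integer(snapshot$l_C),
                            as.integer(snapshot$l_N), step)
  structure(list(ptr = ptr, config = config), class = "replicator_world")
}
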