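#' Named experiment presets
#'
#' Ready-made bindings of a testbed, an inoculation schedule, a reference
#' step and parameter definitions, at two scales: `*-full` presets use the
#' full-scale schedules of the reference experiments (large grids, 1e5-1e6
#' step simulations — hours of computing per learning run), while `*-test`
#' presets are scaled-down twins (small grids, short schedules) that show
#' the same qualitative behavior at desk scale and drive the test suite.
#'
#' Available presets:
#' \describe{
#'   \item{`nsr-count-full` / `nsr-count-test`}{NSR count at the reference
#'     step after a 100-molecule inoculum, from the unfavorable start.}
#'   \item{`nsr-diff-full` / `nsr-diff-test`}{NSR minus control count after
#'     co-inoculating 100 of each; the over-fitting control is obtained by
#'     setting `knockout = TRUE` in the world config.}
#'   \item{`replicator-late-full` / `replicator-late-test`}{Mean replicator
#'     length at a late reference step, from the unfavorable start.}
#'   \item{`replicator-early-full` / `replicator-early-test`}{The same
#'     readout at an early reference step (cheaper, but optimizes for the
#'     wrong regime).}
#'   \item{`progressive-full` / `progressive-test`}{Four warm-started
#'     stages whose objectives read the mean length at successively later
#'     steps, 15 rounds each.}
#' }
#'
#' @param name Preset name (see above).
#' @param seed Master seed stored in the returned learning config.
#' @return List with `defs` (parameter definitions), `objective` (or
#'   `schedule` for progressive presets) and `config` (a
#'   [learning_config()]).
#' @export
exploration_preset <- function(name, seed = 1L) {
  ino_nsr <- function(step) data.frame(species = "nsr", copies = 100L,
                                       step = as.integer(step))
  ino_both <- function(step) data.frame(species = c("nsr", "ctrl"),
                                        copies = c(100L, 100L),
                                        step = as.integer(c(step, step)))
  nsr_full <- nsr_world_config(grid_side = 30, total_material = 40000)
  nsr_test <- nsr_world_config(grid_side = 10, total_material = 3000)
  rep_full <- replicator_world_config(lattice_side = 100)
  rep_test <- replicator_world_config(lattice_side = 30)

  p <- switch(
    name,
    "nsr-count-full" = list(
      defs = nsr_parameter_defs(),
      objective = nsr_objective("nsr_count", nsr_full,
                                reference_step = 150000,
                                inoculations = ino_nsr(10000)),
      config = learning_config(learning_rate = 0.5, rounds = 200, seed = seed)),
    "nsr-count-test" = list(
      defs = nsr_parameter_defs(),
      objective = nsr_objective("nsr_count", nsr_test,
                                reference_step = 5000,
                                inoculations = ino_nsr(300)),
      config = learning_config(learning_rate = 0.5, rounds = 30, seed = seed)),
    "nsr-diff-full" = list(
      defs = nsr_parameter_defs(),
      objective = nsr_objective("nsr_minus_ctrl", nsr_full,
                                reference_step = 150000,
                                inoculations = ino_both(10000)),
      config = learning_config(learning_rate = 0.5, rounds = 50, seed = seed)),
    "nsr-diff-test" = list(
      defs = nsr_parameter_defs(),
      objective = nsr_objective("nsr_minus_ctrl", nsr_test,
                                reference_step = 5000,
                                inoculations = ino_both(300)),
      config = learning_config(learning_rate = 0.5, rounds = 30, seed = seed)),
    "replicator-late-full" = list(
      defs = replicator_parameter_defs(),
      objective = replicator_objective(rep_full, reference_step = 1000000),
      config = learning_config(learning_rate = 0.2, rounds = 60, seed = seed)),
    "replicator-late-test" = list(
      defs = replicator_parameter_defs(),
      objective = replicator_objective(rep_test, reference_step = 30000),
      config = learning_config(learning_rate = 0.2, rounds = 30, seed = seed)),
    "replicator-early-full" = list(
      defs = replicator_parameter_defs(),
      objective = replicator_objective(rep_full, reference_step = 200000),
      config = learning_config(learning_rate = 0.2, rounds = 80, seed = seed)),
    "replicator-early-test" = list(
      defs = replicator_parameter_defs(),
      objective = replicator_objective(rep_test, reference_step = 6000),
      config = learning_config(learning_rate = 0.2, rounds = 30, seed = seed)),
    "progressive-full" = list(
      defs = replicator_parameter_defs(),
      schedule = lapply(c(100000, 200000, 400000, 1000000), function(s)
        list(objective = replicator_objective(rep_full, reference_step = s),
             rounds = 15L)),
      config = learning_config(learning_rate = 0.2, rounds = 60, seed = seed)),
    "progressive-test" = list(
      defs = replicator_parameter_defs(),
      schedule = lapply(c(3000, 6000, 12000, 30000), function(s)
        list(objective = replicator_objective(rep_test, reference_step = s),
             rounds = 15L)),
      config = learning_config(learning_rate = 0.2, rounds = 60, seed = seed)),
    stop("unknown preset '", name, "'")
  )
  p$name <- name
  p
}
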