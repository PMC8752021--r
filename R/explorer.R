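#' Configure a learning run
#'
#' The single rate `learning_rate` plays two roles: it is the fractional
#' perturbation used to probe each parameter (the testing rate) and the
#' scale of the full update step. The two rates are kept equal and
#' represented by one field: probing much finer than one is willing to step
#' wastes simulations, and stepping much further than one has probed is
#' unjustified for a noisy objective.
#'
#' @param learning_rate `e`, in (0, 1).
#' @param rounds Number of learning rounds (>= 1).
#' @param strategy `"gradient"` (simultaneous normalized update of all
#'   parameters) or `"coordinate"` (greedy per-parameter search over seven
#'   geometric candidates).
#' @param zero_change_direction Probe direction assumed for a parameter whose
#'   previous perturbation left the objective unchanged: `"up"` (default) or
#'   `"down"`.
#' @param step_form Downward step form: `"additive"` uses `p*(1-e)`,
#'   `"multiplicative"` uses `p/(1+e)` (the exact inverse of the upward
#'   factor). Upward steps are always `p*(1+e)`.
#' @param replicates_per_evaluation Independent simulation runs averaged per
#'   objective evaluation (default 1; raise for variance reduction).
#' @param seed Master seed; every simulation receives a child seed derived
#'   from it (see [derive_seed()]).
#' @param direction `"ascent"` maximizes the objective, `"descent"` minimizes
#'   it (implemented by negating the objective before all comparisons; the
#'   trace then records the negated values).
#' @return A `learning_config` object.
#' @export
learning_config <- function(learning_rate = 0.2, rounds = 50,
                            strategy = c("gradient", "coordinate"),
                            zero_change_direction = c("up", "down"),
                            step_form = c("additive", "multiplicative"),
                            replicates_per_evaluation = 1L,
                            seed = 1L,
                            direction = c("ascent", "descent")) {
  strategy <- match.arg(strategy)
  zero_change_direction <- match.arg(zero_change_direction)
  step_form <- match.arg(step_form)
  direction <- match.arg(direction)
  if (!is.numeric(learning_rate) || learning_rate <= 0 || learning_rate >= 1)
    stop("learning_rate must lie strictly between 0 and 1")
  rounds <- as.integer(rounds)
  if (is.na(rounds) || rounds < 1L) stop("rounds must be >= 1")
  replicates_per_evaluation <- as.integer(replicates_per_evaluation)
  if (is.na(replicates_per_evaluation) || replicates_per_evaluation < 1L)
    stop("replicates_per_evaluation must be >= 1")
  structure(
    list(learning_rate = learning_rate, rounds = rounds, strategy = strategy,
         zero_change_direction = zero_change_direction, step_form = step_form,
         replicates_per_evaluation = replicates_per_evaluation,
         seed = as.integer(seed), direction = direction),
    class = "learning_config"
  )
}

# one (possibly replicate-averaged) objective evaluation; `path` is the
# counter path identifying the evaluation slot
eval_objective <- function(objective, values, seed, path, replicates = 1L,
                           negate = FALSE) {
  slot_seed <- do.call(derive_seed, c(list(seed), as.list(path)))
  v <- mean(vapply(seq_len(replicates), function(r) {
    objective$fn(values, derive_seed(slot_seed, r))
  }, numeric(1)))
  if (!is.finite(v))
    stop("objective '", objective$id, "' returned a non-finite value at ",
         paste(names(values), signif(values, 6), sep = "=", collapse = ", "))
  if (negate) -v else v
}

# perturb parameter value in direction s (+1/-1) by rate e under step_form
perturb_value <- function(p, e, s, step_form) {
  if (s > 0) p * (1 + e)
  else if (step_form == "additive") p * (1 - e)
  else p / (1 + e)
}

#' Probe the local objective landscape
#'
#' Evaluates the objective at the current parameter set and at `n`
#' one-parameter perturbations (parameter `i` moved in its remembered
#' direction `s_i` by the testing rate `e`), yielding the per-parameter
#' objective changes `dO_i` and their maximum magnitude. All `n + 1`
#' evaluations receive independent child seeds derived from
#' `(seed, round, slot)` with slot 0 the base evaluation and slot `i` the
#' perturbation of parameter `i`.
#'
#' @param objective An objective object (see [synthetic_objective()],
#'   [nsr_objective()], [replicator_objective()]).
#' @param values Named numeric vector of current parameter values.
#' @param defs `parameter_defs` governing the values.
#' @param e Testing rate in (0, 1).
#' @param directions Named or plain vector of +1/-1 probe directions.
#' @param round Round index (seeds the child streams).
#' @param seed Master seed.
#' @param step_form,replicates,negate See [learning_config()].
#' @return A `delta_vector`: list with `base` (objective at `values`),
#'   `deltas`, `directions`, `max_abs` and `evaluations`.
#' @export
probe <- function(objective, values, defs, e, directions, round, seed,
                  step_form = "additive", replicates = 1L, negate = FALSE) {
  n <- length(values)
  stopifnot(length(directions) == n)
  base <- eval_objective(objective, values, seed, c(round, 0L), replicates, negate)
  deltas <- numeric(n)
  for (i in seq_len(n)) {
    cand <- values
    cand[[i]] <- clamp(perturb_value(values[[i]], e, directions[[i]], step_form),
                       defs[[i]], warn = FALSE)
    oi <- eval_objective(objective, cand, seed, c(round, i), replicates, negate)
    deltas[i] <- oi - base
  }
  names(deltas) <- names(values)
  structure(
    list(base = base, deltas = deltas,
         directions = stats::setNames(as.numeric(directions), names(values)),
         max_abs = max(abs(deltas)), evaluations = n + 1L),
    class = "delta_vector"
  )
}

#' Apply one normalized gradient update
#'
#' The signed slope of parameter `i` is `g_i = s_i * dO_i`: positive when
#' increasing the parameter would raise the objective. Each parameter moves
#' by a factor proportional to its normalized slope,
#' `p_i <- p_i * (1 + e * g_i / max_abs)` for `g_i >= 0` and the chosen
#' downward form scaled by `|g_i| / max_abs` otherwise, so the parameter
#' attaining the maximal `|dO|` takes the full step while the rest move in
#' proportion to their potential. A zero `max_abs` (the objective did not
#' respond to any probe) skips the update entirely.
#'
#' @param values Named numeric vector of current values.
#' @param defs Governing `parameter_defs` (results are clamped).
#' @param delta A `delta_vector` from [probe()].
#' @param e Learning rate.
#' @param step_form `"additive"` or `"multiplicative"`.
#' @param warn Warn when a parameter is clamped.
#' @return Updated named value vector (attribute `"clamped"` lists clamped
#'   parameter names).
#' @export
gradient_update <- function(values, defs, delta, e, step_form = "additive",
                            warn = TRUE) {
  if (!is.finite(delta$max_abs)) stop("gradient_update: non-finite max_abs")
  if (delta$max_abs == 0) {
    attr(values, "clamped") <- character(0)
    return(values)
  }
  g <- delta$directions * delta$deltas
  f <- g / delta$max_abs
  out <- values
  for (i in seq_along(values)) {
    out[[i]] <- if (f[[i]] >= 0) {
      values[[i]] * (1 + e * f[[i]])
    } else if (step_form == "additive") {
      values[[i]] * (1 - e * abs(f[[i]]))
    } else {
      values[[i]] / (1 + e * abs(f[[i]]))
    }
  }
  clamp_values(out, defs, warn = warn)
}

#' Next probe directions from a completed round
#'
#' A parameter is next probed in the direction it actually moved: the sign
#' of its signed slope `s_i * dO_i`. When the probe left the objective
#' unchanged the configured `zero_change_direction` is assumed.
#'
#' @param delta A `delta_vector` from the completed round.
#' @param zero_change_direction `"up"` or `"down"`.
#' @return Named vector of +1/-1.
#' @export
next_directions <- function(delta, zero_change_direction = "up") {
  g <- delta$directions * delta$deltas
  zero <- if (zero_change_direction == "up") 1 else -1
  stats::setNames(ifelse(g > 0, 1, ifelse(g < 0, -1, zero)), names(g))
}

new_trace <- function(config, objective_id, n_params, param_names) {
  structure(
    list(config = config, objective_id = objective_id,
         rounds = data.frame(), deltas = NULL, directions = NULL,
         evaluations = integer(0), stage_boundaries = integer(0),
         param_names = param_names),
    class = "learning_trace"
  )
}

#' Run the gradient-ascent explorer
#'
#' Iterates probe -> normalized update -> direction update for
#' `config$rounds` rounds, starting from the definitions' initial values
#' (or `start`) with all probe directions upward. Each round costs `n + 1`
#' objective evaluations (times `replicates_per_evaluation` simulations).
#'
#' @param objective Objective object.
#' @param defs `parameter_defs`.
#' @param config A `learning_config` with `strategy = "gradient"`.
#' @param start Optional named start values (defaults to initial values).
#' @param start_directions Optional +1/-1 vector of initial probe directions
#'   (defaults to all upward); used by progressive schedules to carry
#'   direction memory across stages.
#' @param round_offset Added to the round index when deriving child seeds
#'   (progressive schedules use it so that no two stages share evaluation
#'   streams); leave at 0 for ordinary runs.
#' @return A `learning_trace`.
#' @export
run_gradient_ascent <- function(objective, defs, config, start = NULL,
                                start_directions = NULL, round_offset = 0L) {
  stopifnot(inherits(config, "learning_config"))
  if (config$strategy != "gradient")
    stop("run_gradient_ascent requires strategy = 'gradient'")
  values <- if (is.null(start)) initial_values(defs) else start
  check_values(values, defs)
  n <- length(values)
  dirs <- if (is.null(start_directions)) rep(1, n) else as.numeric(start_directions)
  negate <- config$direction == "descent"
  e <- config$learning_rate

  trace <- new_trace(config, objective$id, n, names(values))
  rounds <- vector("list", config$rounds)
  deltas <- matrix(NA_real_, config$rounds, n, dimnames = list(NULL, names(values)))
  dirmat <- matrix(NA_real_, config$rounds, n, dimnames = list(NULL, names(values)))
  evals <- integer(config$rounds)

  for (r in seq_len(config$rounds)) {
    d <- tryCatch(
      probe(objective, values, defs, e, dirs, r + round_offset, config$seed,
            config$step_form, config$replicates_per_evaluation, negate),
      error = function(err)
        stop("round ", r, ": ", conditionMessage(err), call. = FALSE)
    )
    values <- gradient_update(values, defs, d, e, config$step_form, warn = FALSE)
    dirmat[r, ] <- dirs
    dirs <- next_directions(d, config$zero_change_direction)
    deltas[r, ] <- d$deltas
    evals[r] <- d$evaluations
    rounds[[r]] <- c(list(round = r, objective = d$base), as.list(values))
  }
  trace$rounds <- do.call(rbind, lapply(rounds, as.data.frame))
  trace$deltas <- deltas
  trace$directions <- dirmat
  trace$evaluations <- evals
  trace
}

#' Candidate values for one coordinate-ascent visit
#'
#' The seven-point geometric grid around the current value: the value
#' itself, three upward adjustments `p*(1+e)^k` and three downward
#' adjustments (`p*(1-e)^k`, or `p/(1+e)^k` under the multiplicative form),
#' `k = 1..3`, in that fixed order. Candidates falling outside the
#' parameter's bounds are dropped (the current value always survives).
#'
#' @param p Current value.
#' @param e Rate in (0, 1).
#' @param def Governing `parameter_def`.
#' @param step_form `"additive"` or `"multiplicative"`.
#' @return Numeric vector of at most 7 candidates, current value first.
#' @export
coordinate_candidates <- function(p, e, def, step_form = "additive") {
  stopifnot(e > 0, e < 1)
  up <- p * (1 + e)^(1:3)
  down <- if (step_form == "additive") p * (1 - e)^(1:3) else p / (1 + e)^(1:3)
  cand <- c(p, up, down)
  cand[cand >= def$lower & cand <= def$upper]
}

#' Run the coordinate-ascent explorer
#'
#' Per round, parameters are visited in canonical order; at each visit all
#' surviving candidates of [coordinate_candidates()] — including the
#' incumbent, which is re-evaluated with a fresh stream because the
#' objective is stochastic — are evaluated and the argmax is installed
#' before the next parameter is visited. Ties break in favor of the
#' incumbent, then the earlier candidate.
#'
#' @inheritParams run_gradient_ascent
#' @param config A `learning_config` with `strategy = "coordinate"`.
#' @return A `learning_trace`; the per-round objective is the best value
#'   observed at the round's final parameter visit.
#' @export
run_coordinate_ascent <- function(objective, defs, config, start = NULL) {
  stopifnot(inherits(config, "learning_config"))
  if (config$strategy != "coordinate")
    stop("run_coordinate_ascent requires strategy = 'coordinate'")
  values <- if (is.null(start)) initial_values(defs) else start
  check_values(values, defs)
  n <- length(values)
  negate <- config$direction == "descent"
  e <- config$learning_rate

  trace <- new_trace(config, objective$id, n, names(values))
  rounds <- vector("list", config$rounds)
  evals <- integer(config$rounds)

  for (r in seq_len(config$rounds)) {
    used <- 0L
    best_last <- NA_real_
    for (i in seq_len(n)) {
      cand <- coordinate_candidates(values[[i]], e, defs[[i]], config$step_form)
      obj <- vapply(seq_along(cand), function(k) {
        v <- values
        v[[i]] <- cand[k]
        eval_objective(objective, v, config$seed, c(r, i, k),
                       config$replicates_per_evaluation, negate)
      }, numeric(1))
      used <- used + length(cand)
      # argmax with ties to the incumbent (index 1), then earlier candidate
      best <- which(obj == max(obj))[1L]
      if (obj[1L] == obj[best]) best <- 1L
      values[[i]] <- cand[best]
      best_last <- obj[best]
    }
    evals[r] <- used
    rounds[[r]] <- c(list(round = r, objective = best_last), as.list(values))
  }
  trace$rounds <- do.call(rbind, lapply(rounds, as.data.frame))
  trace$evaluations <- evals
  trace
}

#' Run a progressive (staged, warm-started) learning schedule
#'
#' Each stage runs the gradient-ascent explorer against its own objective —
#' typically the same readout at successively later simulation steps — for
#' its own number of rounds, starting from the previous stage's final
#' parameter values and direction memory. Early stages are cheap (short
#' simulations) and put the parameters in the right region; only the final
#' stage pays for the full-length objective.
#'
#' @param schedule List of stages, each a list with elements `objective` and
#'   `rounds`.
#' @param defs `parameter_defs`.
#' @param config A `learning_config` (`rounds` is taken from the schedule).
#' @param start Optional named start values.
#' @return A `learning_trace` whose rounds concatenate the stages, with
#'   `stage_boundaries` marking the last round of each stage but the final.
#' @export
run_progressive <- function(schedule, defs, config, start = NULL) {
  stopifnot(length(schedule) >= 1L)
  values <- if (is.null(start)) initial_values(defs) else start
  dirs <- NULL
  pieces <- vector("list", length(schedule))
  offset <- 0L
  for (s in seq_along(schedule)) {
    st <- schedule[[s]]
    cfg <- config
    cfg$rounds <- as.integer(st$rounds)
    tr <- run_gradient_ascent(st$objective, defs, cfg, start = values,
                              start_directions = dirs, round_offset = offset)
    nlast <- nrow(tr$rounds)
    values <- stats::setNames(as.numeric(tr$rounds[nlast, tr$param_names]),
                              tr$param_names)
    dirs <- next_directions(
      structure(list(directions = stats::setNames(tr$directions[nlast, ],
                                                  tr$param_names),
                     deltas = stats::setNames(tr$deltas[nlast, ],
                                              tr$param_names)),
                class = "delta_vector"),
      config$zero_change_direction
    )
    tr$rounds$round <- tr$rounds$round + offset
    tr$rounds$stage <- s
    offset <- offset + nlast
    pieces[[s]] <- tr
  }
  out <- pieces[[1L]]
  out$config <- config
  out$objective_id <- paste(vapply(schedule, function(st) st$objective$id,
                                   character(1)), collapse = " -> ")
  out$rounds <- do.call(rbind, lapply(pieces, `[[`, "rounds"))
  out$deltas <- do.call(rbind, lapply(pieces, `[[`, "deltas"))
  out$directions <- do.call(rbind, lapply(pieces, `[[`, "directions"))
  out$evaluations <- do.call(c, lapply(pieces, `[[`, "evaluations"))
  out$stage_boundaries <- utils::head(cumsum(vapply(schedule, function(st)
    as.integer(st$rounds), integer(1))), -1L)
  out
}
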