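#' @export
print.learning_trace <- function(x, ...) {
  nr <- nrow(x$rounds)
  cat("<learning_trace> objective: ", x$objective_id, "\n", sep = "")
  cat("  strategy: ", x$config$strategy,
      ", e = ", x$config$learning_rate,
      ", rounds = ", nr,
      ", seed = ", x$config$seed, "\n", sep = "")
  if (length(x$stage_boundaries))
    cat("  stage boundaries: ", paste(x$stage_boundaries, collapse = ", "), "\n",
        sep = "")
  if (nr > 0) {
    cat("  objective: ", signif(x$rounds$objective[1], 6), " (round 1) -> ",
        signif(x$rounds$objective[nr], 6), " (round ", nr, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.learning_trace <- function(x, ...) x$rounds

#' Final parameter values of a learning trace
#'
#' @param trace A `learning_trace`.
#' @return Named numeric vector (canonical parameter order).
#' @export
final_values <- function(trace) {
  stopifnot(inherits(trace, "learning_trace"))
  n <- nrow(trace$rounds)
  stats::setNames(as.numeric(trace$rounds[n, trace$param_names]),
                  trace$param_names)
}

#' Write a learning trace as TSV
#'
#' One row per round with columns `round`, `objective`, then one column per
#' parameter in canonical order. For progressive runs a sidecar
#' `<path>.stages.tsv` records the stage boundaries.
#'
#' @param trace A `learning_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "learning_trace"))
  df <- trace$rounds[, c("round", "objective", trace$param_names)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(trace$stage_boundaries)) {
    utils::write.table(
      data.frame(stage = seq_along(trace$stage_boundaries),
                 last_round = trace$stage_boundaries),
      paste0(path, ".stages.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Summarize a learning trace
#'
#' Start/final objective value, the improvement factor, and each
#' parameter's start and final value — the numbers one would read off a
#' learning-curve figure.
#'
#' @param object A `learning_trace`.
#' @param ... Unused.
#' @return A list with `objective_start`, `objective_final`,
#'   `improvement_factor` and a `parameters` data frame.
#' @export
summary.learning_trace <- function(object, ...) {
  df <- object$rounds
  n <- nrow(df)
  o0 <- df$objective[1]
  o1 <- df$objective[n]
  pars <- data.frame(
    parameter = object$param_names,
    start = as.numeric(df[1, object$param_names]),
    final = as.numeric(df[n, object$param_names])
  )
  out <- list(objective_id = object$objective_id,
              rounds = n,
              objective_start = o0, objective_final = o1,
              improvement_factor = if (o0 != 0) o1 / o0 else NA_real_,
              parameters = pars)
  class(out) <- "summary.learning_trace"
  out
}

#' @export
print.summary.learning_trace <- function(x, ...) {
  cat("Learning summary — objective: ", x$objective_id, "\n", sep = "")
  cat("  rounds:            ", x$rounds, "\n", sep = "")
  cat("  objective start:   ", signif(x$objective_start, 6), "\n", sep = "")
  cat("  objective final:   ", signif(x$objective_final, 6), "\n", sep = "")
  if (is.finite(x$improvement_factor))
    cat("  improvement factor:", signif(x$improvement_factor, 4), "\n")
  cat("  parameters (start -> final):\n")
  for (i in seq_len(nrow(x$parameters)))
    cat(sprintf("    %-8s %-12g -> %-12g\n", x$parameters$parameter[i],
                x$parameters$start[i], x$parameters$final[i]))
  invisible(x)
}
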