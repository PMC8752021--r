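#' Define an explorable parameter
#'
#' A parameter definition names one tunable quantity of a simulator, its
#' value domain and the bounds that multiplicative updates are clamped to.
#' Probability-kind parameters are bounded inside (0, 1]: since every update
#' of the explorer is multiplicative (a factor of the form `1 + e*x`), an
#' exact zero would be absorbing, so the default lower bound is a tiny
#' strictly positive value rather than 0.
#'
#' @param name Identifier (unique within a definition set).
#' @param initial Starting value, inside `[lower, upper]`.
#' @param kind `"probability"` (upper bound at most 1) or `"positive-real"`.
#' @param lower,upper Bounds; defaults depend on `kind`:
#'   `[1e-12, 1]` for probabilities, `[1e-12, 1e6]` for positive reals.
#' @param description Free-text note on what the parameter controls.
#' @return An object of class `parameter_def`.
#' @examples
#' parameter_def("PAT", 0.5, description = "nucleotide attachment probability")
#' @export
parameter_def <- function(name, initial,
                          kind = c("probability", "positive-real"),
                          lower = NULL, upper = NULL, description = "") {
  kind <- match.arg(kind)
  if (is.null(lower)) lower <- 1e-12
  if (is.null(upper)) upper <- if (kind == "probability") 1 else 1e6
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(initial) || !is.finite(lower) || !is.finite(upper))
    stop("parameter_def: non-finite value in definition of '", name, "'")
  if (lower < 0 || lower >= upper)
    stop("parameter_def('", name, "'): need 0 <= lower < upper")
  if (kind == "probability" && upper > 1)
    stop("parameter_def('", name, "'): probability upper bound must be <= 1")
  if (initial < lower || initial > upper)
    stop("parameter_def('", name, "'): initial value ", initial,
         " outside [", lower, ", ", upper, "]")
  structure(
    list(name = name, kind = kind, initial = initial,
         lower = lower, upper = upper, description = description),
    class = "parameter_def"
  )
}

#' Collect parameter definitions into an ordered set
#'
#' The order of definitions is the canonical parameter order used by every
#' exploration strategy: index `i` in the finite-difference formulas always
#' refers to this order, and learning-trace columns follow it.
#'
#' @param ... `parameter_def` objects (or a single list of them).
#' @return An object of class `parameter_defs` (a named, ordered list).
#' @export
parameter_defs <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && !inherits(defs[[1L]], "parameter_def"))
    defs <- defs[[1L]]
  if (length(defs) == 0L) stop("parameter_defs: need at least one definition")
  ok <- vapply(defs, inherits, logical(1), "parameter_def")
  if (!all(ok)) stop("parameter_defs: all arguments must be parameter_def objects")
  nms <- vapply(defs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("parameter_defs: duplicate parameter name(s): ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(defs) <- nms
  structure(defs, class = "parameter_defs")
}

#' @export
print.parameter_defs <- function(x, ...) {
  cat("<parameter_defs> ", length(x), " parameters\n", sep = "")
  for (d in x)
    cat(sprintf("  %-8s %-13s initial=%-10g bounds=[%g, %g]\n",
                d$name, d$kind, d$initial, d$lower, d$upper))
  invisible(x)
}

#' Initial parameter values of a definition set
#'
#' @param defs A `parameter_defs` object.
#' @return Named numeric vector in canonical order.
#' @export
initial_values <- function(defs) {
  stopifnot(inherits(defs, "parameter_defs"))
  vapply(defs, `[[`, numeric(1), "initial")
}

#' Clamp a value to a parameter's bounds
#'
#' Out-of-bounds values are moved to the nearest bound (clamping, not
#' rejection), preserving the simultaneous-update semantics of a learning
#' round; a warning is emitted so that clamped rounds are visible in logs.
#' Clamping is idempotent.
#'
#' @param value Finite numeric scalar.
#' @param def A `parameter_def`.
#' @param warn Emit a warning when clamping occurs (default `TRUE`).
#' @return The clamped value.
#' @export
clamp <- function(value, def, warn = TRUE) {
  stopifnot(inherits(def, "parameter_def"))
  if (!is.finite(value))
    stop("clamp: non-finite value for parameter '", def$name,
         "' signals a corrupted update")
  if (value < def$lower) {
    if (warn) warning("parameter '", def$name, "' clamped to lower bound ",
                      def$lower, call. = FALSE)
    return(def$lower)
  }
  if (value > def$upper) {
    if (warn) warning("parameter '", def$name, "' clamped to upper bound ",
                      def$upper, call. = FALSE)
    return(def$upper)
  }
  value
}

# Clamp a whole named vector against its defs, without per-call warnings;
# returns the vector plus an attribute naming clamped parameters.
clamp_values <- function(values, defs, warn = TRUE) {
  out <- values
  hit <- character(0)
  for (nm in names(defs)) {
    d <- defs[[nm]]
    v <- out[[nm]]
    if (!is.finite(v))
      stop("clamp: non-finite value for parameter '", nm, "'")
    if (v < d$lower) { out[[nm]] <- d$lower; hit <- c(hit, nm) }
    else if (v > d$upper) { out[[nm]] <- d$upper; hit <- c(hit, nm) }
  }
  if (length(hit) && warn)
    warning("clamped parameter(s): ", paste(hit, collapse = ", "), call. = FALSE)
  attr(out, "clamped") <- hit
  out
}

# validate a named value vector against defs (order + bounds)
check_values <- function(values, defs) {
  if (is.null(names(values)) || !identical(names(values), names(defs)))
    stop("parameter values must be named and in definition order: ",
         paste(names(defs), collapse = ", "))
  for (nm in names(defs)) {
    d <- defs[[nm]]
    v <- values[[nm]]
    if (!is.finite(v) || v < d$lower || v > d$upper)
      stop("parameter '", nm, "' = ", v, " outside [", d$lower, ", ", d$upper, "]")
  }
  invisible(values)
}
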