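# Shared helpers: independent oracle for the update rule, tiny objective
# builders, and random-instance generators used by the property tests.

# Literal, independent transcription of the normalized update formula with
# the signed-slope extension: g_i = s_i * dO_i, every parameter moves by
# the factor (1 + e * g_i / max|dO|) (additive downward form) or divides
# by (1 + e * |g_i| / max|dO|) when g_i < 0 (multiplicative form).
# Deliberately written as plain arithmetic, no shared code with the
# implementation.
oracle_update <- function(p, dO, s, e, form = "additive") {
  M <- max(abs(dO))
  if (M == 0) return(p)
  g <- s * dO
  out <- numeric(length(p))
  for (i in seq_along(p)) {
    if (form == "additive") {
      out[i] <- p[i] * (1 + e * g[i] / M)
    } else {
      out[i] <- if (g[i] >= 0) p[i] * (1 + e * g[i] / M)
                else p[i] / (1 + e * abs(g[i]) / M)
    }
  }
  out
}

# random update-rule instances: params in (0,1), dO on a wide signed scale,
# s in {-1,+1}, e in (0,1)
random_update_instance <- function(n = 8) {
  list(p = runif(n, 1e-6, 1),
       dO = rnorm(n) * 10^runif(n, -3, 3),
       s = sample(c(-1, 1), n, replace = TRUE),
       e = runif(1, 0.05, 0.95))
}

# deterministic objective over named values from a plain function of the
# value vector
fn_objective <- function(id, f) {
  objective(id, function(values, seed) f(values))
}

# unbounded-ish defs for synthetic experiments
wide_defs <- function(values) {
  parameter_defs(lapply(names(values), function(nm)
    parameter_def(nm, values[[nm]], kind = "positive-real",
                  lower = 1e-12, upper = 1e6)))
}

# the bundled 8-dimensional concave synthetic recovery problem: optimum
# spread over two orders of magnitude, start displaced by factors up to e^1
recovery_problem <- function(noise_sd = 0) {
  optimum <- c(a = 0.5, b = 0.02, c = 3, d = 0.15, e = 40, f = 1,
               g = 0.004, h = 8)
  start <- optimum * exp(c(1, -1, 0.7, -0.6, 1, -0.9, 0.5, -1))
  defs <- wide_defs(start)
  list(defs = defs, optimum = optimum, start = start,
       objective = synthetic_objective(optimum, weights = 1,
                                       noise_sd = noise_sd))
}

tiny_nsr_config <- function(...) {
  nsr_world_config(grid_side = 10, total_material = 2000, ...)
}
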