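#' The eight explored parameters of the NSR RNA-pool model
#'
#' All are per-step event probabilities: `PNF` non-enzymatic nucleotide
#' formation from a precursor; `PNFR` the enzymatic rate used instead in
#' rooms holding a functional NSR; `PND` free-nucleotide decay back to
#' precursor; `PRL` random ligation per molecule pair; `PBB` breaking per
#' internal bond; `PAT` template-directed attachment of a free nucleotide;
#' `PFP` false pairing given an attachment; `PMV` molecule movement to an
#' adjacent room.
#'
#' @param PNF,PNFR,PND,PRL,PBB,PAT,PFP,PMV Probabilities in `[0, 1]`.
#' @return Named numeric vector in canonical order.
#' @export
nsr_params <- function(PNF, PNFR, PND, PRL, PBB, PAT, PFP, PMV) {
  v <- c(PNF = PNF, PNFR = PNFR, PND = PND, PRL = PRL,
         PBB = PBB, PAT = PAT, PFP = PFP, PMV = PMV)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("all NSR parameters must be probabilities in [0, 1]")
  v
}

#' Parameter definitions for exploring the NSR model
#'
#' The initial values default to a setting under which an inoculated NSR
#' population declines — the natural starting point for a learning run
#' whose goal is to reverse that decline.
#'
#' @param initial Named vector of starting values (defaults to the
#'   unfavorable reference setting).
#' @return A `parameter_defs` of the eight explored probabilities.
#' @export
nsr_parameter_defs <- function(initial = nsr_start_unfavorable()) {
  parameter_defs(lapply(names(initial), function(nm)
    parameter_def(nm, initial[[nm]], kind = "probability")))
}

#' Reference parameter settings for the NSR model
#'
#' `nsr_start_unfavorable()` is the setting under which a 100-molecule NSR
#' inoculum declines (the learning start); `nsr_reference_favorable()` is a
#' setting under which a single inoculated NSR molecule spreads.
#'
#' @return Named parameter vector (see [nsr_params()]).
#' @export
nsr_start_unfavorable <- function() {
  nsr_params(PNF = 4e-3, PNFR = 0.02, PND = 1e-3, PRL = 2e-5,
             PBB = 1e-5, PAT = 0.5, PFP = 0.1, PMV = 1e-3)
}

#' @rdname nsr_start_unfavorable
#' @export
nsr_reference_favorable <- function() {
  nsr_params(PNF = 2e-4, PNFR = 0.9, PND = 0.01, PRL = 2e-6,
             PBB = 1e-6, PAT = 0.1, PFP = 0.01, PMV = 0.01)
}

default_nsr_motif <- "AUCGGCUAAC"
default_ctrl_motif <- "AGCUCAGUCA"

#' Configure an NSR world
#'
#' @param grid_side Rooms per side of the toroidal grid (>= 2).
#' @param total_material Raw-material units distributed uniformly across
#'   rooms as precursors at initialization.
#' @param nsr_motif,ctrl_motif Nucleotide sequences (same length, distinct);
#'   a molecule is classified NSR/Ctrl when its sequence contains the motif
#'   as a contiguous subsequence. The complement does not count.
#' @param duplex_separation Probability per step that a completed nascent
#'   strand detaches from its template.
#' @param knockout When `TRUE`, NSR molecules keep their identity (and are
#'   counted) but lose catalytic function — the over-fitting control.
#' @return An `nsr_world_config` list.
#' @export
nsr_world_config <- function(grid_side = 10, total_material = 4000,
                             nsr_motif = default_nsr_motif,
                             ctrl_motif = default_ctrl_motif,
                             duplex_separation = 0.5, knockout = FALSE) {
  stopifnot(grid_side >= 2, total_material >= 1,
            nchar(nsr_motif) == nchar(ctrl_motif), nsr_motif != ctrl_motif,
            duplex_separation >= 0, duplex_separation <= 1)
  structure(list(grid_side = as.integer(grid_side),
                 total_material = as.integer(total_material),
                 nsr_motif = nsr_motif, ctrl_motif = ctrl_motif,
                 duplex_separation = duplex_separation,
                 knockout = isTRUE(knockout)),
            class = "nsr_world_config")
}

#' Initialize an NSR world
#'
#' All material starts as precursors split as evenly as possible across
#' rooms; there are no molecules until [nsr_inoculate()] places some.
#'
#' @param config An [nsr_world_config()].
#' @return An `nsr_world` handle.
#' @export
nsr_world <- function(config = nsr_world_config()) {
  stopifnot(inherits(config, "nsr_world_config"))
  ptr <- .nsr_world_create(config$grid_side, config$total_material,
                           config$nsr_motif, config$ctrl_motif,
                           config$duplex_separation, config$knockout)
  structure(list(ptr = ptr, config = config), class = "nsr_world")
}

#' Inoculate NSR or control molecules
#'
#' Places `copies` exact copies of the species motif in uniformly random
#' rooms. Inoculated material is exogenous: the conservation ledger grows
#' by `copies * nchar(motif)`.
#'
#' @param world An `nsr_world`.
#' @param species `"nsr"` or `"ctrl"`.
#' @param copies Number of molecules (>= 1).
#' @return The world, invisibly (state is modified in place).
#' @export
nsr_inoculate <- function(world, species = c("nsr", "ctrl"), copies = 1L) {
  stopifnot(inherits(world, "nsr_world"))
  species <- match.arg(species)
  .nsr_world_inoculate(world$ptr, species, as.integer(copies))
  invisible(world)
}

#' Advance an NSR world
#'
#' Applies `n` Monte-Carlo steps. Each step fires, in fixed order per
#' event: nucleotide formation, nucleotide decay, random ligation, bond
#' breaking, template-directed synthesis (with false pairing and duplex
#' separation), and molecule movement.
#'
#' @param world An `nsr_world`.
#' @param params Named parameter vector (see [nsr_params()]).
#' @param n Number of steps.
#' @return The world, invisibly.
#' @export
nsr_step <- function(world, params, n = 1L) {
  stopifnot(inherits(world, "nsr_world"))
  .nsr_world_step(world$ptr, params, as.integer(n))
  invisible(world)
}

#' Current counts of an NSR world
#'
#' @param world An `nsr_world`.
#' @return List with `step`, `nsr`, `ctrl`, `molecules`,
#'   `free_nucleotides`, `precursors`, `material` (audited sum) and
#'   `ledger` (expected total).
#' @export
nsr_counts <- function(world) {
  stopifnot(inherits(world, "nsr_world"))
  .nsr_world_counts(world$ptr)
}

#' Run an NSR world with an inoculation schedule
#'
#' Steps the world `n_steps` times, firing each inoculation before the
#' events of its scheduled (0-based, absolute) step, and records a time
#' series. Conservation is audited at every recorded row.
#'
#' @param world An `nsr_world`.
#' @param params Named parameter vector.
#' @param n_steps Steps to run (>= 1).
#' @param inoculations Data frame with columns `species`, `copies`, `step`
#'   (or `NULL` for none).
#' @param record_every Recording stride in steps; the final step is always
#'   recorded.
#' @return Data frame: `step`, `nsr_count`, `ctrl_count`, `molecule_count`,
#'   `free_nucleotides`, `precursors`, `material`.
#' @export
nsr_run <- function(world, params, n_steps, inoculations = NULL,
                    record_every = n_steps) {
  stopifnot(inherits(world, "nsr_world"))
  if (is.null(inoculations))
    inoculations <- data.frame(species = character(0), copies = integer(0),
                               step = integer(0))
  out <- .nsr_world_run(world$ptr, params, as.integer(n_steps),
                        as.integer(inoculations$step),
                        as.character(inoculations$species),
                        as.integer(inoculations$copies),
                        as.integer(record_every))
  # audit conservation on rows recorded after the last inoculation fired
  ledger <- nsr_counts(world)$ledger
  settled <- out$step > max(c(inoculations$step, -1))
  if (any(out$material[settled] != ledger))
    warning("material conservation violated in recorded series")
  out
}

#' Does a sequence carry the NSR (or control) motif?
#'
#' Classification is by contiguous motif containment on the template
#' strand; the complement of the motif is a different molecule and does not
#' count. Under knockout, NSR identity is retained but
#' [nsr_is_functional()] is `FALSE`.
#'
#' @param sequence Character vector of base sequences.
#' @param config An [nsr_world_config()].
#' @return Logical vector.
#' @export
nsr_is_nsr <- function(sequence, config) {
  grepl(config$nsr_motif, sequence, fixed = TRUE)
}

#' @rdname nsr_is_nsr
#' @export
nsr_is_ctrl <- function(sequence, config) {
  grepl(config$ctrl_motif, sequence, fixed = TRUE)
}

#' @rdname nsr_is_nsr
#' @export
nsr_is_functional <- function(sequence, config) {
  nsr_is_nsr(sequence, config) & !config$knockout
}

#' @export
print.nsr_world <- function(x, ...) {
  ct <- nsr_counts(x)
  cat("<nsr_world> ", x$config$grid_side, "x", x$config$grid_side,
      " rooms, step ", ct$step, "\n", sep = "")
  cat("  NSR ", ct$nsr, ", Ctrl ", ct$ctrl, ", molecules ", ct$molecules,
      ", free ", ct$free_nucleotides, ", precursors ", ct$precursors,
      "\n  material ", ct$material, " / ledger ", ct$ledger,
      if (x$config$knockout) "  [knockout]" else "", "\n", sep = "")
  invisible(x)
}

#' Serialize / restore an NSR world as plain text
#'
#' The snapshot format is a TSV with a `kind` column: `room` rows carry
#' `room, precursors, fA, fU, fC, fG`; `molecule` rows carry
#' `room, sequence, nascent`; a single `meta` row carries the step counter
#' and material ledger in `precursors`/`fA`.
#'
#' @param world An `nsr_world`.
#' @param path File path.
#' @return `path` (write) or a restored `nsr_world` (read).
#' @export
write_nsr_snapshot <- function(world, path) {
  stopifnot(inherits(world, "nsr_world"))
  sn <- .nsr_world_snapshot(world$ptr)
  rooms <- data.frame(kind = "room", sn$rooms, sequence = "", nascent = "")
  mols <- sn$molecules
  moldf <- if (nrow(mols)) {
    data.frame(kind = "molecule", room = mols$room, precursors = 0,
               fA = 0, fU = 0, fC = 0, fG = 0,
               sequence = mols$sequence, nascent = mols$nascent)
  } else NULL
  meta <- data.frame(kind = "meta", room = 0, precursors = sn$step,
                     fA = sn$ledger, fU = 0, fC = 0, fG = 0,
                     sequence = "", nascent = "")
  utils::write.table(rbind(meta, rooms, moldf), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nsr_snapshot
#' @param config The [nsr_world_config()] the snapshot was taken under
#'   (motifs and constants are not stored in the snapshot).
#' @export
read_nsr_snapshot <- function(path, config) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(kind = "character",
                                         sequence = "character",
                                         nascent = "character"),
                          na.strings = NULL)
  df$sequence[is.na(df$sequence)] <- ""
  df$nascent[is.na(df$nascent)] <- ""
  meta <- df[df$kind == "meta", ]
  rooms <- df[df$kind == "room", ]
  rooms <- rooms[order(rooms$room), ]
  mols <- df[df$kind == "molecule", ]
  ptr <- .nsr_world_restore(config$grid_side, config$nsr_motif,
                            config$ctrl_motif, config$duplex_separation,
                            config$knockout,
                            as.integer(rooms$precursors),
                            as.integer(rooms$fA), as.integer(rooms$fU),
                            as.integer(rooms$fC), as.integer(rooms$fG),
                            as.integer(mols$room), mols$sequence,
                            mols$nascent, meta$precursors[1], meta$fA[1])
  structure(list(ptr = ptr, config = config), class = "nsr_world")
}
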