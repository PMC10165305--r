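TERM_NAMES <- c("steric", "vdw_attract", "rg", "hbond", "ss_pair")

#' Score-term weight vector
#'
#' Named non-negative weights, one per energy term. At least one weight must
#' be positive. Terms: `steric` (quadratic clash penalty below 4 Angstrom
#' between atoms two or more residues apart), `vdw_attract` (-1 per
#' side-chain pseudo-atom pair within 4.5-6.5 Angstrom), `rg` (radius of
#' gyration of CA + CEN atoms, Angstrom), `hbond` (-1 per backbone O..N pair
#' at sequence separation >= 3 within 2.6-3.4 Angstrom), `ss_pair`
#' (per-residue mismatch between the Ramachandran-classified backbone state
#' and the target secondary structure).
#'
#' @param steric,vdw_attract,rg,hbond,ss_pair Non-negative weights.
#' @return Named numeric vector of class `score_weights`.
#' @export
score_weights <- function(steric = 0, vdw_attract = 0, rg = 0, hbond = 0,
                          ss_pair = 0) {
  w <- c(steric = unname(steric), vdw_attract = unname(vdw_attract),
         rg = unname(rg), hbond = unname(hbond), ss_pair = unname(ss_pair))
  if (any(w < 0)) stop("weights must be non-negative")
  if (all(w == 0)) stop("at least one weight must be positive")
  structure(w, class = "score_weights")
}

ss_codes <- function(ss_target, L) {
  if (is.null(ss_target)) ss_target <- strrep("L", L)
  s <- if (length(ss_target) == 1L) strsplit(ss_target, "")[[1]] else ss_target
  if (length(s) != L)
    stop("ss_target length (", length(s), ") != sequence length (", L, ")")
  code <- match(s, c("H", "E", "L")) - 1L
  if (anyNA(code)) stop("ss_target may only contain H, E, L")
  code
}

#' Coarse-grained energy terms of a structure
#'
#' Evaluates the five surrogate energy terms (see [score_weights()] for
#' their definitions) on a built structure. The secondary-structure mismatch
#' term classifies each residue from its phi/psi angles (helix:
#' phi in \[-100, -30\] and psi in \[-80, -5\]; strand: phi in \[-180, -60\]
#' and psi in \[60, 180\]; otherwise loop) and counts disagreements with
#' `ss_target`.
#'
#' @param s A `structure3d` (from [build_backbone()]) or a [conformation].
#' @param ss_target Per-residue H/E/L string (or character vector); `NULL`
#'   means all-loop.
#' @return Named numeric vector of the five term values.
#' @export
energy_terms <- function(s, ss_target = NULL) {
  if (inherits(s, "conformation")) s <- build_backbone(s)
  stopifnot(inherits(s, "structure3d"))
  L <- nres(s)
  d <- s$dihedrals
  if (is.null(d)) stop("structure carries no dihedrals")
  t <- cpp_energy_terms(s$coords, d[, "phi"], d[, "psi"],
                        ss_codes(ss_target, L))
  names(t) <- TERM_NAMES
  t
}

#' Weighted stage score
#'
#' The conformational energy of a stage is the dot product of the term
#' values with the stage's weight vector; lower is better.
#'
#' @param terms Named term vector as returned by [energy_terms()].
#' @param weights A [score_weights] vector.
#' @return Single numeric score.
#' @export
stage_score <- function(terms, weights) {
  if (!all(TERM_NAMES %in% names(terms)))
    stop("missing term(s): ",
         paste(setdiff(TERM_NAMES, names(terms)), collapse = ", "))
  sum(terms[TERM_NAMES] * unclass(weights)[TERM_NAMES])
}

## Fused fast path used by all search loops: score a conformation directly.
## `counter` is an evaluation-audit environment from new_eval_counter().
conf_energy <- function(conf, ss_code, weights, counter = NULL) {
  d <- conf$dihedrals
  e <- cpp_score_conformation(d[, "omega"], d[, "phi"], d[, "psi"],
                              cen_radii(conf$sequence), ss_code,
                              unclass(weights)[TERM_NAMES])
  if (!is.null(counter)) counter$n <- counter$n + 1L
  e
}

#' Evaluation-audit counter
#'
#' Search functions accept a counter environment and increment `$n` once per
#' energy evaluation (one evaluation per fragment-insertion attempt). Used
#' to verify budget parity between protocols.
#'
#' @return Environment with field `n` initialised to 0.
#' @export
new_eval_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e
}

#' Single protocol stage
#'
#' @param name Stage label.
#' @param weights [score_weights] used as the stage's fitness.
#' @param k Fragment length used in this stage (3 or 9).
#' @param cycles Base fragment-insertion attempts of the stage, before the
#'   `increase_cycles` multiplier.
#' @param temperature Metropolis temperature (energy units).
#' @return List of class `protocol_stage`.
#' @export
protocol_stage <- function(name, weights, k, cycles, temperature = 2) {
  stopifnot(k %in% c(3, 9), cycles >= 0, temperature > 0)
  structure(list(name = name, weights = weights, k = as.integer(k),
                 cycles = as.integer(cycles), temperature = temperature),
            class = "protocol_stage")
}

#' Stage schedule
#'
#' Ordered list of [protocol_stage()]s. The final stage of any schedule must
#' enable all five energy terms (the full, "score3-like" energy used to
#' report decoys).
#'
#' @param ... `protocol_stage` objects.
#' @return List of class `stage_schedule`.
#' @export
stage_schedule <- function(...) {
  stages <- list(...)
  if (length(stages) == 1L && is.list(stages[[1]]) &&
      !inherits(stages[[1]], "protocol_stage"))
    stages <- stages[[1]]
  if (!length(stages)) stop("a schedule needs at least one stage")
  lapply(stages, function(s) stopifnot(inherits(s, "protocol_stage")))
  last <- stages[[length(stages)]]
  if (any(unclass(last$weights) == 0))
    stop("the final stage must use the all-terms weight set")
  structure(stages, class = "stage_schedule")
}

#' @export
print.stage_schedule <- function(x, ...) {
  cat("<stage_schedule> ", length(x), " stage(s)\n", sep = "")
  for (s in x)
    cat(sprintf("  %-8s k=%d cycles=%d T=%.2g weights=(%s)\n", s$name, s$k,
                s$cycles, s$temperature,
                paste(unclass(s$weights), collapse = ", ")))
  invisible(x)
}

#' Default stage schedules
#'
#' The baseline ab initio protocol ramps the energy in four stages,
#' progressively adding terms (steric-only; + compactness and hydrogen
#' bonding; compactness and secondary structure emphasis; all terms), using
#' 9-mer fragments for the first three stages and 3-mers for the final
#' refinement stage. The evolutionary protocols use a three-stage schedule
#' equal to baseline stages 2-4 (their initial population is generated by
#' baseline stage 1).
#'
#' @param base_cycles Integer vector of 4 base cycle counts for the baseline
#'   stages; the defaults are package configuration, multiplied at run time
#'   by `increase_cycles`.
#' @param temperature Metropolis temperature applied to every stage.
#' @return List with elements `abinitio` (4 stages) and `evolutionary`
#'   (3 stages), both [stage_schedule]s.
#' @export
default_schedules <- function(base_cycles = c(2000L, 2000L, 2000L, 4000L),
                              temperature = 2) {
  stopifnot(length(base_cycles) == 4L)
  s1 <- protocol_stage("stage1", score_weights(steric = 1), 9,
                       base_cycles[1], temperature)
  s2 <- protocol_stage("stage2",
                       score_weights(steric = 1, rg = 0.5, hbond = 1), 9,
                       base_cycles[2], temperature)
  s3 <- protocol_stage("stage3",
                       score_weights(steric = 1, rg = 1, ss_pair = 2), 9,
                       base_cycles[3], temperature)
  s4 <- protocol_stage("stage4",
                       score_weights(1, 1, 1, 1, 1), 3,
                       base_cycles[4], temperature)
  list(abinitio = stage_schedule(s1, s2, s3, s4),
       evolutionary = stage_schedule(s2, s3, s4))
}

#' Serialize / restore a schedule as YAML
#'
#' @param schedule A [stage_schedule].
#' @param path File path.
#' @return `schedule_to_yaml` returns `path` invisibly;
#'   `schedule_from_yaml` returns a [stage_schedule].
#' @export
schedule_to_yaml <- function(schedule, path) {
  stopifnot(inherits(schedule, "stage_schedule"))
  x <- lapply(schedule, function(s)
    list(name = s$name, weights = as.list(unclass(s$weights)), k = s$k,
         cycles = s$cycles, temperature = s$temperature))
  yaml::write_yaml(list(stages = x), path)
  invisible(path)
}

#' @rdname schedule_to_yaml
#' @export
schedule_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  stage_schedule(lapply(x$stages, function(s)
    protocol_stage(s$name, do.call(score_weights, s$weights), s$k, s$cycles,
                   s$temperature)))
}

#' Write a whitespace-delimited score file
#'
#' One row per decoy: total score, the five term values and the decoy tag,
#' in the style of classic protein-decoy score tables.
#'
#' @param decoys A `decoy_set` (see [abinitio_protocol()]).
#' @param path Output path.
#' @param ss_target Secondary-structure target used for the term breakdown.
#' @return `path`, invisibly.
#' @export
write_score_file <- function(decoys, path, ss_target = NULL) {
  stopifnot(inherits(decoys, "decoy_set"))
  rows <- lapply(seq_along(decoys$conformations), function(i) {
    t <- energy_terms(decoys$conformations[[i]], ss_target)
    data.frame(total = sum(t * rep(1, 5)), t(t), tag = decoys$tags[i])
  })
  df <- do.call(rbind, rows)
  df$total <- decoys$energies
  utils::write.table(format(df, digits = 6), path, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
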