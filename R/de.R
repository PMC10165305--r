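#' Differential-evolution configuration
#'
#' Settings for the memetic searches. The DE strategy is fixed to
#' `rand/1/bin`: the mutant is built from a random base member plus the
#' weighted difference of two further distinct members, followed by
#' binomial crossover with one forced gene. The defaults are the study
#' settings: a small mutation weight `F = 0.025` generating trials with
#' slight variation around their base conformation, and a high crossover
#' probability `CR = 0.99`.
#'
#' @param population_size Number of members. `rand/1` mutation requires at
#'   least 4; size 1 is also accepted as a documented degenerate case (the
#'   trial then equals its target) used to check that crowding reduces to
#'   greedy selection.
#' @param generations_per_stage Generations run in each schedule stage.
#' @param F Mutation weight (>= 0).
#' @param CR Crossover probability in `[0, 1]`.
#' @param local_search Refinement insertions per target per generation; the
#'   default `NULL` derives the budget from the stage's base cycles times
#'   `increase_cycles` (see the package vignette for the accounting).
#' @param increase_cycles Budget multiplier (the evolutionary protocols use
#'   0.1 where the baseline uses 10: a hundredfold smaller per-generation
#'   allocation, spent over the generations).
#' @param seed Base RNG seed.
#' @return List of class `de_config`.
#' @export
de_config <- function(population_size = 100, generations_per_stage = 100,
                      F = 0.025, CR = 0.99, local_search = NULL,
                      increase_cycles = 0.1, seed = 1) {
  population_size <- as.integer(population_size)
  if (population_size < 1L)
    stop("population_size must be >= 1")
  if (population_size %in% 2:3)
    stop("population_size must be 1 (degenerate) or >= 4 for rand/1")
  if (CR < 0 || CR > 1) stop("CR must be in [0, 1]")
  if (F < 0) stop("F must be >= 0")
  if (increase_cycles <= 0) stop("increase_cycles must be > 0")
  structure(list(population_size = population_size,
                 generations_per_stage = as.integer(generations_per_stage),
                 F = F, CR = CR, strategy = "rand/1/bin",
                 local_search = local_search,
                 increase_cycles = increase_cycles,
                 seed = as.integer(seed)),
            class = "de_config")
}

#' Population container
#'
#' @param members List of [conformation]s.
#' @param fitness Numeric vector of fitness values (current stage score).
#' @param stage_index,generation Bookkeeping indices.
#' @return List of class `de_population`.
#' @export
de_population <- function(members, fitness, stage_index = 1L,
                          generation = 0L) {
  stopifnot(length(members) == length(fitness))
  structure(list(members = members, fitness = fitness,
                 stage_index = as.integer(stage_index),
                 generation = as.integer(generation)),
            class = "de_population")
}

#' @export
print.de_population <- function(x, ...) {
  cat("<de_population> ", length(x$members), " members, stage ",
      x$stage_index, ", generation ", x$generation, ", best fitness ",
      round(min(x$fitness), 3), "\n", sep = "")
  invisible(x)
}

#' Build a DE/rand/1/bin trial conformation
#'
#' Genes are the per-residue phi and psi angles (omega is left to fragment
#' insertion). The mutant gene is
#' `wrap_angle(x_r1 + F * angle_diff(x_r2, x_r3))` with `r1, r2, r3`
#' distinct and different from the target; angular arithmetic uses the
#' signed shortest arc. Binomial crossover takes the mutant gene where
#' `u_g < CR` or at one forced random gene, and the target gene elsewhere.
#'
#' @param target_idx Index of the target member.
#' @param pop A [de_population].
#' @param F,CR DE parameters.
#' @param arithmetic `"circular"` (default) performs the mutation with
#'   shortest-arc differences on the circle, avoiding wrap artifacts at the
#'   +/-180 seam; `"linear"` treats angles as plain reals (the raw
#'   difference), provided for comparison.
#' @return A trial [conformation].
#' @export
de_trial <- function(target_idx, pop, F, CR,
                     arithmetic = c("circular", "linear")) {
  arithmetic <- match.arg(arithmetic)
  n <- length(pop$members)
  target <- pop$members[[target_idx]]
  if (n == 1L) {
    r1 <- r2 <- r3 <- 1L        # degenerate: zero difference, trial = target
  } else if (n < 4L) {
    stop("rand/1 mutation needs a population of at least 4")
  } else {
    pool <- setdiff(seq_len(n), target_idx)
    r <- sample(pool, 3L)
    r1 <- r[1]; r2 <- r[2]; r3 <- r[3]
  }
  gene <- function(conf) as.vector(conf$dihedrals[, c("phi", "psi")])
  x_t <- gene(target)
  x1 <- gene(pop$members[[r1]])
  x2 <- gene(pop$members[[r2]])
  x3 <- gene(pop$members[[r3]])
  d <- if (arithmetic == "circular") angle_diff(x2, x3) else x2 - x3
  mutant <- wrap_angle(x1 + F * d)
  ng <- length(x_t)
  j_rand <- sample.int(ng, 1L)
  use_mut <- stats::runif(ng) < CR
  use_mut[j_rand] <- TRUE
  trial_genes <- ifelse(use_mut, mutant, x_t)
  d <- target$dihedrals
  d[, c("phi", "psi")] <- matrix(trial_genes, ncol = 2)
  conformation(target$sequence, d)
}

#' Metropolis fragment-insertion refinement
#'
#' Applies `attempts` Metropolis fragment-insertion steps under the stage's
#' score and returns the best conformation seen (including the start
#' point). Exactly `attempts` energy evaluations are charged to `counter`;
#' the start-point energy is taken from `e_start` when known, otherwise it
#' is computed once without charge.
#'
#' @inheritParams run_mc_stage
#' @param attempts Number of insertion attempts (>= 0).
#' @param e_start Known energy of `conf` under the stage weights.
#' @return List with `conformation` and `energy` (best seen).
#' @export
local_refine <- function(conf, lib, stage, attempts, ss_target = NULL,
                         counter = NULL, e_start = NULL) {
  if (attempts < 0) stop("attempts must be >= 0")
  res <- run_mc_stage(conf, lib, stage, attempts, ss_target = ss_target,
                      counter = counter, recover_best = TRUE,
                      e_current = e_start)
  list(conformation = res$conformation, energy = res$best_energy)
}

## Shared engine of HybridDE / CrowdingDE. `selection` decides whether a
## refined trial competes with its own target (greedy) or with its nearest
## member by CA-RMSD (crowding).
memetic_engine <- function(sequence, libs, config, schedule, ss_target,
                           selection = c("greedy", "crowding"),
                           init_stage = NULL, counter = NULL,
                           track_diversity = FALSE) {
  selection <- match.arg(selection)
  stopifnot(inherits(config, "de_config"))
  if (!inherits(sequence, "aa_sequence")) sequence <- aa_sequence(sequence)
  if (is.null(schedule)) schedule <- default_schedules()$evolutionary
  if (is.null(init_stage))
    # steric-only seeding stage, scaled like the first evolutionary stage
    init_stage <- protocol_stage("stage1", score_weights(steric = 1),
                                 schedule[[1]]$k, schedule[[1]]$cycles,
                                 schedule[[1]]$temperature)
  libs <- normalize_libs(libs)
  if (is.null(counter)) counter <- new_eval_counter()
  L <- length(sequence)
  ssc <- ss_codes(ss_target, L)
  np <- config$population_size
  gens <- config$generations_per_stage
  ic <- config$increase_cycles

  ## initial population: independent baseline-stage-1 runs at the stage-1
  ## share of the total budget (see vignette, budget accounting)
  init_cycles <- round(init_stage$cycles * ic * max(1L, gens))
  members <- vector("list", np)
  for (i in seq_len(np)) {
    set.seed(config$seed + i)
    members[[i]] <- run_mc_stage(extended_conformation(sequence),
                                 lib_for_stage(libs, init_stage$k),
                                 init_stage, init_cycles,
                                 ss_target = ss_target,
                                 counter = counter)$conformation
  }
  set.seed(config$seed)
  init_members <- members
  fitness <- rep(NA_real_, np)
  hist <- list()
  for (s in seq_along(schedule)) {
    stage <- schedule[[s]]
    lib <- lib_for_stage(libs, stage$k)
    for (i in seq_len(np))                     # (re)score under stage weights
      fitness[i] <- conf_energy(members[[i]], ssc, stage$weights, counter)
    b <- max(2L, round(stage$cycles * ic))     # per-target budget/generation
    h_trial <- as.integer(ceiling((b - 1L) / 2))
    h_member <- b - 1L - h_trial
    for (g in seq_len(max(0L, gens))) {
      for (i in seq_len(np)) {
        trial <- de_trial(i, de_population(members, fitness), config$F,
                          config$CR)
        e_t <- conf_energy(trial, ssc, stage$weights, counter)
        ref <- local_refine(trial, lib, stage, h_trial,
                            ss_target = ss_target, counter = counter,
                            e_start = e_t)
        j <- if (selection == "greedy") i
             else nearest_index(ref$conformation, members)
        if (ref$energy < fitness[j]) {
          members[[j]] <- ref$conformation
          fitness[j] <- ref$energy
        }
        upd <- local_refine(members[[i]], lib, stage, h_member,
                            ss_target = ss_target, counter = counter,
                            e_start = fitness[i])
        members[[i]] <- upd$conformation
        fitness[i] <- upd$energy
      }
      hist[[length(hist) + 1L]] <- data.frame(
        stage = s, generation = g, best = min(fitness),
        mean = mean(fitness),
        diversity = if (track_diversity) mean_pairwise_rmsd(members)
                    else NA_real_)
    }
  }
  history <- if (length(hist)) do.call(rbind, hist)
             else data.frame(stage = integer(), generation = integer(),
                             best = numeric(), mean = numeric(),
                             diversity = numeric())
  structure(list(
    population = de_population(members, fitness,
                               stage_index = length(schedule),
                               generation = max(0L, gens)),
    initial_population = init_members,
    history = history,
    method = if (selection == "greedy") "hybridde" else "crowdingde",
    config = config, schedule = schedule,
    n_evaluations = counter$n), class = "memetic_run")
}

#' HybridDE: memetic differential evolution with fragment insertion
#'
#' Population-based conformational search combining DE/rand/1/bin over
#' dihedral genomes with Metropolis fragment-insertion refinement of both
#' trial and surviving solutions. The fitness follows a three-stage
#' schedule (the baseline protocol's stages 2-4); the initial population is
#' generated by independent runs of the baseline's steric-only first stage.
#' Selection is strictly-better greedy replacement of the trial's target.
#'
#' @param sequence Target [aa_sequence].
#' @param libs Fragment libraries (list with 9-mer and/or 3-mer).
#' @param config A [de_config()].
#' @param schedule Three-stage [stage_schedule]; default
#'   `default_schedules()$evolutionary`.
#' @param ss_target Secondary-structure target string.
#' @param init_stage Stage used to seed the initial population (default:
#'   the baseline's steric-only stage 1).
#' @param counter Optional audit counter.
#' @return Object of class `memetic_run`: final `population`, per-generation
#'   `history` (best and mean fitness), `n_evaluations`, configuration.
#' @export
hybridde <- function(sequence, libs, config = de_config(), schedule = NULL,
                     ss_target = NULL, init_stage = NULL, counter = NULL) {
  memetic_engine(sequence, libs, config, schedule, ss_target,
                 selection = "greedy", init_stage = init_stage,
                 counter = counter)
}

#' @export
print.memetic_run <- function(x, ...) {
  cat("<memetic_run> ", x$method, ": ", length(x$population$members),
      " members, ", nrow(x$history), " generations recorded, best fitness ",
      round(min(x$population$fitness), 3), ", ", x$n_evaluations,
      " energy evaluations\n", sep = "")
  invisible(x)
}

#' Convert a memetic run's final population to a decoy set
#'
#' @param run A `memetic_run`.
#' @return A `decoy_set` whose energies are the final-stage fitness values.
#' @export
as_decoy_set <- function(run) {
  stopifnot(inherits(run, "memetic_run"))
  structure(list(conformations = run$population$members,
                 energies = run$population$fitness,
                 tags = sprintf("%s_%04d", run$method,
                                seq_along(run$population$members)),
                 method = run$method,
                 n_evaluations = run$n_evaluations,
                 config = run$config),
            class = "decoy_set")
}
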