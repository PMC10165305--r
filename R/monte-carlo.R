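#' Metropolis acceptance criterion
#'
#' Moves that do not worsen the energy are always accepted; a worsening move
#' is accepted when the supplied uniform draw `u` falls below
#' `exp(-delta_e / temperature)`.
#'
#' @param delta_e Energy change of the proposed move.
#' @param temperature Metropolis temperature, must be positive.
#' @param u Uniform(0,1) draw; defaults to a fresh draw from the current RNG
#'   stream.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_e, temperature, u = stats::runif(1)) {
  if (temperature <= 0) stop("temperature must be positive")
  if (delta_e <= 0) return(TRUE)
  u < exp(-delta_e / temperature)
}

normalize_libs <- function(libs) {
  if (inherits(libs, "fragment_library")) libs <- list(libs)
  out <- list()
  for (l in libs) {
    stopifnot(inherits(l, "fragment_library"))
    out[[as.character(l$k)]] <- l
  }
  out
}

lib_for_stage <- function(libs, k) {
  l <- libs[[as.character(k)]]
  if (is.null(l)) {
    # short targets cannot host 9-mers; fall back to the library we have
    if (length(libs) == 0L) stop("no fragment library supplied")
    l <- libs[[1L]]
  }
  l
}

#' Run one Metropolis Monte Carlo stage
#'
#' Performs `cycles` fragment-insertion attempts on `conf`, each proposed by
#' [random_fragment_move()], scored under the stage's weights and accepted
#' by [metropolis_accept()]. Exactly `cycles` energy evaluations are charged
#' to `counter` (scoring the incumbent start point is free: attempts are
#' synonymous with energy evaluations).
#'
#' @param conf Starting [conformation].
#' @param lib Fragment library matching the stage's fragment length.
#' @param stage A [protocol_stage()].
#' @param cycles Number of insertion attempts (>= 0).
#' @param ss_target Secondary-structure target string.
#' @param counter Optional [new_eval_counter()] audit counter.
#' @param recover_best Return the best-energy conformation seen (default)
#'   rather than the last accepted one.
#' @param e_current Known energy of `conf` under this stage's weights; if
#'   `NULL` it is computed once without charging the counter.
#' @return List with `conformation`, `energy`, `trace` (current energy after
#'   each cycle), `best_energy`, `accepted` (count).
#' @export
run_mc_stage <- function(conf, lib, stage, cycles, ss_target = NULL,
                         counter = NULL, recover_best = TRUE,
                         e_current = NULL) {
  stopifnot(inherits(stage, "protocol_stage"))
  if (cycles < 0) stop("cycles must be >= 0")
  L <- nres(conf)
  ssc <- ss_codes(ss_target, L)
  if (is.null(e_current))
    e_current <- conf_energy(conf, ssc, stage$weights)
  best <- conf; e_best <- e_current
  trace <- numeric(cycles)
  acc <- 0L
  for (cy in seq_len(cycles)) {
    prop <- random_fragment_move(conf, lib)
    e_new <- conf_energy(prop$conformation, ssc, stage$weights, counter)
    if (metropolis_accept(e_new - e_current, stage$temperature)) {
      conf <- prop$conformation
      e_current <- e_new
      acc <- acc + 1L
      if (e_current < e_best) { best <- conf; e_best <- e_current }
    }
    trace[cy] <- e_current
  }
  out_conf <- if (recover_best) best else conf
  out_e <- if (recover_best) e_best else e_current
  list(conformation = out_conf, energy = out_e, trace = trace,
       best_energy = e_best, accepted = acc)
}

#' Baseline protocol configuration
#'
#' @param increase_cycles Positive multiplier on every stage's base cycle
#'   count (the budget unit shared across protocols).
#' @param n_decoys Number of independent trajectories / decoys.
#' @param seed Base RNG seed; trajectory `i` uses `seed + i`.
#' @return List of class `protocol_config`.
#' @export
protocol_config <- function(increase_cycles = 10, n_decoys = 1, seed = 1) {
  if (!is.numeric(increase_cycles) || increase_cycles <= 0)
    stop("increase_cycles must be > 0")
  if (n_decoys < 1) stop("n_decoys must be >= 1")
  structure(list(increase_cycles = increase_cycles,
                 n_decoys = as.integer(n_decoys),
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Four-stage fragment-assembly Monte Carlo protocol
#'
#' The baseline decoy generator. Each trajectory starts from the fully
#' extended conformation and runs the schedule's stages in order with
#' `round(base_cycles * increase_cycles)` insertion attempts per stage,
#' carrying the stage result (best-seen by default) into the next stage.
#' The final conformation is reported with its all-terms (final-stage)
#' score. Trajectories are independent given per-decoy seeds `seed + i`.
#'
#' @param sequence Target [aa_sequence].
#' @param libs Fragment libraries (a list; 9-mer and 3-mer as available).
#' @param config A [protocol_config()].
#' @param schedule Four-stage [stage_schedule]; default
#'   `default_schedules()$abinitio`.
#' @param ss_target Secondary-structure target string.
#' @param counter Optional audit counter.
#' @return Object of class `decoy_set`: list with `conformations`,
#'   `energies` (final-stage scores), `tags`, `method`, `n_evaluations`.
#' @export
abinitio_protocol <- function(sequence, libs, config = protocol_config(),
                              schedule = NULL, ss_target = NULL,
                              counter = NULL) {
  stopifnot(inherits(config, "protocol_config"))
  if (!inherits(sequence, "aa_sequence")) sequence <- aa_sequence(sequence)
  if (is.null(schedule)) schedule <- default_schedules()$abinitio
  libs <- normalize_libs(libs)
  if (is.null(counter)) counter <- new_eval_counter()
  confs <- vector("list", config$n_decoys)
  energies <- numeric(config$n_decoys)
  final_stage <- schedule[[length(schedule)]]
  ssc <- ss_codes(ss_target, length(sequence))
  for (i in seq_len(config$n_decoys)) {
    set.seed(config$seed + i)
    conf <- extended_conformation(sequence)
    for (stage in schedule) {
      cycles <- round(stage$cycles * config$increase_cycles)
      res <- run_mc_stage(conf, lib_for_stage(libs, stage$k), stage, cycles,
                          ss_target = ss_target, counter = counter)
      conf <- res$conformation
    }
    confs[[i]] <- conf
    energies[i] <- conf_energy(conf, ssc, final_stage$weights)
    set.seed(NULL)
  }
  structure(list(conformations = confs, energies = energies,
                 tags = sprintf("decoy_%04d", seq_len(config$n_decoys)),
                 method = "abinitio", n_evaluations = counter$n,
                 config = config),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat("<decoy_set> ", length(x$conformations), " decoys (", x$method,
      "), energy range [", round(min(x$energies), 2), ", ",
      round(max(x$energies), 2), "], ", x$n_evaluations,
      " energy evaluations\n", sep = "")
  invisible(x)
}

#' Join several decoy sets
#' @param ... `decoy_set` objects.
#' @return A single `decoy_set`.
#' @export
join_decoys <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "decoy_set"))
    sets <- sets[[1]]
  structure(list(
    conformations = do.call(c, lapply(sets, `[[`, "conformations")),
    energies = do.call(c, lapply(sets, `[[`, "energies")),
    tags = unlist(lapply(seq_along(sets), function(i)
      paste0("run", i, "_", sets[[i]]$tags))),
    method = sets[[1]]$method,
    n_evaluations = sum(vapply(sets, `[[`, numeric(1), "n_evaluations")),
    config = sets[[1]]$config), class = "decoy_set")
}
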