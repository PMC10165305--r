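## CA-RMSD nearest neighbour over a plain list of conformations.
nearest_index <- function(conf, members, metric = c("rmsd", "dihedral")) {
  metric <- match.arg(metric)
  d <- vapply(members, function(m) conformation_distance(conf, m, metric),
              numeric(1))
  which.min(d)   # ties: lowest index
}

conformation_distance <- function(a, b, metric = c("rmsd", "dihedral")) {
  metric <- match.arg(metric)
  if (metric == "rmsd") return(ca_rmsd(a, b))
  g <- function(x) as.vector(x$dihedrals[, c("phi", "psi")])
  sqrt(mean(angle_diff(g(a), g(b))^2))
}

mean_pairwise_rmsd <- function(members) {
  n <- length(members)
  if (n < 2L) return(0)
  cas <- lapply(members, ca_coords)
  tot <- 0; cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + superpose_rmsd(cas[[i]], cas[[j]])$rmsd
    cnt <- cnt + 1L
  }
  tot / cnt
}

#' Structurally nearest population member
#'
#' Returns the index of the member minimising the structural distance
#' (CA-RMSD after optimal superposition, or root-mean-square dihedral
#' difference) to `conf`; ties are broken by the lowest index.
#'
#' @param conf A [conformation].
#' @param pop A [de_population].
#' @param metric `"rmsd"` (default) or `"dihedral"`.
#' @return 1-based member index.
#' @export
nearest_member <- function(conf, pop, metric = c("rmsd", "dihedral")) {
  stopifnot(inherits(pop, "de_population"))
  if (!length(pop$members)) stop("population is empty")
  nearest_index(conf, pop$members, match.arg(metric))
}

#' Crowding replacement
#'
#' The trial competes only with its structurally nearest population member
#' and replaces it when (and only when) its fitness is strictly better;
#' otherwise the population is returned unchanged. This preserves multiple
#' optimised niches in a multimodal landscape.
#'
#' @param trial A trial [conformation].
#' @param pop A [de_population] whose fitness matches `stage_weights`.
#' @param stage_weights [score_weights] under which fitness is measured.
#' @param ss_target Secondary-structure target string.
#' @param trial_fitness Precomputed trial fitness; computed if `NULL`.
#' @param metric Crowding distance metric, see [nearest_member()].
#' @return List with the updated `population` and `replaced` (the index
#'   replaced, or `NA` if none).
#' @export
crowding_replace <- function(trial, pop, stage_weights, ss_target = NULL,
                             trial_fitness = NULL,
                             metric = c("rmsd", "dihedral")) {
  stopifnot(inherits(pop, "de_population"))
  if (is.null(trial_fitness))
    trial_fitness <- conf_energy(trial, ss_codes(ss_target, nres(trial)),
                                 stage_weights)
  j <- nearest_member(trial, pop, match.arg(metric))
  if (trial_fitness < pop$fitness[j]) {
    pop$members[[j]] <- trial
    pop$fitness[j] <- trial_fitness
    return(list(population = pop, replaced = j))
  }
  list(population = pop, replaced = NA_integer_)
}

#' CrowdingDE: memetic differential evolution with crowding niching
#'
#' Identical to [hybridde()] except for the selection step: each refined
#' trial competes with its structurally nearest member (CA-RMSD) rather
#' than with its own target, so distinct low-energy conformations survive
#' side by side. The per-generation history additionally records the mean
#' pairwise CA-RMSD of the population (diversity trace).
#'
#' @inheritParams hybridde
#' @return A `memetic_run`; see [hybridde()].
#' @export
crowdingde <- function(sequence, libs, config = de_config(),
                       schedule = NULL, ss_target = NULL, init_stage = NULL,
                       counter = NULL) {
  memetic_engine(sequence, libs, config, schedule, ss_target,
                 selection = "crowding", init_stage = init_stage,
                 counter = counter, track_diversity = TRUE)
}

#' Niche summary of a population
#'
#' Pairwise CA-RMSD matrix of the population plus the niche count at a
#' distance threshold (single-linkage components of the graph joining
#' members closer than `threshold`).
#'
#' @param pop A [de_population].
#' @param threshold Distance threshold in Angstrom.
#' @return List with `distance` (symmetric matrix, zero diagonal),
#'   `n_niches`, `medoids` (one member index per niche).
#' @export
niche_summary <- function(pop, threshold = 2) {
  stopifnot(inherits(pop, "de_population"))
  n <- length(pop$members)
  cas <- lapply(pop$members, ca_coords)
  D <- matrix(0, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- superpose_rmsd(cas[[i]], cas[[j]])$rmsd
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (D[i, j] < threshold && comp[j] > comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    if (!changed) break
  }
  niches <- unique(comp)
  medoids <- vapply(niches, function(cn) {
    idx <- which(comp == cn)
    idx[which.min(colSums(D[idx, idx, drop = FALSE]))]
  }, integer(1))
  list(distance = D, n_niches = length(niches), medoids = medoids)
}

#' Fitness sharing selection (not implemented)
#'
#' Alternative niching schemes considered alongside crowding; retained as
#' explicit stubs.
#'
#' @param ... Ignored.
#' @export
sharing_select <- function(...) stop("fitness sharing is not implemented; use crowdingde()")

#' @rdname sharing_select
#' @export
speciation_select <- function(...) stop("speciation is not implemented; use crowdingde()")
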