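#' Ideal secondary-structure conformation
#'
#' Builds a conformation from an H/E/L string using ideal dihedrals:
#' helix (-57, -47), strand (-120, 120); loop residues are drawn from a
#' neutral loop region (-150, 30) with seeded jitter of +/- 10 degrees on
#' both angles (the jitter stays outside the helix and strand Ramachandran
#' boxes, so loop residues always classify as loop). Omega is 180
#' everywhere.
#'
#' @param ss H/E/L string (or character vector).
#' @param seed RNG seed for the loop jitter.
#' @param sequence Optional [aa_sequence]; a random one is generated
#'   otherwise.
#' @return A [conformation].
#' @export
make_ideal_conformation <- function(ss, seed = 1, sequence = NULL) {
  s <- if (length(ss) == 1L) strsplit(ss, "")[[1]] else ss
  if (!length(s)) stop("ss must be non-empty")
  if (!all(s %in% c("H", "E", "L")))
    stop("ss may only contain H, E, L")
  L <- length(s)
  set.seed(seed)
  if (is.null(sequence)) sequence <- random_sequence(L, id = "toy")
  phi <- psi <- numeric(L)
  for (i in seq_len(L)) {
    if (s[i] == "H") { phi[i] <- -57; psi[i] <- -47 }
    else if (s[i] == "E") { phi[i] <- -120; psi[i] <- 120 }
    else {
      phi[i] <- -150 + stats::runif(1, -10, 10)
      psi[i] <- 30 + stats::runif(1, -10, 10)
    }
  }
  conformation(sequence, cbind(omega = rep(180, L), phi = phi, psi = psi))
}

perturbed_copy <- function(conf, noise_deg, id) {
  d <- conf$dihedrals
  if (noise_deg > 0) {
    L <- nrow(d)
    d[, "phi"] <- wrap_angle(d[, "phi"] + stats::rnorm(L, 0, noise_deg))
    d[, "psi"] <- wrap_angle(d[, "psi"] + stats::rnorm(L, 0, noise_deg))
  }
  sq <- conf$sequence
  attr(sq, "id") <- id
  conformation(sq, d)
}

toy_problem <- function(target, native, ss_target, libraries,
                        deceptive = FALSE, decoy_fold = NULL, info = list()) {
  structure(list(target = target, native = native, ss_target = ss_target,
                 libraries = libraries, deceptive = deceptive,
                 decoy_fold = decoy_fold, info = info),
            class = "toy_problem")
}

#' @export
print.toy_problem <- function(x, ...) {
  cat("<toy_problem> ", length(x$target), " residues, ss = ", x$ss_target,
      if (x$deceptive) " [deceptive two-fold]" else "", "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic folding toy problem
#'
#' A self-contained test substrate: a random target sequence, a native
#' conformation built from ideal secondary-structure dihedrals, and 3-mer
#' (and, where the chain is long enough, 9-mer) fragment libraries built
#' from the native itself plus `n_noise_sources` dihedral-perturbed copies.
#' With `n_noise_sources = 0` the library is closed over the native: the
#' top-ranked fragment of every window is the aligned native window, so
#' greedy paving reconstructs the native exactly.
#'
#' @param length Chain length (>= 9 so that 9-mer fragments fit).
#' @param ss_pattern H/E/L string of that length; default: helix with loop
#'   caps.
#' @param n_noise_sources Number of perturbed copies added as fragment
#'   sources.
#' @param noise_deg Standard deviation (degrees) of the dihedral noise.
#' @param seed RNG seed; generation is fully reproducible from the
#'   arguments.
#' @param n_per_position Fragments retained per library window. The default
#'   1 keeps only the best-matching (aligned) fragment per window, giving a
#'   closed, controlled move set; raise it for richer searches.
#' @param include_native Keep the native itself among the fragment sources
#'   (default). When `FALSE` the libraries are built from the perturbed
#'   copies only, so fragment quality degrades with `noise_deg`; the native
#'   is then no longer exactly reconstructible.
#' @return A `toy_problem`: list with `target`, `native`, `ss_target`,
#'   `libraries` (named by fragment length).
#' @export
make_toy_problem <- function(length, ss_pattern = NULL, n_noise_sources = 0,
                             noise_deg = 0, seed = 1, n_per_position = 1,
                             include_native = TRUE) {
  if (length < 9) stop("length must be >= 9 (largest fragment must fit)")
  if (is.null(ss_pattern))
    ss_pattern <- paste0("L", strrep("H", length - 2L), "L")
  if (nchar(ss_pattern) != length) stop("ss_pattern length mismatch")
  native <- make_ideal_conformation(ss_pattern, seed = seed)
  set.seed(seed + 1L)
  sources <- if (include_native) list(native) else list()
  for (i in seq_len(n_noise_sources))
    sources[[length(sources) + 1L]] <- perturbed_copy(native, noise_deg,
                                                      paste0("noise", i))
  if (!length(sources))
    stop("no fragment sources: set include_native = TRUE or n_noise_sources > 0")
  libs <- list()
  for (k in c(3L, 9L))
    if (length >= k)
      libs[[as.character(k)]] <- build_library(sources, native$sequence, k,
                                               n_per_position)
  toy_problem(native$sequence, native, ss_pattern, libs)
}

#' Greedy fragment paving
#'
#' Inserts the top-ranked fragment at every window of the library in order.
#' On a closed library this reconstructs the source conformation exactly.
#'
#' @param conf Starting [conformation].
#' @param lib A [fragment_library].
#' @return The paved [conformation].
#' @export
pave_top_fragments <- function(conf, lib) {
  for (pos in seq_along(lib$positions))
    conf <- insert_fragment(conf, lib$positions[[pos]][[1L]], pos)
  conf
}

## Deceptive fold geometry: three strand arms joined by two 2-residue
## turns. The native fold A uses spread ("zig-zag") turns; the decoy fold B
## uses turns that pack the arms into a compact shape whose side-chain
## contacts give it a strictly lower all-terms energy. Turn regions are
## spaced more than 9 residues apart so no single fragment insertion can
## exchange both turns at once.
DECEPTIVE_TURN_A <- c(phi = 150, psi = -30)
DECEPTIVE_TURN_B <- c(phi = 60, psi = -180)

deceptive_layout <- function(length) {
  if (length < 12) stop("length must be >= 12")
  a2 <- max(6L, as.integer(ceiling((length - 4L) / 3)))
  rem <- length - 4L - a2
  a1 <- max(1L, rem %/% 2L)
  a3 <- rem - a1
  t1 <- a1 + seq_len(2L)
  t2 <- a1 + 2L + a2 + seq_len(2L)
  list(a1 = a1, a2 = a2, a3 = a3, turn1 = t1, turn2 = t2)
}

deceptive_fold <- function(sequence, layout, turn) {
  L <- length(sequence)
  phi <- rep(-120, L); psi <- rep(120, L)
  for (idx in c(layout$turn1, layout$turn2)) {
    phi[idx] <- turn["phi"]; psi[idx] <- turn["psi"]
  }
  conformation(sequence, cbind(omega = rep(180, L), phi = phi, psi = psi))
}

#' Generate the deceptive two-fold benchmark
#'
#' Constructs two structurally distinct folds of the same sequence: the
#' designated native fold A and a decoy fold B whose all-terms surrogate
#' energy is strictly lower (B packs its arms through side-chain contacts
#' that A lacks). Fragment libraries are seeded from both folds, so every
#' search sees moves towards either. Energy minimisation is therefore
#' drawn towards B, away from the native: the landscape is deceptive. The
#' construction verifies, and returns, the energy margin
#' `energy(A) - energy(B) > 0` and the CA-RMSD between the folds (> 4 A).
#'
#' @param length Chain length (>= 12; the default 20 gives arms long
#'   enough for a robust margin).
#' @param seed RNG seed (sequence generation).
#' @param n_per_position Fragments retained per library window (default 2:
#'   the aligned windows of the two folds).
#' @return A `toy_problem` with `deceptive = TRUE`, `native` = fold A,
#'   `decoy_fold` = fold B, and `info` carrying `energy_native`,
#'   `energy_decoy`, `margin`, `fold_rmsd`.
#' @export
make_deceptive_problem <- function(length = 20, seed = 1,
                                   n_per_position = 2) {
  layout <- deceptive_layout(length)
  set.seed(seed)
  sequence <- random_sequence(length, id = "deceptive")
  ss <- rep("E", length)
  ss[c(layout$turn1, layout$turn2)] <- "L"
  ss <- paste(ss, collapse = "")
  foldA <- deceptive_fold(sequence, layout, DECEPTIVE_TURN_A)
  foldB <- deceptive_fold(sequence, layout, DECEPTIVE_TURN_B)
  w <- score_weights(1, 1, 1, 1, 1)
  ssc <- ss_codes(ss, length)
  eA <- conf_energy(foldA, ssc, w)
  eB <- conf_energy(foldB, ssc, w)
  if (!(eB < eA))
    stop("construction failed: decoy fold is not lower in energy at length ",
         length)
  fold_rmsd <- ca_rmsd(foldA, foldB)
  if (fold_rmsd <= 4)
    stop("construction failed: folds are closer than 4 A at length ", length)
  srcA <- foldA; attr(srcA$sequence, "id") <- "foldA"
  srcB <- foldB; attr(srcB$sequence, "id") <- "foldB"
  libs <- list()
  for (k in c(3L, 9L))
    if (length >= k)
      libs[[as.character(k)]] <- build_library(list(srcA, srcB), sequence, k,
                                               n_per_position)
  toy_problem(sequence, foldA, ss, libs, deceptive = TRUE,
              decoy_fold = foldB,
              info = list(energy_native = eA, energy_decoy = eB,
                          margin = eA - eB, fold_rmsd = fold_rmsd))
}
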