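#' Fold a protein sequence by energy minimisation
#'
#' Front end to the three search protocols: the four-stage fragment-assembly
#' Monte Carlo baseline (`"abinitio"`), the memetic differential evolution
#' search (`"hybridde"`) and its crowding-niching variant (`"crowdingde"`).
#' Accepts either a target sequence plus fragment libraries or a
#' `toy_problem` from the synthetic generators (whose libraries, secondary
#' structure and native reference are then used automatically).
#'
#' @param x An [aa_sequence] (or string) or a `toy_problem`.
#' @param method One of `"abinitio"`, `"hybridde"`, `"crowdingde"`.
#' @param libs Fragment libraries (ignored when `x` is a `toy_problem`).
#' @param ss_target Secondary-structure target string.
#' @param reference Optional native structure/conformation for RMSD
#'   evaluation.
#' @param config A [protocol_config()] or [de_config()] matching the
#'   method; a default is built from `seed` otherwise.
#' @param schedule Optional [stage_schedule] override.
#' @param seed RNG seed used when `config` is not supplied.
#' @param ... Passed to the underlying runner.
#' @return Object of class `psp_fold` with components `method`, `decoys`
#'   (a `decoy_set`), `run` (the `memetic_run`, for the evolutionary
#'   methods), `table` (energy/RMSD table when a reference is available)
#'   and `reference`.
#' @examples
#' \donttest{
#' prob <- make_toy_problem(12, seed = 3)
#' sched <- default_schedules(base_cycles = c(50L, 50L, 50L, 100L))
#' fit <- psp_fold(prob, method = "abinitio",
#'                 config = protocol_config(increase_cycles = 1,
#'                                          n_decoys = 5, seed = 3),
#'                 schedule = sched$abinitio)
#' print(fit)
#' }
#' @export
psp_fold <- function(x, method = c("abinitio", "hybridde", "crowdingde"),
                     libs = NULL, ss_target = NULL, reference = NULL,
                     config = NULL, schedule = NULL, seed = 1, ...) {
  method <- match.arg(method)
  if (inherits(x, "toy_problem")) {
    sequence <- x$target
    libs <- x$libraries
    if (is.null(ss_target)) ss_target <- x$ss_target
    if (is.null(reference)) reference <- x$native
  } else {
    sequence <- if (inherits(x, "aa_sequence")) x else aa_sequence(x)
    if (is.null(libs)) stop("fragment libraries are required")
  }
  if (method == "abinitio") {
    if (is.null(config)) config <- protocol_config(seed = seed)
    stopifnot(inherits(config, "protocol_config"))
    decoys <- abinitio_protocol(sequence, libs, config, schedule,
                                ss_target, ...)
    run <- NULL
  } else {
    if (is.null(config)) config <- de_config(seed = seed)
    stopifnot(inherits(config, "de_config"))
    runner <- if (method == "hybridde") hybridde else crowdingde
    run <- runner(sequence, libs, config, schedule, ss_target, ...)
    decoys <- as_decoy_set(run)
  }
  tab <- if (!is.null(reference)) decoy_table(decoys, reference) else NULL
  structure(list(method = method, decoys = decoys, run = run, table = tab,
                 reference = reference, sequence = sequence,
                 config = config),
            class = "psp_fold")
}

#' @export
print.psp_fold <- function(x, ...) {
  cat("<psp_fold> method = ", x$method, ", ",
      length(x$decoys$conformations), " final conformation(s)\n", sep = "")
  cat("  best energy: ", round(min(x$decoys$energies), 3), sep = "")
  if (!is.null(x$table))
    cat(",  lowest CA-RMSD to reference: ",
        round(min(x$table$rmsd), 2), " A", sep = "")
  cat("\n  energy evaluations: ", x$decoys$n_evaluations, "\n", sep = "")
  invisible(x)
}

#' @export
summary.psp_fold <- function(object, ...) {
  cat("Protocol: ", object$method, "  (",
      length(object$decoys$conformations), " decoys, ",
      object$decoys$n_evaluations, " energy evaluations)\n", sep = "")
  cat("\nEnergy distribution:\n  ")
  print(distribution_summary(object$decoys$energies))
  if (!is.null(object$table)) {
    cat("CA-RMSD to reference (A):\n  ")
    print(distribution_summary(object$table$rmsd))
    if (stats::sd(object$table$energy) > 0 &&
        stats::sd(object$table$rmsd) > 0)
      cat(sprintf("Spearman(energy, rmsd) = %.3f\n",
                  stats::cor(object$table$energy, object$table$rmsd,
                             method = "spearman")))
  }
  if (!is.null(object$run) && nrow(object$run$history)) {
    h <- object$run$history
    cat("\nFitness trace: ", nrow(h), " generations over ",
        max(h$stage), " stages; final best ",
        round(h$best[nrow(h)], 3), "\n", sep = "")
  }
  invisible(object)
}

#' @export
plot.psp_fold <- function(x, which = c("auto", "scatter", "history"), ...) {
  which <- match.arg(which)
  if (which == "auto")
    which <- if (!is.null(x$table)) "scatter" else "history"
  if (which == "scatter") {
    if (is.null(x$table)) stop("no reference structure: no RMSD available")
    plot_energy_rmsd(x$table, main = paste0(x$method,
                                            ": energy vs CA-RMSD"), ...)
  } else {
    if (is.null(x$run) || !nrow(x$run$history))
      stop("no generation history to plot")
    h <- x$run$history
    idx <- seq_len(nrow(h))
    graphics::plot(idx, h$mean, type = "l", col = "darkgreen",
                   xlab = "generation (stages concatenated)",
                   ylab = "stage fitness",
                   main = paste0(x$method, ": fitness evolution"), ...)
    graphics::lines(idx, h$best, col = "red")
    for (sb in which(diff(h$stage) != 0))
      graphics::abline(v = sb + 0.5, lty = 3, col = "grey50")
    graphics::legend("topright", c("population mean", "best"), lty = 1,
                     col = c("darkgreen", "red"), bty = "n", cex = 0.8)
  }
  invisible(x)
}
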