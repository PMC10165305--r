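#' Energy-versus-RMSD decoy table
#'
#' One row per decoy: tag, all-terms energy and CA-RMSD to the reference
#' structure after optimal superposition. This is the evaluation surface on
#' which prediction protocols are compared.
#'
#' @param decoys A `decoy_set`.
#' @param reference Reference native structure: a `structure3d`, a
#'   [conformation], or a CA coordinate matrix.
#' @param method Provenance label; defaults to the decoy set's method.
#' @return `data.frame` with columns `tag`, `method`, `energy`, `rmsd`.
#' @export
decoy_table <- function(decoys, reference, method = NULL) {
  stopifnot(inherits(decoys, "decoy_set"))
  ref_ca <- ca_coords(reference)
  if (length(decoys$conformations) &&
      nrow(ref_ca) != nres(decoys$conformations[[1]]))
    stop("reference length does not match decoy length")
  rmsd <- vapply(decoys$conformations,
                 function(cf) superpose_rmsd(ca_coords(cf), ref_ca)$rmsd,
                 numeric(1))
  data.frame(tag = decoys$tags,
             method = if (is.null(method)) decoys$method else method,
             energy = decoys$energies, rmsd = rmsd,
             stringsAsFactors = FALSE)
}

#' Distribution summary (quartiles, median, extremes)
#'
#' Five-number summary using linear interpolation between closest ranks
#' (quantile type 7), the convention used for the violin annotations of
#' decoy distributions.
#'
#' @param x Numeric vector (length >= 1).
#' @return List of class `distribution_summary` with `min`, `q1`, `median`,
#'   `q3`, `max`, `n`.
#' @export
distribution_summary <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty input")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(min = min(x), q1 = q[1], median = q[2], q3 = q[3],
                 max = max(x), n = length(x)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("n=%d  min=%.4g  q1=%.4g  median=%.4g  q3=%.4g  max=%.4g\n",
              x$n, x$min, x$q1, x$median, x$q3, x$max))
  invisible(x)
}

#' Compare decoy tables across methods
#'
#' Per-method energy and RMSD distribution summaries, the best-energy and
#' lowest-RMSD decoys, and the Spearman rank correlation between energy and
#' RMSD. A low or negative correlation indicates a deceptive landscape:
#' the best-energy solutions are not those closest to the native structure.
#' (The correlation is a quantitative diagnostic added by this package on
#' top of the usual visual comparison.)
#'
#' @param tables Named list of [decoy_table()] data frames (>= 2 methods),
#'   or a single combined data frame with a `method` column.
#' @return Object of class `method_comparison` with per-method statistics;
#'   `as.data.frame()` yields the summary table.
#' @export
compare_methods <- function(tables) {
  if (is.data.frame(tables))
    tables <- split(tables, tables$method)
  if (!length(tables)) stop("no method tables supplied")
  for (t in tables)
    if (!nrow(t)) stop("empty method table")
  stats_one <- function(t) {
    list(energy = distribution_summary(t$energy),
         rmsd = distribution_summary(t$rmsd),
         best_energy = t[which.min(t$energy), , drop = FALSE],
         lowest_rmsd = t[which.min(t$rmsd), , drop = FALSE],
         spearman = if (nrow(t) > 1L)
           stats::cor(t$energy, t$rmsd, method = "spearman") else NA_real_,
         n = nrow(t))
  }
  structure(list(methods = lapply(tables, stats_one)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> ", length(x$methods), " methods\n", sep = "")
  for (m in names(x$methods)) {
    s <- x$methods[[m]]
    cat("\n== ", m, " (n = ", s$n, ") ==\n", sep = "")
    cat("  energy: "); print(s$energy)
    cat("  rmsd:   "); print(s$rmsd)
    cat(sprintf("  best energy %.4g at rmsd %.3g A; lowest rmsd %.3g A\n",
                s$best_energy$energy, s$best_energy$rmsd,
                s$lowest_rmsd$rmsd))
    cat(sprintf("  Spearman(energy, rmsd) = %.3f%s\n", s$spearman,
                if (!is.na(s$spearman) && s$spearman < 0.2)
                  "  [deceptive: low energy does not imply low RMSD]"
                else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.method_comparison <- function(x, ...) {
  do.call(rbind, lapply(names(x$methods), function(m) {
    s <- x$methods[[m]]
    data.frame(method = m, n = s$n,
               energy_min = s$energy$min, energy_median = s$energy$median,
               rmsd_min = s$rmsd$min, rmsd_median = s$rmsd$median,
               spearman = s$spearman, stringsAsFactors = FALSE)
  }))
}

#' Write a method-comparison report as TSV
#' @param x A `method_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Energy-versus-RMSD scatter plot
#'
#' The standard comparison figure: one point per decoy, coloured by method,
#' with marginal distribution hints in the axis labels.
#'
#' @param tables A combined [decoy_table()] data frame (or named list).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the combined data frame.
#' @export
plot_energy_rmsd <- function(tables, ...) {
  df <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  methods <- unique(df$method)
  cols <- grDevices::hcl.colors(max(3L, length(methods)), "Dark 3")
  graphics::plot(df$rmsd, df$energy, col = cols[match(df$method, methods)],
                 pch = 19, cex = 0.6, xlab = "CA-RMSD to native (A)",
                 ylab = "all-terms energy", ...)
  graphics::legend("topright", legend = methods, col = cols[seq_along(methods)],
                   pch = 19, bty = "n", cex = 0.8)
  invisible(df)
}
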