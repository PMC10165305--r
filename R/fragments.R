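#' Backbone-dihedral fragment
#'
#' A run of `k` consecutive residues excised from a source structure,
#' carrying its (omega, phi, psi) triples, source sequence window and a
#' provenance tag. Fragment insertion replaces all three dihedrals of the
#' target window with the fragment's (the fragment carries the source
#' geometry, including omega).
#'
#' @param dihedrals `k x 3` matrix of (omega, phi, psi), degrees.
#' @param source_seq `k`-letter source sequence window.
#' @param source_id Provenance tag.
#' @return Object of class `fragment`.
#' @export
fragment <- function(dihedrals, source_seq, source_id = "src") {
  dihedrals <- as.matrix(dihedrals)
  k <- nrow(dihedrals)
  if (!k %in% c(3L, 9L)) stop("fragment length must be 3 or 9")
  storage.mode(dihedrals) <- "double"
  dihedrals[] <- wrap_angle(dihedrals)
  colnames(dihedrals) <- c("omega", "phi", "psi")
  structure(list(k = k, dihedrals = dihedrals,
                 source_seq = as.character(source_seq)[1],
                 source_id = as.character(source_id)[1]),
            class = "fragment")
}

#' Build a fragment library for a target sequence
#'
#' For every length-`k` window of the target, all `k`-mers of every source
#' are scored by sequence similarity to the window (identity count, the
#' simplest reading of similarity-based selection; see `score_fun` to
#' substitute e.g. a substitution-matrix score) and the best
#' `n_per_position` are retained. Ties are broken by source order, then
#' source offset, making the build fully deterministic.
#'
#' @param sources List of `(sequence, conformation)` pairs: each element a
#'   list with elements `sequence` ([aa_sequence]) and `conformation`
#'   ([conformation]); a bare [conformation] is also accepted (its own
#'   sequence is used).
#' @param target Target [aa_sequence].
#' @param k Fragment length, 3 or 9.
#' @param n_per_position Candidates retained per window (default 25).
#' @param score_fun Similarity hook: `function(window_chars, kmer_chars)`
#'   returning a numeric score. Default: identity count.
#' @return Object of class `fragment_library`: list with `k`,
#'   `n_per_position`, `target_id` and `positions` (one ranked fragment list
#'   per target window `1..L-k+1`).
#' @export
build_library <- function(sources, target, k, n_per_position = 25,
                          score_fun = NULL) {
  if (!inherits(target, "aa_sequence")) target <- aa_sequence(target)
  if (inherits(sources, "conformation")) sources <- list(sources)
  if (!length(sources)) stop("at least one source is required")
  k <- as.integer(k)
  if (!k %in% c(3L, 9L)) stop("k must be 3 or 9")
  L <- length(target)
  if (k > L) stop("k exceeds target length")
  if (is.null(score_fun))
    score_fun <- function(w, f) sum(w == f)
  srcs <- lapply(seq_along(sources), function(i) {
    s <- sources[[i]]
    if (inherits(s, "conformation")) s <- list(sequence = s$sequence,
                                               conformation = s)
    if (length(s$sequence) < k)
      stop("source ", i, " shorter than k")
    s
  })
  tgt <- unclass(target)
  positions <- vector("list", L - k + 1L)
  for (pos in seq_len(L - k + 1L)) {
    window <- tgt[pos:(pos + k - 1L)]
    cand <- list(); sc <- numeric(0); src_i <- integer(0); off_i <- integer(0)
    for (si in seq_along(srcs)) {
      s <- srcs[[si]]
      sseq <- unclass(s$sequence)
      nk <- length(sseq) - k + 1L
      for (off in seq_len(nk)) {
        kmer <- sseq[off:(off + k - 1L)]
        cand[[length(cand) + 1L]] <- fragment(
          s$conformation$dihedrals[off:(off + k - 1L), , drop = FALSE],
          paste(kmer, collapse = ""),
          source_id = paste0(seq_id(s$sequence), "@", off))
        sc <- c(sc, score_fun(window, kmer))
        src_i <- c(src_i, si); off_i <- c(off_i, off)
      }
    }
    ord <- order(-sc, src_i, off_i)
    keep <- ord[seq_len(min(n_per_position, length(ord)))]
    positions[[pos]] <- cand[keep]
  }
  structure(list(k = k, n_per_position = as.integer(n_per_position),
                 target_id = seq_id(target), positions = positions),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("<fragment_library> k=", x$k, ", ", length(x$positions),
      " windows, <= ", x$n_per_position, " fragments each (target ",
      x$target_id, ")\n", sep = "")
  invisible(x)
}

#' Insert a fragment into a conformation
#'
#' Returns a new conformation whose dihedrals on the window
#' `[pos, pos + k - 1]` are replaced by the fragment's; every other residue
#' is untouched and the input conformation is not modified.
#'
#' @param conf A [conformation].
#' @param frag A [fragment].
#' @param pos 1-based window start, `1 <= pos <= L - k + 1`.
#' @return A new [conformation].
#' @export
insert_fragment <- function(conf, frag, pos) {
  stopifnot(inherits(conf, "conformation"), inherits(frag, "fragment"))
  L <- nres(conf)
  if (pos < 1L || pos > L - frag$k + 1L)
    stop("pos out of range: ", pos)
  d <- conf$dihedrals
  d[pos:(pos + frag$k - 1L), ] <- frag$dihedrals
  conf$dihedrals <- d
  conf
}

#' Propose a random fragment insertion
#'
#' Draws a window position uniformly, then a fragment uniformly from that
#' window's retained list, and returns the proposed conformation together
#' with the draw. No acceptance decision is made here. Uses the current R
#' random-number stream.
#'
#' @param conf A [conformation].
#' @param lib A [build_library()] result for `conf`'s sequence.
#' @return List `(conformation, pos, fragment)`.
#' @export
random_fragment_move <- function(conf, lib) {
  npos <- length(lib$positions)
  pos <- sample.int(npos, 1L)
  frs <- lib$positions[[pos]]
  frag <- frs[[sample.int(length(frs), 1L)]]
  list(conformation = insert_fragment(conf, frag, pos), pos = pos,
       fragment = frag)
}

#' Write / read a fragment library as TSV
#'
#' Plain tab-separated dialect: one row per fragment with columns
#' `position`, `rank`, `k`, `source_id`, `source_seq`, then `k` repeated
#' triples `omega_i`, `phi_i`, `psi_i` (degrees). A header row is included.
#'
#' @param lib A [fragment_library].
#' @param path File path.
#' @param target_id Target identifier recorded when reading.
#' @return `write_fragments` returns `path` invisibly; `read_fragments`
#'   returns a [fragment_library].
#' @export
write_fragments <- function(lib, path) {
  stopifnot(inherits(lib, "fragment_library"))
  k <- lib$k
  ang_cols <- as.vector(t(outer(seq_len(k), c("omega", "phi", "psi"),
                                function(i, a) paste0(a, "_", i))))
  rows <- list()
  for (pos in seq_along(lib$positions)) {
    frs <- lib$positions[[pos]]
    for (r in seq_along(frs)) {
      f <- frs[[r]]
      rows[[length(rows) + 1L]] <- c(pos, r, k, f$source_id, f$source_seq,
                                     sprintf("%.4f", as.vector(t(f$dihedrals))))
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("position", "rank", "k", "source_id", "source_seq",
                   ang_cols)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path, target_id = "target") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  k <- df$k[1]
  npos <- max(df$position)
  positions <- vector("list", npos)
  for (pos in seq_len(npos)) {
    sub <- df[df$position == pos, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    if (!nrow(sub)) stop("window ", pos, " has no fragments")
    positions[[pos]] <- lapply(seq_len(nrow(sub)), function(i) {
      ang <- as.numeric(sub[i, 5 + seq_len(3 * k)])
      fragment(matrix(ang, k, 3, byrow = TRUE), sub$source_seq[i],
               sub$source_id[i])
    })
  }
  structure(list(k = as.integer(k),
                 n_per_position = max(df$rank),
                 target_id = target_id, positions = positions),
            class = "fragment_library")
}
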