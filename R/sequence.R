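AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid sequence
#'
#' Light-weight container for a protein primary sequence: one-letter codes
#' from the 20-letter standard alphabet plus a free-text identifier. Any
#' other character (including B, J, O, U, X, Z) is rejected.
#'
#' @param x Either a single string or a character vector of one-letter codes.
#' @param id Identifier for the sequence.
#' @return An object of class `aa_sequence`: a character vector of residues
#'   with an `id` attribute.
#' @examples
#' aa_sequence("ACDEFG", id = "toy")
#' @export
aa_sequence <- function(x, id = "seq") {
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L)
    x <- strsplit(x, "")[[1]]
  x <- toupper(as.character(x))
  if (length(x) < 1L) stop("sequence must contain at least one residue")
  bad <- setdiff(unique(x), AA_ALPHABET)
  if (length(bad))
    stop("invalid residue code(s): ", paste(bad, collapse = ", "))
  structure(x, id = as.character(id)[1], class = "aa_sequence")
}

#' @export
print.aa_sequence <- function(x, ...) {
  cat("<aa_sequence> ", attr(x, "id"), " (", length(x), " aa)\n", sep = "")
  cat(paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

#' @export
as.character.aa_sequence <- function(x, ...) paste(unclass(x), collapse = "")

seq_id <- function(x) attr(x, "id")

#' Read a sequence from a FASTA file
#'
#' Reads single- or multi-record FASTA. By default the first record is used;
#' pass `id` to select a record by its header.
#'
#' @param path Path to a FASTA file.
#' @param id Optional record identifier to select.
#' @return An [aa_sequence].
#' @export
read_fasta <- function(path, id = NULL) {
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  ids <- rownames(fa$ali)
  pick <- if (is.null(id)) 1L else match(id, ids)
  if (is.na(pick)) stop("no FASTA record with id '", id, "'")
  res <- fa$ali[pick, ]
  res <- res[res != "-"]
  aa_sequence(res, id = ids[pick])
}

#' Random amino-acid sequence
#'
#' Draws a random sequence over the 20-letter alphabet. For lengths up to 20
#' the residues are drawn without replacement, so every k-mer of the sequence
#' is unique; fragment-library ranking by sequence identity then has a
#' strict maximum at the aligned offset, which the toy-problem generators
#' rely on.
#'
#' @param length Number of residues.
#' @param id Identifier.
#' @return An [aa_sequence].
#' @export
random_sequence <- function(length, id = "random") {
  stopifnot(length >= 1)
  res <- if (length <= 20L) sample(AA_ALPHABET, length)
         else sample(AA_ALPHABET, length, replace = TRUE)
  aa_sequence(res, id = id)
}
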