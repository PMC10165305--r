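AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")
AA1 <- setNames(names(AA3), AA3)

#' Read CA coordinates and sequence from a PDB file
#'
#' Extracts alpha-carbon coordinates from the first model and (by default)
#' the first chain of a PDB file, preferring altloc 'A' where alternates
#' exist. Residue numbering from the file is preserved as an attribute.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; `NULL` (default) takes the first chain.
#' @param missing_ca `"error"` (default) fails if a residue in the chain has
#'   no CA atom; `"skip"` drops such residues with a warning.
#' @return List with `xyz` (`n x 3` CA coordinates, Angstrom), `sequence`
#'   (an [aa_sequence]) and `resno` (original residue numbers).
#' @export
read_pdb_ca <- function(path, chain = NULL, missing_ca = c("error", "skip")) {
  missing_ca <- match.arg(missing_ca)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms for chain '", chain, "'")
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  resno <- unique(at$resno)
  keep_xyz <- matrix(NA_real_, length(resno), 3)
  res_code <- character(length(resno))
  has_ca <- logical(length(resno))
  for (i in seq_along(resno)) {
    rows <- at[at$resno == resno[i], , drop = FALSE]
    res_code[i] <- AA1[rows$resid[1]]
    ca <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(ca)) {
      has_ca[i] <- TRUE
      keep_xyz[i, ] <- as.numeric(ca[1, c("x", "y", "z")])
    }
  }
  if (any(!has_ca)) {
    if (missing_ca == "error")
      stop("residue(s) without CA atom: ",
           paste(resno[!has_ca], collapse = ", "))
    warning("skipping ", sum(!has_ca), " residue(s) without CA atom")
    keep_xyz <- keep_xyz[has_ca, , drop = FALSE]
    res_code <- res_code[has_ca]
    resno <- resno[has_ca]
  }
  if (anyNA(res_code)) stop("non-standard residue name in chain")
  list(xyz = keep_xyz, sequence = aa_sequence(res_code, id = basename(path)),
       resno = resno)
}

#' Read a backbone conformation (dihedrals) from a PDB file
#'
#' Measures phi/psi/omega from the backbone atoms of the first chain (or
#' `chain`) and returns a [conformation]. Terminal angles that are
#' undefined (phi of the first residue, psi of the last) default to 180.
#' Requires N, CA and C atoms; CA-only traces cannot be converted.
#'
#' @inheritParams read_pdb_ca
#' @return A [conformation].
#' @export
read_pdb_conformation <- function(path, chain = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file: ",
                                           conditionMessage(e)))
  if (is.null(chain)) chain <- pdb$atom$chain[pdb$atom$type == "ATOM"][1]
  sel <- bio3d::atom.select(pdb, chain = chain, verbose = FALSE)
  pdb <- bio3d::trim.pdb(pdb, sel)
  tor <- bio3d::torsion.pdb(pdb)
  res <- pdb$atom[pdb$atom$elety == "CA", "resid"]
  L <- length(res)
  phi <- tor$phi; psi <- tor$psi; omg <- tor$omega
  if (length(phi) != L) stop("incomplete backbone in ", path)
  # our convention stores the omega that places residue i (i >= 2)
  omega <- c(180, omg[seq_len(L - 1)])
  phi[is.na(phi)] <- 180
  psi[is.na(psi)] <- 180
  omega[is.na(omega)] <- 180
  conformation(aa_sequence(AA1[res], id = basename(path)),
               cbind(omega = wrap_angle(omega), phi = wrap_angle(phi),
                     psi = wrap_angle(psi)))
}

#' Write a coarse-grained structure as a PDB file
#'
#' Emits standard fixed-width ATOM records (8.3 coordinates), one residue
#' per 5 atoms (N, CA, C, O and the CEN pseudo-atom), residues numbered from
#' 1, chain A. Files are re-readable by [read_pdb_ca()] and by standard
#' structure viewers.
#'
#' @param s A `structure3d` from [build_backbone()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "structure3d"))
  L <- nres(s)
  elety <- rep(c("N", "CA", "C", "O", "CEN"), L)
  elesy <- rep(c("N", "C", "C", "O", "C"), L)
  resno <- rep(seq_len(L), each = 5)
  resid <- rep(AA3[as.character(unclass(s$sequence))], each = 5)
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = as.numeric(t(s$coords)),
                     resno = resno, resid = resid, eleno = seq_len(5 * L),
                     elety = elety, chain = rep("A", 5 * L), elesy = elesy)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write PDB file at ", path)
  invisible(path)
}
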