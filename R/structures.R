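#' @useDynLib rnaenm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RNA_BASES <- c("A", "C", "G", "U")

new_rna_structure <- function(atoms, xyz, source = "") {
  stopifnot(is.data.frame(atoms), is.list(xyz), length(xyz) >= 1L)
  for (m in xyz) stopifnot(is.matrix(m), nrow(m) == nrow(atoms), ncol(m) == 3L)
  structure(list(atoms = atoms, xyz = xyz, source = source),
            class = "rna_structure")
}

#' Number of models and residues of an RNA structure
#' @param x an `rna_structure`
#' @param ... ignored
#' @export
print.rna_structure <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("RNA structure '%s': %d model(s), %d residue(s), %d atoms\n",
              x$source, length(x$xyz), nrow(res), nrow(x$atoms)))
  cat("sequence:", paste(res$base, collapse = ""), "\n")
  invisible(x)
}

#' @export
dim.rna_structure <- function(x) c(length(x$xyz), nrow(x$atoms))

# One row per residue in file order, with atom index ranges.
residue_table <- function(x) {
  a <- x$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  idx <- !duplicated(key)
  data.frame(chain = a$chain[idx], resno = a$resno[idx], icode = a$icode[idx],
             base = a$base[idx],
             first = which(idx),
             last = c(which(idx)[-1L] - 1L, nrow(a)),
             stringsAsFactors = FALSE)
}

rna_sequence <- function(x) paste(residue_table(x)$base, collapse = "")

# Residues whose names indicate DNA or solvent/ions: silently skippable.
NON_RNA_RESID <- c("DA", "DC", "DG", "DT", "DU", "HOH", "WAT", "MG", "NA",
                   "K", "CL", "ZN", "MN", "CA", "SO4", "PO4", "GOL", "SPM")

#' Read an RNA structure from a PDB file
#'
#' Parses ATOM records of the four standard ribonucleotides.  Alternate
#' locations are resolved by keeping the highest-occupancy altloc (ties
#' resolved by file order); HETATM records and non-RNA residues are skipped
#' with a warning.  Residues that look like modified ribonucleotides (they
#' carry a ribose but a non-standard residue name) raise an error and must be
#' replaced by their standard analog before analysis.
#'
#' @param path path to a PDB file
#' @param model_policy `"all"` keeps every MODEL as one conformation of the
#'   returned ensemble; `"first"` keeps only the first.
#' @return an object of class `rna_structure` with fields `atoms`
#'   (data frame: chain, resno, icode, base, name, element, bfactor,
#'   occupancy) and `xyz` (list of natoms x 3 coordinate matrices, one per
#'   model).
#' @export
read_rna_pdb <- function(path, model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error for '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM records in '", path, "'")
  nmodel <- nrow(pdb$xyz)
  keep_type <- at$type == "ATOM"
  if (any(!keep_type))
    warning(sum(!keep_type), " HETATM record(s) skipped")
  resid <- trimws(at$resid)
  is_std <- resid %in% RNA_BASES
  # modified ribonucleotide: has a ribose O2'/C1' but nonstandard name
  elety <- trimws(at$elety)
  reskey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  ribose_res <- unique(reskey[elety %in% c("O2'", "O2*")])
  modres <- keep_type & !is_std & (reskey %in% ribose_res) &
    !(resid %in% NON_RNA_RESID)
  if (any(modres)) {
    bad <- unique(resid[modres])
    stop("modified ribonucleotide(s) present (", paste(bad, collapse = ", "),
         "); replace them with their standard analog before reading")
  }
  if (any(keep_type & !is_std))
    warning("skipped non-RNA residue(s): ",
            paste(unique(resid[keep_type & !is_std]), collapse = ", "))
  keep <- keep_type & is_std
  if (!any(keep)) stop("no standard ribonucleotide ATOM records in '",
                       path, "'")
  at <- at[keep, , drop = FALSE]
  xyz_all <- pdb$xyz[, , drop = FALSE]
  col_idx <- as.numeric(t(outer(which(keep), 1:3,
                                function(i, k) 3 * (i - 1) + k)))
  xyz_all <- xyz_all[, col_idx, drop = FALSE]
  # altloc resolution: within a residue, keep for each atom name the record
  # with the highest occupancy (first on ties)
  elety <- trimws(at$elety)
  elety <- gsub("\\*", "'", elety)         # old-style primes
  reskey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  akey <- paste(reskey, elety, sep = "\r")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(factor(akey, levels = unique(akey)), -occ,
               seq_len(nrow(at)))
  first_of <- ord[!duplicated(akey[ord])]
  sel <- sort(first_of)
  at <- at[sel, , drop = FALSE]
  elety <- elety[sel]
  nat <- nrow(at)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    base = trimws(at$resid),
    name = elety,
    element = guess_element(elety, at$elesy),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    occupancy = occ[sel],
    stringsAsFactors = FALSE)
  models <- if (model_policy == "first") 1L else seq_len(nmodel)
  xyz <- lapply(models, function(m) {
    v <- xyz_all[m, ]
    mm <- matrix(v, ncol = 3L, byrow = TRUE)[sel, , drop = FALSE]
    if (any(!is.finite(mm)))
      stop("ensemble-consistency error: model ", m,
           " lacks coordinates for atoms present in model 1")
    mm
  })
  new_rna_structure(atoms, xyz, source = basename(path))
}

guess_element <- function(name, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- trimws(elesy)
    ok <- !is.na(e) & e != ""
    if (all(ok)) return(toupper(e))
  } else ok <- rep(FALSE, length(name))
  e <- if (is.null(elesy)) rep(NA_character_, length(name)) else toupper(trimws(elesy))
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", gsub("'", "", name)), 1L, 1L))
  ifelse(ok, e, guess)
}

#' Write an RNA structure to a PDB file
#'
#' Multi-model structures are written with MODEL/ENDMDL records.  A per-atom
#' or per-bead scalar can be stamped into the B-factor column, e.g. to map
#' fluctuation profiles or regression coefficients onto the structure.
#'
#' @param x an `rna_structure`
#' @param path output file
#' @param bfactor optional replacement B-factor vector: either one value per
#'   atom, or one value per bead of `beads` (stamped onto each bead's member
#'   atoms)
#' @param beads optional `coarse_model` used to expand a per-bead `bfactor`
#' @export
write_rna_pdb <- function(x, path, bfactor = NULL, beads = NULL) {
  stopifnot(inherits(x, "rna_structure"))
  b <- x$atoms$bfactor
  if (!is.null(bfactor)) {
    if (!is.null(beads)) {
      stopifnot(length(bfactor) == nrow(beads$beads))
      b <- rep(0, nrow(x$atoms))
      for (k in seq_along(beads$members)) b[beads$members[[k]]] <- bfactor[k]
    } else {
      stopifnot(length(bfactor) == nrow(x$atoms))
      b <- bfactor
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x$xyz) > 1L
  a <- x$atoms
  for (m in seq_along(x$xyz)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- x$xyz[[m]]
    prev_chain <- a$chain[1L]
    serial <- 0L
    for (i in seq_len(nrow(a))) {
      if (a$chain[i] != prev_chain) {
        writeLines("TER", con)
        prev_chain <- a$chain[i]
      }
      serial <- serial + 1L
      nm <- a$name[i]
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm_fmt, a$base[i], a$chain[i], a$resno[i],
        ifelse(a$icode[i] == "", " ", a$icode[i]),
        xyz[i, 1L], xyz[i, 2L], xyz[i, 3L],
        min(a$occupancy[i], 999), max(-99, min(b[i], 999)),
        a$element[i]), con)
    }
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
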