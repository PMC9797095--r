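# Deterministic generators of idealized all-atom RNA structures and
# synthetic benchmark datasets.  Every generator is a pure function of its
# arguments (plus an explicit seed where randomness is involved), so fixtures
# are reproducible without any external download.

WC_PAIR <- c(A = "U", U = "A", G = "C", C = "G")

# canonical PDB atom order within a residue
ATOM_ORDER <- c("P", "OP1", "OP2", "OP3", "O5'", "C5'", "C4'", "O4'", "C3'",
                "O3'", "C2'", "O2'", "C1'",
                "N9", "C8", "N7", "C5", "C6", "O6", "N6", "N1", "C2", "N2",
                "O2", "N3", "C4", "N4", "O4")

aform_template <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "aform_template.csv", package = "rnaenm")
      tpl <- utils::read.csv(path, stringsAsFactors = FALSE)
      par <- tpl[tpl$base == "PARAM", ]
      tpl <- tpl[tpl$base != "PARAM", ]
      lst <- lapply(split(tpl, tpl$base), function(d) {
        ord <- order(match(d$name, ATOM_ORDER))
        d <- d[ord, ]
        m <- as.matrix(d[, c("x", "y", "z")])
        rownames(m) <- d$name
        attr(m, "element") <- d$element
        m
      })
      cache <<- list(bases = lst,
                     twist = par$x[par$name == "twist"] * pi / 180,
                     rise = par$x[par$name == "rise"])
    }
    cache
  }
})

check_sequence <- function(s) {
  v <- strsplit(toupper(s), "")[[1L]]
  if (length(v) == 0L || !all(v %in% RNA_BASES))
    stop("invalid RNA sequence: ", s)
  v
}

revcomp <- function(s) paste(rev(WC_PAIR[check_sequence(s)]), collapse = "")

helix_step <- function(m, i, twist, rise) {
  g <- m %*% t(rot_z(twist * i))
  g[, 3L] <- g[, 3L] + rise * i
  g
}

dyad_flip <- function(m) {
  m[, 2L] <- -m[, 2L]
  m[, 3L] <- -m[, 3L]
  m
}

residue_block <- function(base, coords, chain, resno, drop_p = FALSE) {
  tplm <- aform_template()$bases[[base]]
  nm <- rownames(tplm)
  keep <- if (drop_p) !(nm %in% c("P", "OP1", "OP2")) else rep(TRUE, length(nm))
  list(atoms = data.frame(
         chain = chain, resno = resno, icode = "", base = base,
         name = nm[keep], element = attr(tplm, "element")[keep],
         bfactor = 0, occupancy = 1, stringsAsFactors = FALSE),
       xyz = coords[keep, , drop = FALSE])
}

#' Build an idealized A-form RNA helix
#'
#' Places rigid all-atom nucleotide templates by helical symmetry (twist
#' 32.7 degrees, rise 2.81 Angstrom per step).  With `duplex = TRUE` a second
#' antiparallel strand is generated by the base-pair dyad so that
#' Watson-Crick partners form proper hydrogen-bond geometry; `complement`
#' may override individual partner bases to plant mismatches.
#'
#' @param sequence 5'->3' sequence of the first strand
#' @param duplex build the complementary strand (chain B)?
#' @param complement sequence of the second strand, 5'->3'; defaults to the
#'   reverse complement of `sequence`
#' @return an `rna_structure` with one model and all residues complete
#'   (every residue carries its 5' phosphate)
#' @export
build_aform <- function(sequence, duplex = FALSE, complement = NULL) {
  seq1 <- check_sequence(sequence)
  tpl <- aform_template()
  blocks <- list()
  for (i in seq_along(seq1)) {
    crd <- helix_step(tpl$bases[[seq1[i]]], i - 1L, tpl$twist, tpl$rise)
    blocks[[length(blocks) + 1L]] <- residue_block(seq1[i], crd, "A", i)
  }
  if (duplex) {
    if (is.null(complement)) complement <- revcomp(sequence)
    seq2 <- check_sequence(complement)
    if (length(seq2) != length(seq1))
      stop("complement length must match sequence length")
    for (j in seq_along(seq2)) {
      i <- length(seq1) - j + 1L            # pair index on strand 1
      crd <- helix_step(dyad_flip(tpl$bases[[seq2[j]]]), i - 1L,
                        tpl$twist, tpl$rise)
      blocks[[length(blocks) + 1L]] <- residue_block(seq2[j], crd, "B", j)
    }
  }
  atoms <- do.call(rbind, lapply(blocks, `[[`, "atoms"))
  xyz <- do.call(rbind, lapply(blocks, `[[`, "xyz"))
  rownames(xyz) <- NULL
  new_rna_structure(atoms, list(xyz),
                    source = paste0("aform:", sequence,
                                    if (duplex) paste0("/", complement)))
}

rodrigues <- function(axis, theta) {
  a <- unit(axis)
  k <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
  diag(3L) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
}

#' Build an idealized RNA hairpin
#'
#' The stem is an A-form duplex folded into a single chain; loop residues are
#' placed on a smooth arc interpolating between the two stem ends (screw
#' interpolation of the residue frames with an outward bulge).  Loop geometry
#' is idealized for completeness, not thermodynamic realism; where the
#' backbone O3'-P distance at the loop junctions exceeds the bonding
#' threshold, the bonded bead topology is simply severed there.
#'
#' @param stem5 5' strand of the stem, 5'->3'
#' @param loop loop sequence
#' @param stem3 3' strand of the stem; defaults to the reverse complement of
#'   `stem5`
#' @return an `rna_structure`, single chain of
#'   `nchar(stem5) + nchar(loop) + nchar(stem3)` residues
#' @export
build_hairpin <- function(stem5, loop, stem3 = NULL) {
  s5 <- check_sequence(stem5)
  sl <- check_sequence(loop)
  if (is.null(stem3)) stem3 <- revcomp(stem5)
  s3 <- check_sequence(stem3)
  if (length(s3) != length(s5)) stop("stem strands must have equal length")
  tpl <- aform_template()
  n <- length(s5)
  blocks <- list()
  resno <- 0L
  for (i in seq_len(n)) {
    resno <- resno + 1L
    crd <- helix_step(tpl$bases[[s5[i]]], i - 1L, tpl$twist, tpl$rise)
    blocks[[length(blocks) + 1L]] <- residue_block(s5[i], crd, "A", resno)
  }
  # loop: screw interpolation between the placement of strand-1 step n-1 and
  # the dyad placement at the same step, with an outward bulge along +z
  axis <- as.numeric(rot_z(tpl$twist * (n - 1L)) %*% c(1, 0, 0))
  pivot <- c(0, 0, tpl$rise * (n - 1L))
  bulge <- min(8, 2.2 + 0.9 * length(sl))
  for (k in seq_along(sl)) {
    f <- k / (length(sl) + 1L)
    base0 <- helix_step(tpl$bases[[sl[k]]], n - 1L, tpl$twist, tpl$rise)
    base0[, 3L] <- base0[, 3L] + sin(pi * f) * bulge
    rot <- rodrigues(axis, pi * f)
    crd <- sweep(sweep(base0, 2L, pivot) %*% t(rot), 2L, pivot, "+")
    resno <- resno + 1L
    blocks[[length(blocks) + 1L]] <- residue_block(sl[k], crd, "A", resno)
  }
  for (j in seq_along(s3)) {
    i <- n - j + 1L
    crd <- helix_step(dyad_flip(tpl$bases[[s3[j]]]), i - 1L,
                      tpl$twist, tpl$rise)
    resno <- resno + 1L
    blocks[[length(blocks) + 1L]] <- residue_block(s3[j], crd, "A", resno)
  }
  atoms <- do.call(rbind, lapply(blocks, `[[`, "atoms"))
  xyz <- do.call(rbind, lapply(blocks, `[[`, "xyz"))
  rownames(xyz) <- NULL
  new_rna_structure(atoms, list(xyz),
                    source = paste0("hairpin:", stem5, "-", loop))
}

#' Mutate a base in place
#'
#' Replaces the base atoms of one residue by an idealized base aligned on the
#' glycosidic frame (glycosidic nitrogen, C1' direction and base plane);
#' backbone and sugar atoms are untouched, bit for bit.  Mutating a base to
#' itself returns the structure unchanged.
#'
#' @param x an `rna_structure`
#' @param residue residue index (order of appearance)
#' @param new_base one of A, C, G, U
#' @param pin_bead if `TRUE`, the new base is additionally translated so that
#'   its C2 atom lands exactly on the old C2 position, keeping all bead
#'   centers bitwise identical across variants (useful for isolating the
#'   sequence sensitivity of a model from bead-geometry changes)
#' @export
mutate_base <- function(x, residue, new_base, pin_bead = FALSE) {
  stopifnot(inherits(x, "rna_structure"), new_base %in% RNA_BASES)
  res <- residue_table(x)
  if (residue < 1L || residue > nrow(res)) stop("no such residue: ", residue)
  old_base <- res$base[residue]
  if (old_base == new_base) return(x)
  rows <- res$first[residue]:res$last[residue]
  nm <- x$atoms$name[rows]
  glyN_old <- if (old_base %in% c("A", "G")) "N9" else "N1"
  ref_old <- if (old_base %in% c("A", "G")) "C4" else "C2"
  need <- c("C1'", glyN_old, ref_old)
  if (!all(need %in% nm))
    stop("mutagenesis error: residue ", residue, " lacks frame atoms ",
         paste(setdiff(need, nm), collapse = ","))
  base_rows <- rows[!(nm %in% c(P_GROUP, S_GROUP))]
  keep_rows <- setdiff(seq_len(nrow(x$atoms)), base_rows)
  tpl <- aform_template()$bases[[new_base]]
  tnm <- rownames(tpl)
  tkeep <- !(tnm %in% c(P_GROUP, S_GROUP))
  glyN_new <- if (new_base %in% c("A", "G")) "N9" else "N1"
  ref_new <- if (new_base %in% c("A", "G")) "C4" else "C2"
  frame_of <- function(orig, xaxis_to, plane) {
    xax <- unit(xaxis_to - orig)
    zax <- unit(cross3(xax, plane - orig))
    cbind(xax, cross3(zax, xax), zax)
  }
  new_xyz <- vector("list", length(x$xyz))
  for (m in seq_along(x$xyz)) {
    xyz <- x$xyz[[m]]
    at <- function(n) xyz[rows[match(n, nm)], ]
    f_old <- frame_of(at(glyN_old), at("C1'"), at(ref_old))
    tat <- function(n) tpl[n, ]
    f_new <- frame_of(tat(glyN_new), tpl["C1'", ], tat(ref_new))
    rot <- f_old %*% t(f_new)
    placed <- sweep(tpl[tkeep, , drop = FALSE], 2L, tat(glyN_new)) %*% t(rot)
    placed <- sweep(placed, 2L, at(glyN_old), "+")
    rownames(placed) <- tnm[tkeep]
    if (pin_bead && "C2" %in% nm && "C2" %in% rownames(placed)) {
      shift <- at("C2") - placed["C2", ]
      placed <- sweep(placed, 2L, shift, "+")
    }
    new_xyz[[m]] <- placed
  }
  # assemble: replace the base rows (keep residue-internal ordering: backbone
  # first as emitted, then base atoms appended at the residue's end)
  bb_rows <- rows[nm %in% c(P_GROUP, S_GROUP)]
  before <- seq_len(nrow(x$atoms)) < min(rows)
  after <- seq_len(nrow(x$atoms)) > max(rows)
  tpl_elem <- attr(tpl, "element")[tkeep]
  res_atoms <- rbind(
    x$atoms[bb_rows, , drop = FALSE],
    data.frame(chain = res$chain[residue], resno = res$resno[residue],
               icode = res$icode[residue], base = new_base,
               name = tnm[tkeep], element = tpl_elem, bfactor = 0,
               occupancy = 1, stringsAsFactors = FALSE))
  res_atoms$base <- new_base
  atoms <- rbind(x$atoms[before, , drop = FALSE], res_atoms,
                 x$atoms[after, , drop = FALSE])
  rownames(atoms) <- NULL
  xyz_out <- lapply(seq_along(x$xyz), function(m) {
    old <- x$xyz[[m]]
    out <- rbind(old[before, , drop = FALSE], old[bb_rows, , drop = FALSE],
                 new_xyz[[m]], old[after, , drop = FALSE])
    rownames(out) <- NULL
    out
  })
  new_rna_structure(atoms, xyz_out, source = x$source)
}

#' Generate a synthetic conformational ensemble along chosen modes
#'
#' Conformations are the reference bead coordinates displaced along the given
#' mode vectors with per-conformation random coefficients, optionally wrapped
#' in random rigid-body transforms.  Used as ground-truth fixtures for
#' ensemble-variance analyses.
#'
#' @param cm a `coarse_model` providing the reference bead coordinates
#' @param mode_vectors 3N x k matrix of displacement directions
#' @param amplitudes length-k standard deviations of the random coefficients
#' @param n_conf number of conformations (>= 2)
#' @param seed integer seed
#' @param rigid_noise apply a random rotation + translation to each
#'   conformation after the first?  The first conformation stays in the
#'   reference frame (it defines the frame of any ensemble analysis, so
#'   keeping it fixed leaves recovered components comparable to the input
#'   mode vectors).
#' @return a `bead_ensemble`: list of n x 3 coordinate matrices plus the
#'   reference model
#' @export
make_ensemble <- function(cm, mode_vectors, amplitudes, n_conf = 10L,
                          seed = 1L, rigid_noise = FALSE) {
  stopifnot(inherits(cm, "coarse_model"), n_conf >= 2L)
  mode_vectors <- as.matrix(mode_vectors)
  if (nrow(mode_vectors) != 3L * cm$n)
    stop("mode/model layout mismatch: expected ", 3L * cm$n, " rows")
  if (length(amplitudes) != ncol(mode_vectors))
    stop("one amplitude per mode vector required")
  set.seed(seed)
  ref <- cm$coords
  confs <- vector("list", n_conf)
  for (c in seq_len(n_conf)) {
    coef <- stats::rnorm(length(amplitudes)) * amplitudes
    disp <- matrix(as.numeric(mode_vectors %*% coef), ncol = 3L, byrow = TRUE)
    xx <- ref + disp
    if (rigid_noise && c > 1L)
      xx <- apply_rigid(xx, random_rotation(), stats::rnorm(3L, sd = 5))
    confs[[c]] <- xx
  }
  structure(list(coords = confs, model = cm), class = "bead_ensemble")
}
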