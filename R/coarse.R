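# Coarse-graining: three beads per nucleotide (phosphate, sugar, base)
# positioned on the P, C1' and C2 atoms, or a one-bead-per-nucleotide
# phosphate-only scheme for comparison experiments.

P_GROUP <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P", "O5'")
S_GROUP <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'", "O3'")

#' Coarse-grain an RNA structure into beads
#'
#' Assigns one bead per chemical group of each nucleotide: the phosphate
#' group (centered on P), the sugar (centered on C1') and the base (centered
#' on C2).  Atoms partition across the beads of their residue: phosphate
#' atoms and the O5' linker go to the P bead, ribose atoms including O2' and
#' O3' to the sugar bead, and all remaining atoms to the base bead.  A bead
#' is created only when its center atom is present, so a 5'-terminal residue
#' without a phosphate yields two beads.  Bonded topology (bonds, angles,
#' dihedrals along the covalent bead graph) is built at the same time.
#'
#' @param x an `rna_structure`
#' @param model index of the conformation used for bead coordinates
#' @param scheme `"psb"` for the three-bead scheme, `"p"` for phosphate-only
#'   beads (whole residue mapped onto one bead at P)
#' @return an object of class `coarse_model`: `beads` (data frame with chain,
#'   resno, base, role, residue index and center-atom index), `coords`
#'   (n x 3), `members` (list of atom-index vectors), `bonds`, `angles`,
#'   `dihedrals` (index matrices), and the source structure/model.
#' @export
coarse_grain <- function(x, model = 1L, scheme = c("psb", "p")) {
  stopifnot(inherits(x, "rna_structure"))
  scheme <- match.arg(scheme)
  res <- residue_table(x)
  a <- x$atoms
  xyz <- x$xyz[[model]]
  members <- list()
  b_res <- integer(); b_role <- character(); b_center <- integer()
  cen <- c(P = "P", S = "C1'", B = "C2")
  roles <- if (scheme == "psb") c("P", "S", "B") else "P"
  for (r in seq_len(nrow(res))) {
    rows <- res$first[r]:res$last[r]
    nm <- a$name[rows]
    if (!res$base[r] %in% RNA_BASES)
      stop("non-standard residue ", res$base[r], " at ", res$chain[r],
           res$resno[r])
    if (scheme == "psb" && !all(c("C1'", "C2") %in% nm))
      stop("incomplete residue ", res$chain[r], res$resno[r], res$base[r],
           ": missing ", paste(setdiff(c("C1'", "C2"), nm), collapse = ","))
    for (role in roles) {
      ci <- rows[match(cen[[role]], nm)]
      if (is.na(ci)) next               # e.g. 5'-terminal residue without P
      mem <- if (scheme == "p") rows else switch(role,
        P = rows[nm %in% P_GROUP],
        S = rows[nm %in% S_GROUP],
        B = rows[!(nm %in% c(P_GROUP, S_GROUP))])
      members[[length(members) + 1L]] <- mem
      b_res <- c(b_res, r); b_role <- c(b_role, role)
      b_center <- c(b_center, ci)
    }
  }
  centers <- b_center
  beads <- data.frame(
    chain = res$chain[b_res], resno = res$resno[b_res],
    icode = res$icode[b_res], base = res$base[b_res], role = b_role,
    residue_index = b_res, center = b_center, stringsAsFactors = FALSE)
  cm <- structure(list(
    beads = beads, coords = xyz[centers, , drop = FALSE],
    members = members, n = nrow(beads),
    structure = x, model = model, scheme = scheme), class = "coarse_model")
  build_topology(cm)
}

#' @export
print.coarse_model <- function(x, ...) {
  cat(sprintf("coarse model: %d beads (%s scheme), %d bonds, %d angles, %d dihedrals\n",
              x$n, x$scheme, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  invisible(x)
}

# Is residue r2 covalently downstream of r1 in the same chain?
residues_linked <- function(x, model, res, r1, r2) {
  if (res$chain[r1] != res$chain[r2]) return(FALSE)
  dseq <- res$resno[r2] - res$resno[r1]
  if (!(dseq %in% c(0L, 1L))) return(FALSE)
  if (dseq == 0L && res$icode[r2] == res$icode[r1]) return(FALSE)
  a <- x$atoms; xyz <- x$xyz[[model]]
  o3 <- res$first[r1]:res$last[r1]
  o3 <- o3[a$name[o3] == "O3'"]
  p <- res$first[r2]:res$last[r2]
  p <- p[a$name[p] == "P"]
  if (length(o3) == 1L && length(p) == 1L)
    return(sqrt(sum((xyz[o3, ] - xyz[p, ])^2)) < 2.5)
  TRUE                                   # atoms absent: trust numbering
}

#' Rebuild the bonded bead topology of a coarse model
#'
#' Bonds connect the P and S beads of a residue, the S and B beads of a
#' residue, and the S bead of residue i to the P bead of residue i+1 within
#' one chain (consecutive numbering and, when both atoms are present, an
#' O3'-P distance below 2.5 Angstrom).  Angles are all simple 3-bead paths
#' along bonds and dihedrals all simple 4-bead paths, deduplicated under
#' reversal.
#'
#' @param cm a `coarse_model`
#' @export
build_topology <- function(cm) {
  n <- cm$n
  b <- cm$beads
  edges <- NULL
  if (n > 0L) {
    res <- residue_table(cm$structure)
    for (r in unique(b$residue_index)) {
      ip <- which(b$residue_index == r & b$role == "P")
      is <- which(b$residue_index == r & b$role == "S")
      ib <- which(b$residue_index == r & b$role == "B")
      if (length(ip) && length(is)) edges <- rbind(edges, c(ip, is))
      if (length(is) && length(ib)) edges <- rbind(edges, c(is, ib))
    }
    rs <- sort(unique(b$residue_index))
    for (k in seq_along(rs)[-1L]) {
      r1 <- rs[k - 1L]; r2 <- rs[k]
      if (!residues_linked(cm$structure, cm$model, res, r1, r2)) next
      if (cm$scheme == "p") {
        i1 <- which(b$residue_index == r1 & b$role == "P")
        i2 <- which(b$residue_index == r2 & b$role == "P")
      } else {
        i1 <- which(b$residue_index == r1 & b$role == "S")
        i2 <- which(b$residue_index == r2 & b$role == "P")
      }
      if (length(i1) && length(i2)) edges <- rbind(edges, c(i1, i2))
    }
  }
  if (is.null(edges)) edges <- matrix(integer(), 0L, 2L)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1L]]] <- c(adj[[edges[i, 1L]]], edges[i, 2L])
    adj[[edges[i, 2L]]] <- c(adj[[edges[i, 2L]]], edges[i, 1L])
  }
  angles <- NULL
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    cmb <- utils::combn(sort(nb), 2L)
    angles <- rbind(angles, t(rbind(cmb[1L, ], j, cmb[2L, ])))
  }
  if (is.null(angles)) angles <- matrix(integer(), 0L, 3L)
  dihedrals <- NULL
  for (e in seq_len(nrow(edges))) {
    j <- edges[e, 1L]; k <- edges[e, 2L]
    for (i in adj[[j]]) for (l in adj[[k]]) {
      if (i == k || l == j || i == l) next
      quad <- c(i, j, k, l)
      if (quad[1L] > quad[4L] ||
          (quad[1L] == quad[4L] && quad[2L] > quad[3L]))
        quad <- rev(quad)
      dihedrals <- rbind(dihedrals, quad)
    }
  }
  if (is.null(dihedrals)) dihedrals <- matrix(integer(), 0L, 4L)
  else dihedrals <- unique(dihedrals)
  rownames(dihedrals) <- NULL
  cm$bonds <- edges
  cm$angles <- angles
  cm$dihedrals <- dihedrals
  cm
}

# Pairwise shortest bond-graph distances up to 3 (4 = farther/no path).
graph_distance_le3 <- function(n, edges) {
  d <- matrix(4L, n, n)
  diag(d) <- 0L
  a <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    a[edges] <- TRUE
    a[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  d[a & d > 1L] <- 1L
  a2 <- (a %*% a) > 0
  d[a2 & d > 2L] <- 2L
  a3 <- (a2 %*% a) > 0
  d[a3 & d > 3L] <- 3L
  d
}
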