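# Atom typing, interaction weights and the surface-in-contact modulation
# term beta_ij of the sequence-sensitive elastic network.

SOBOLEV_CLASSES <- c("hydrophilic", "acceptor", "donor", "hydrophobic",
                     "aromatic", "neutral", "neutral_donor",
                     "neutral_acceptor")

WATER_RADIUS <- 1.4

#' Atom type table for the four standard ribonucleotides
#'
#' Maps each heavy atom of A, C, G and U to one of eight interaction classes
#' (hydrophilic, acceptor, donor, hydrophobic, aromatic, neutral,
#' neutral-donor, neutral-acceptor) and carries element-wise van der Waals
#' radii.  The packaged defaults can be replaced by a user-edited CSV with
#' columns `base` (`*` for backbone atoms shared by all bases), `name`, and
#' `type`.
#'
#' @param path optional CSV overriding the packaged table
#' @param radii_path optional CSV (`element`, `radius`) overriding the
#'   packaged van der Waals radii
#' @return an `atom_type_table` with `$types` and `$radii`
#' @export
atom_types <- function(path = NULL, radii_path = NULL) {
  default <- is.null(path) && is.null(radii_path)
  if (default && !is.null(.rnaenm_cache$atom_types))
    return(.rnaenm_cache$atom_types)
  if (is.null(path))
    path <- system.file("extdata", "atom_types.csv", package = "rnaenm")
  if (is.null(radii_path))
    radii_path <- system.file("extdata", "vdw_radii.csv", package = "rnaenm")
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(tt$type %in% SOBOLEV_CLASSES))
    stop("unknown atom type class: ",
         paste(setdiff(tt$type, SOBOLEV_CLASSES), collapse = ", "))
  rr <- utils::read.csv(radii_path, stringsAsFactors = FALSE)
  if (any(rr$radius <= 0)) stop("van der Waals radii must be positive")
  out <- structure(list(types = tt,
                        radii = stats::setNames(rr$radius, rr$element)),
                   class = "atom_type_table")
  if (default) .rnaenm_cache$atom_types <- out
  out
}

.rnaenm_cache <- new.env(parent = emptyenv())

#' Pairwise interaction weight matrix of the eight atom classes
#'
#' Interactions between atom classes are binary: favorable (weight 3) or
#' unfavorable (weight 1).  The matrix is symmetric and editable via CSV.
#'
#' @param path optional CSV override (8 x 8 table of `F`/`U` flags)
#' @param favorable,unfavorable numeric weights of the two interaction kinds
#' @return symmetric 8 x 8 numeric matrix with class labels
#' @export
interaction_matrix <- function(path = NULL, favorable = 3, unfavorable = 1) {
  key <- if (is.null(path)) paste0("im", favorable, "_", unfavorable)
         else NULL
  if (!is.null(key) && !is.null(.rnaenm_cache[[key]]))
    return(.rnaenm_cache[[key]])
  if (is.null(path))
    path <- system.file("extdata", "interaction_matrix.csv",
                        package = "rnaenm")
  m <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       colClasses = "character")
  rn <- m$type
  m <- as.matrix(m[, -1L])
  rownames(m) <- rn
  if (!identical(sort(rn), sort(colnames(m))) || !identical(m, t(m)))
    stop("interaction matrix must be symmetric with matching labels")
  out <- ifelse(m == "F", favorable, unfavorable)
  mode(out) <- "numeric"
  out <- out[SOBOLEV_CLASSES, SOBOLEV_CLASSES]
  if (!is.null(key)) .rnaenm_cache[[key]] <- out
  out
}

# type index (1..8) per atom of a structure; errors on untyped atoms
type_atoms <- function(atoms, types) {
  tt <- types$types
  key_spec <- paste(tt$base, tt$name)
  idx <- match(paste(atoms$base, atoms$name), key_spec)
  bb <- match(paste("*", atoms$name), key_spec)
  idx[is.na(idx)] <- bb[is.na(idx)]
  if (any(is.na(idx))) {
    bad <- unique(paste0(atoms$base, ":", atoms$name)[is.na(idx)])
    stop("no atom type for ", paste(bad, collapse = ", "))
  }
  match(tt$type[idx], SOBOLEV_CLASSES)
}

#' Extended-radius surface areas in contact between atoms
#'
#' Computes, for every atom pair, the area of the face shared by the two
#' atoms' additively-weighted Voronoi cells, each cell constrained to the
#' atom's extended sphere (van der Waals radius plus a 1.4 Angstrom water
#' probe).  All proximal atoms occlude the shared face, so two atoms can be
#' in contact directly or through a solvent-sized gap, but never through a
#' third atom.
#'
#' @param coords n x 3 coordinate matrix (Angstrom)
#' @param elements length-n element symbols
#' @param types an `atom_type_table` (for the radii)
#' @return a `contact_areas` object: data frame of `i`, `j` (1-based atom
#'   indices, i < j) and `area` (Angstrom^2)
#' @export
surface_in_contact <- function(coords, elements, types = atom_types()) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L,
            all(is.finite(coords)))
  r <- types$radii[toupper(elements)]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  res <- contact_areas_cpp(coords, as.numeric(r) + WATER_RADIUS)
  structure(data.frame(i = res$i, j = res$j, area = res$area),
            class = c("contact_areas", "data.frame"))
}

#' Surface-in-contact interaction term between bead pairs
#'
#' For every pair of beads (i, j), sums the type-weighted atomic contact
#' areas over the member atoms of the two beads:
#' beta_ij = sum_k sum_l eps(T(k), T(l)) * S_kl.  Favorable atomic contacts
#' (weight 3) between e.g. donor and acceptor atoms make the modulated
#' long-range spring stiffer than unfavorable ones (weight 1), which is what
#' lets the model feel base identity: a G.C pair buries more favorably
#' interacting surface than an A.U pair.
#'
#' @param cm a `coarse_model`
#' @param areas `contact_areas` computed over the full atom set of the
#'   model's structure (computed on demand when `NULL`)
#' @param types an `atom_type_table`
#' @param eps 8 x 8 interaction weight matrix
#' @return symmetric n x n matrix of nonnegative modulation weights
#' @export
beta_matrix <- function(cm, areas = NULL, types = atom_types(),
                        eps = interaction_matrix()) {
  stopifnot(inherits(cm, "coarse_model"))
  atoms <- cm$structure$atoms
  xyz <- cm$structure$xyz[[cm$model]]
  if (is.null(areas))
    areas <- surface_in_contact(xyz, atoms$element, types)
  tidx <- type_atoms(atoms, types)
  bead_of <- integer(nrow(atoms))
  for (k in seq_along(cm$members)) bead_of[cm$members[[k]]] <- k
  bi <- bead_of[areas$i]
  bj <- bead_of[areas$j]
  w <- eps[cbind(tidx[areas$i], tidx[areas$j])] * areas$area
  keep <- bi != 0L & bj != 0L & bi != bj
  beta <- matrix(0, cm$n, cm$n)
  if (any(keep)) {
    ii <- pmin(bi[keep], bj[keep])
    jj <- pmax(bi[keep], bj[keep])
    agg <- rowsum(w[keep], paste(ii, jj))
    ij <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
    beta[ij] <- agg[, 1L]
    beta[ij[, 2:1, drop = FALSE]] <- agg[, 1L]
  }
  beta
}
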