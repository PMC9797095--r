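# Comparing normal modes with observed conformational changes and with the
# variance apparent in structural ensembles.

#' Rigid-body superposition of two conformations
#'
#' Least-squares (reflection-guarded) superposition of the target bead
#' coordinates onto the start coordinates, returning the displacement vector
#' start -> superposed target and the RMSD over bead centers.
#'
#' @param start,target n x 3 coordinate matrices with identical bead layout
#' @return list with `rotation`, `translation`, `displacement` (length-3n
#'   vector, target minus start after superposition) and `rmsd`
#' @export
superimpose <- function(start, target) {
  start <- as.matrix(start); target <- as.matrix(target)
  fit <- kabsch(start, target)
  moved <- apply_rigid(target, fit$rotation, fit$translation)
  disp <- moved - start
  list(rotation = fit$rotation, translation = fit$translation,
       displacement = as.numeric(t(disp)),
       rmsd = sqrt(mean(rowSums(disp^2))))
}

#' Overlap between one mode and a displacement vector
#'
#' Absolute cosine similarity: 1 when the displacement is parallel (or
#' antiparallel) to the mode, 0 when orthogonal.
#'
#' @param e eigenvector (length 3n)
#' @param r displacement vector (length 3n)
#' @export
overlap <- function(e, r) {
  if (length(e) != length(r)) stop("vectors differ in length")
  ne <- sqrt(sum(e^2)); nr <- sqrt(sum(r^2))
  if (ne < 1e-12 || nr < 1e-12) stop("zero-norm input")
  abs(sum(e * r)) / (ne * nr)
}

#' Cumulative overlap of a mode set with a displacement
#'
#' Root-sum-square of the individual overlaps over the first `n_modes`
#' nontrivial modes: how much of the conformational change the mode subspace
#' can collectively reproduce.
#'
#' @param x an `enm` fit or `mode_set`
#' @param r displacement vector
#' @param n_modes number of nontrivial modes
#' @param include_trivial count trivial modes as part of the set (used for
#'   full-basis completeness checks)
#' @export
cumulative_overlap <- function(x, r, n_modes, include_trivial = FALSE) {
  m <- modes_of(x)
  stopifnot(n_modes >= 1L)
  first <- if (include_trivial) 0L else m$n_trivial
  sel <- first + seq_len(n_modes)
  if (max(sel) > ncol(m$vectors)) stop("not enough modes")
  ov <- apply(m$vectors[, sel, drop = FALSE], 2L, overlap, r = r)
  min(1, sqrt(sum(ov^2)))
}

#' Number of modes corresponding to a fraction of the nontrivial spectrum
#'
#' `ceiling(fraction * (3n - 6))`, so at least one mode is always used.
#' Reported benchmark curves sweep 1..`mode_count(n, 0.10)` with the
#' headline value at 5 percent.
#'
#' @param n_beads bead count
#' @param fraction fraction of the nontrivial modes
#' @export
mode_count <- function(n_beads, fraction) {
  max(1L, as.integer(ceiling(fraction * (3L * n_beads - 6L))))
}

#' Should a conformational pair enter the benchmark?
#'
#' Pairs whose superposed bead-center RMSD is below 2 Angstrom sample the
#' same conformation and are rejected.
#'
#' @param start,target bead coordinate matrices
#' @param min_rmsd rejection threshold, Angstrom
#' @export
conformational_pair_ok <- function(start, target, min_rmsd = 2) {
  superimpose(start, target)$rmsd >= min_rmsd
}

# coordinate matrices of a conformational ensemble, as a list
ensemble_coords <- function(x) {
  if (inherits(x, "bead_ensemble")) return(x$coords)
  if (inherits(x, "rna_structure")) {
    cms <- lapply(seq_along(x$xyz), function(m) coarse_grain(x, model = m))
    return(lapply(cms, `[[`, "coords"))
  }
  if (is.list(x) && all(vapply(x, is.matrix, TRUE))) return(x)
  stop("expected a bead_ensemble, multi-model rna_structure, or list of ",
       "coordinate matrices")
}

#' Rigid-body-free principal component analysis of an ensemble
#'
#' Standard PCA of the superposed conformations can still contain rotational
#' and translational variance whenever the ensemble has more than two
#' members.  This routine removes it: all conformations are superposed onto
#' the first, PCA is computed by singular value decomposition, the PCs are
#' Gram-Schmidt orthonormalized against the six rigid-body vectors of the
#' reference conformation (rigid-body basis first), and each PC's explained
#' variance is corrected by the rigid-body content it lost, then
#' renormalized.  PCs are returned in decreasing order of corrected
#' variance.
#'
#' @param x a `bead_ensemble`, a multi-model `rna_structure`, or a list of
#'   n x 3 coordinate matrices
#' @param var_target keep PCs until this cumulative corrected variance is
#'   reached (default 0.99)
#' @return a `pc_set`: `components` (3n x k), raw variances `v`, corrected
#'   variances `c` (each renormalized over the retained set), and
#'   `degenerate` flag for pure rigid-body ensembles
#' @export
nrt_pca <- function(x, var_target = 0.99) {
  confs <- ensemble_coords(x)
  if (length(confs) < 2L) stop("need at least two conformations")
  ref <- confs[[1L]]
  n <- nrow(ref)
  if (all(vapply(confs[-1L], function(cc) max(abs(cc - ref)) < 1e-10, TRUE)))
    stop("zero-variance ensemble: all conformations identical")
  mat <- t(vapply(confs, function(cc) {
    fit <- kabsch(ref, cc)
    as.numeric(t(apply_rigid(cc, fit$rotation, fit$translation)))
  }, numeric(3L * n)))
  ctr <- colMeans(mat)
  mat <- sweep(mat, 2L, ctr)
  if (max(abs(mat)) < 1e-8 * max(abs(ref) + 1)) {
    # conformations differ only by rigid transforms: nothing internal left
    warning("degenerate variance correction: ensemble variance is purely ",
            "rigid-body")
    return(structure(list(components = matrix(0, 3L * n, 0L),
                          v = numeric(), c = numeric(), degenerate = TRUE),
                     class = "pc_set"))
  }
  sv <- svd(mat)
  keep <- sv$d > 1e-10 * max(sv$d)
  pcs <- sv$v[, keep, drop = FALSE]
  v <- sv$d[keep]^2
  v <- v / sum(v)
  rt <- rt_basis(ref)
  # rigid-body content of each raw PC, then Gram-Schmidt with RT first
  rt_content <- colSums((t(rt) %*% pcs)^2)
  cvar <- v * (1 - rt_content)
  basis <- rt
  comps <- list(); keep_idx <- integer()
  for (k in seq_len(ncol(pcs))) {
    w <- pcs[, k] - basis %*% crossprod(basis, pcs[, k])
    nw <- sqrt(sum(w^2))
    if (nw < 1e-8) next                    # PC entirely rigid-body
    w <- w / nw
    basis <- cbind(basis, w)
    comps[[length(comps) + 1L]] <- w
    keep_idx <- c(keep_idx, k)
  }
  degenerate <- sum(cvar) < 1e-12
  if (degenerate) {
    warning("degenerate variance correction: ensemble variance is purely ",
            "rigid-body")
    cs <- rep(0, length(keep_idx))
  } else {
    cs <- cvar[keep_idx] / sum(cvar[keep_idx])
  }
  comp <- do.call(cbind, comps)
  ord <- order(cs, decreasing = TRUE)
  comp <- comp[, ord, drop = FALSE]
  cs <- cs[ord]
  vraw <- v[keep_idx][ord]
  if (!degenerate) {
    upto <- which(cumsum(cs) >= var_target - 1e-12)[1L]
    if (!is.na(upto)) {
      comp <- comp[, seq_len(upto), drop = FALSE]
      cs <- cs[seq_len(upto)]
      vraw <- vraw[seq_len(upto)]
    }
  }
  structure(list(components = comp, v = vraw / sum(vraw),
                 c = cs, degenerate = degenerate),
            class = "pc_set")
}

#' @export
print.pc_set <- function(x, ...) {
  cat(sprintf("rigid-body-free PCA: %d component(s)%s\n", ncol(x$components),
              if (x$degenerate) " [degenerate: rigid-body-only variance]"
              else ""))
  cat("corrected variances:", paste(signif(x$c, 3), collapse = " "), "\n")
  invisible(x)
}

#' Root mean square inner product between modes and principal components
#'
#' @param x an `enm` fit or `mode_set`
#' @param pcs a `pc_set`
#' @param n_modes number of nontrivial modes compared
#' @export
rmsip <- function(x, pcs, n_modes) {
  m <- modes_of(x)
  if (ncol(pcs$components) == 0L) stop("empty principal component set")
  sel <- m$n_trivial + seq_len(n_modes)
  ip <- crossprod(m$vectors[, sel, drop = FALSE], pcs$components)
  min(1, sqrt(sum(ip^2) / n_modes))
}

#' Normalized cumulative overlap between modes and principal components
#'
#' Variance-weighted sum over PCs of the squared cumulative overlap with the
#' first `n_modes` nontrivial modes; between 0 and 1 because the corrected
#' variances sum to at most 1.
#'
#' @inheritParams rmsip
#' @export
nco <- function(x, pcs, n_modes) {
  m <- modes_of(x)
  if (ncol(pcs$components) == 0L) stop("empty principal component set")
  if (sum(pcs$c) > 1 + 1e-8) stop("PC variances must sum to at most 1")
  sel <- m$n_trivial + seq_len(n_modes)
  ip <- crossprod(m$vectors[, sel, drop = FALSE], pcs$components)  # N x M
  min(1, sum(pcs$c * colSums(ip^2)))
}
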