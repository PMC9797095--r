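# Elastic network potentials and their analytic Hessians.
#
# All three models are harmonic expansions about the input conformation, so
# every term's first derivative vanishes at the reference geometry and the
# Hessian of a term V(q) of an internal coordinate q (bond length, angle,
# dihedral or pair distance) reduces to V''(q0) * grad(q) grad(q)^T, with
# grad(q) the standard Wilson rows.  The sequence-sensitive model adds a
# surface-in-contact modulation beta_ij to the long-range term; the two
# anisotropic-network baselines depend on bead geometry only.

#' Elastic network parameters
#'
#' @param alpha1,alpha2,alpha3,alpha4 weights of the bond-stretch, angle,
#'   dihedral and long-range terms of the sequence-sensitive potential
#' @param favorable,unfavorable interaction weights of the two atomic
#'   contact classes entering beta_ij
#' @param gamma uniform spring constant of the anisotropic network models
#' @param rc distance cutoff (Angstrom) of the cutoff network; the default
#'   10 is the value found optimal for RNA three-bead networks
#' @param power inverse-distance exponent of the power-dependent network
#' @param trivial_tol eigenvalues below `trivial_tol * max(eigenvalue)` are
#'   classified as rigid-body modes
#' @export
enm_control <- function(alpha1 = 1e3, alpha2 = 1e4, alpha3 = 1e4,
                        alpha4 = 1e-2, favorable = 3, unfavorable = 1,
                        gamma = 1, rc = 10, power = 7, trivial_tol = 1e-8) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            alpha4 = alpha4, favorable = favorable,
            unfavorable = unfavorable, gamma = gamma, rc = rc,
            power = power, trivial_tol = trivial_tol)
  if (any(unlist(p) <= 0)) stop("all elastic network parameters must be > 0")
  p
}

# ---- internal-coordinate gradients -----------------------------------------

grad_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- vec_norm(u); nv <- vec_norm(v)
  uh <- u / nu; vh <- v / nv
  ct <- sum(uh * vh)
  st <- sqrt(max(1e-14, 1 - ct * ct))
  ga <- (ct * uh - vh) / (nu * st)
  gc <- (ct * vh - uh) / (nv * st)
  list(ga = ga, gb = -(ga + gc), gc = gc)
}

grad_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  l2 <- vec_norm(b2)
  n1sq <- sum(n1 * n1); n2sq <- sum(n2 * n2)
  if (n1sq < 1e-12 || n2sq < 1e-12)
    stop("undefined dihedral: collinear beads")
  ga <- -l2 / n1sq * n1
  gd <- l2 / n2sq * n2
  s <- sum(b1 * b2) / (l2 * l2)
  t <- sum(b3 * b2) / (l2 * l2)
  gb <- -(1 + s) * ga + t * gd
  gc <- s * ga - (1 + t) * gd
  list(ga = ga, gb = gb, gc = gc, gd = gd)
}

# add g2 * b b^T for a small set of beads; bvec is a named list bead -> 3-vec
add_rank1 <- function(H, beads, grads, g2) {
  m <- length(beads)
  idx <- as.numeric(t(outer(3 * (beads - 1L), 1:3, "+")))
  b <- unlist(grads)
  H[idx, idx] <- H[idx, idx] + g2 * tcrossprod(b)
  H
}

# vectorized accumulation of sum_k g2_k * b_k b_k^T over bead pairs,
# with b = (-u, u): blocks  ii += g2 uu^T, jj += g2 uu^T, ij -= g2 uu^T
pair_hessian_add <- function(H, coords, pi, pj, g2) {
  if (length(pi) == 0L) return(H)
  dx <- coords[pj, , drop = FALSE] - coords[pi, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  if (any(r < 1e-8)) stop("geometry error: coincident beads")
  u <- dx / r
  for (a in 1:3) for (b in 1:3) {
    val <- g2 * u[, a] * u[, b]
    off <- cbind(3 * (pi - 1L) + a, 3 * (pj - 1L) + b)
    H[off] <- H[off] - val
    off2 <- cbind(3 * (pj - 1L) + b, 3 * (pi - 1L) + a)
    H[off2] <- H[off2] - val
    dg <- rowsum(c(val, val), c(pi, pj))
    who <- as.integer(rownames(dg))
    di <- cbind(3 * (who - 1L) + a, 3 * (who - 1L) + b)
    H[di] <- H[di] + dg[, 1L]
  }
  H
}

# long-range pair set: bead pairs farther than 3 steps along the bond graph
# (or in different connected components)
longrange_pairs <- function(cm) {
  d <- graph_distance_le3(cm$n, cm$bonds)
  which(upper.tri(d) & d >= 4L, arr.ind = TRUE)
}

reference_internal <- function(cm) {
  x <- cm$coords
  bl <- if (nrow(cm$bonds)) sqrt(rowSums(
    (x[cm$bonds[, 2L], , drop = FALSE] - x[cm$bonds[, 1L], , drop = FALSE])^2))
  else numeric()
  th <- apply(cm$angles, 1L, function(a)
    calc_angle(x[a[1L], ], x[a[2L], ], x[a[3L], ]))
  ph <- apply(cm$dihedrals, 1L, function(a)
    calc_dihedral(x[a[1L], ], x[a[2L], ], x[a[3L], ], x[a[4L], ]))
  list(bonds = as.numeric(bl), angles = as.numeric(th),
       dihedrals = as.numeric(ph))
}

#' Potential energy of a conformation under the sequence-sensitive network
#'
#' Evaluates the four-term potential (bond stretch, angle bend, dihedral
#' torsion, contact-modulated 12-10 long-range) of an arbitrary conformation
#' around the reference model.  The harmonic terms vanish at the reference
#' geometry; each long-range pair sits at the minimum of its 12-10 well,
#' contributing -(beta_ij + alpha4).
#'
#' @param conf n x 3 (or length-3n) coordinates with the reference bead
#'   layout
#' @param cm the reference `coarse_model`
#' @param beta bead-pair modulation matrix from [beta_matrix()]
#' @param params [enm_control()] parameters
#' @export
energy_encom <- function(conf, cm, beta, params = enm_control()) {
  x <- if (is.matrix(conf)) conf else matrix(conf, ncol = 3L, byrow = TRUE)
  if (nrow(x) != cm$n) stop("conformation does not match the bead layout")
  ref <- reference_internal(cm)
  v <- 0
  if (nrow(cm$bonds)) {
    r <- sqrt(rowSums((x[cm$bonds[, 2L], , drop = FALSE] -
                       x[cm$bonds[, 1L], , drop = FALSE])^2))
    if (any(r < 1e-8)) stop("geometry error: zero-length bond")
    v <- v + params$alpha1 * sum((r - ref$bonds)^2)
  }
  if (nrow(cm$angles)) {
    th <- apply(cm$angles, 1L, function(a)
      calc_angle(x[a[1L], ], x[a[2L], ], x[a[3L], ]))
    v <- v + params$alpha2 * sum((th - ref$angles)^2)
  }
  if (nrow(cm$dihedrals)) {
    ph <- apply(cm$dihedrals, 1L, function(a)
      calc_dihedral(x[a[1L], ], x[a[2L], ], x[a[3L], ], x[a[4L], ]))
    dd <- ph - ref$dihedrals
    v <- v + params$alpha3 * sum((1 - cos(dd)) + 0.5 * (1 - cos(3 * dd)))
  }
  lr <- longrange_pairs(cm)
  if (nrow(lr)) {
    r0 <- sqrt(rowSums((cm$coords[lr[, 2L], , drop = FALSE] -
                        cm$coords[lr[, 1L], , drop = FALSE])^2))
    r <- sqrt(rowSums((x[lr[, 2L], , drop = FALSE] -
                       x[lr[, 1L], , drop = FALSE])^2))
    k <- beta[lr] + params$alpha4
    v <- v + sum(k * (5 * (r0 / r)^12 - 6 * (r0 / r)^10))
  }
  v
}

#' Analytic Hessian of the sequence-sensitive network
#'
#' @inheritParams energy_encom
#' @return symmetric 3n x 3n matrix; each 3 x 3 row-block sums to zero
#'   (translation invariance)
#' @export
hessian_encom <- function(cm, beta, params = enm_control()) {
  n <- cm$n
  if (n < 3L) stop("rank error: need at least 3 beads")
  x <- cm$coords
  H <- matrix(0, 3L * n, 3L * n)
  if (nrow(cm$bonds))
    H <- pair_hessian_add(H, x, cm$bonds[, 1L], cm$bonds[, 2L],
                          rep(2 * params$alpha1, nrow(cm$bonds)))
  for (q in seq_len(nrow(cm$angles))) {
    a <- cm$angles[q, ]
    g <- grad_angle(x[a[1L], ], x[a[2L], ], x[a[3L], ])
    H <- add_rank1(H, a, g, 2 * params$alpha2)
  }
  for (q in seq_len(nrow(cm$dihedrals))) {
    a <- cm$dihedrals[q, ]
    g <- grad_dihedral(x[a[1L], ], x[a[2L], ], x[a[3L], ], x[a[4L], ])
    H <- add_rank1(H, a, g, 5.5 * params$alpha3)
  }
  lr <- longrange_pairs(cm)
  if (nrow(lr)) {
    r0 <- sqrt(rowSums((x[lr[, 2L], , drop = FALSE] -
                        x[lr[, 1L], , drop = FALSE])^2))
    k <- 120 * (beta[lr] + params$alpha4) / r0^2
    H <- pair_hessian_add(H, x, lr[, 1L], lr[, 2L], k)
  }
  (H + t(H)) / 2
}

#' Hessian of the distance-cutoff anisotropic network
#'
#' Beads closer than the cutoff are joined by springs of uniform constant
#' gamma; each connected pair contributes the standard anisotropic
#' superblock along the inter-bead direction.
#'
#' @param cm a `coarse_model`
#' @param params [enm_control()] (uses `gamma` and `rc`)
#' @export
hessian_cut_anm <- function(cm, params = enm_control()) {
  n <- cm$n
  x <- cm$coords
  d <- as.matrix(stats::dist(x))
  pr <- which(upper.tri(d) & d <= params$rc, arr.ind = TRUE)
  H <- matrix(0, 3L * n, 3L * n)
  if (nrow(pr) == 0L) {
    warning("disconnected network: no bead pair within the cutoff")
    return(H)
  }
  deg <- tabulate(c(pr[, 1L], pr[, 2L]), n)
  if (any(deg == 0L))
    warning("disconnected network: ", sum(deg == 0L),
            " bead(s) without neighbors within the cutoff")
  pair_hessian_add(H, x, pr[, 1L], pr[, 2L], rep(params$gamma, nrow(pr)))
}

#' Hessian of the power-dependent anisotropic network
#'
#' All bead pairs are connected; the spring constant decays as the inverse
#' of the pair distance to the chosen power.
#'
#' @param cm a `coarse_model`
#' @param params [enm_control()] (uses `gamma` and `power`)
#' @export
hessian_pd_anm <- function(cm, params = enm_control()) {
  n <- cm$n
  x <- cm$coords
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  r0 <- sqrt(rowSums((x[pr[, 2L], , drop = FALSE] -
                      x[pr[, 1L], , drop = FALSE])^2))
  if (any(r0 < 1e-8)) stop("geometry error: coincident beads")
  H <- matrix(0, 3L * n, 3L * n)
  pair_hessian_add(H, x, pr[, 1L], pr[, 2L], params$gamma / r0^params$power)
}

#' Diagonalize a Hessian into a normal mode set
#'
#' Eigenvalues are sorted ascending; near-zero modes are classified as
#' trivial (rigid translations/rotations) by a relative magnitude threshold
#' and verified by projection onto the analytic rigid-body subspace.
#'
#' @param H symmetric 3n x 3n Hessian
#' @param coords the n x 3 bead coordinates (for the rigid-body basis)
#' @param trivial_tol relative eigenvalue threshold
#' @return a `mode_set`: eigenvalues `values`, orthonormal eigenvectors
#'   `vectors` (columns), `frequencies` (sqrt(lambda)/2pi), `n_trivial`
#' @export
diagonalize <- function(H, coords, trivial_tol = 1e-8) {
  stopifnot(isSymmetric(H, tol = 1e-6))
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  thr <- trivial_tol * max(abs(values))
  ntriv <- sum(abs(values) < thr)
  if (ntriv > 6L)
    warning("degenerate geometry: ", ntriv, " near-zero modes (expected 6)")
  rt <- rt_basis(coords)
  if (ntriv > 0L) {
    pr <- colSums((t(rt) %*% vectors[, seq_len(ntriv), drop = FALSE])^2)
    if (any(pr < 0.99))
      warning("trivial mode(s) project weakly (<0.99) onto the rigid-body ",
              "subspace")
  }
  values[seq_len(ntriv)] <- 0
  structure(list(values = values, vectors = vectors,
                 frequencies = sqrt(pmax(values, 0)) / (2 * pi),
                 n_trivial = ntriv),
            class = "mode_set")
}

#' Fit an elastic network normal-mode model to an RNA structure
#'
#' The central model constructor.  Coarse-grains the structure into
#' phosphate/sugar/base beads, builds the requested potential
#' (`"encom"`: sequence-sensitive four-term potential with surface-in-contact
#' modulated long-range springs; `"cut_anm"`: uniform springs within a
#' distance cutoff; `"pd_anm"`: all-pair springs with inverse power-law
#' constants), assembles the analytic Hessian and diagonalizes it.
#'
#' @param x an `rna_structure` or a prebuilt `coarse_model`
#' @param model which elastic network potential to use
#' @param params [enm_control()] parameters
#' @param model_index conformation used when `x` is a multi-model ensemble
#' @param scheme bead scheme passed to [coarse_grain()]
#' @param types,eps atom typing tables for the surface-in-contact term
#' @return an object of class `enm` with components `model`, `cm`
#'   (the coarse model), `beta` (contact modulation, sequence-sensitive
#'   potential only), `hessian`, and `modes` (a `mode_set`)
#' @examples
#' helix <- build_aform("GCGCGC", duplex = TRUE)
#' fit <- enm(helix)
#' fit
#' head(msf(fit))
#' @export
enm <- function(x, model = c("encom", "cut_anm", "pd_anm"),
                params = enm_control(), model_index = 1L,
                scheme = c("psb", "p"), types = atom_types(),
                eps = NULL) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  cm <- if (inherits(x, "coarse_model")) x
        else coarse_grain(x, model = model_index, scheme = scheme)
  beta <- NULL
  if (model == "encom") {
    if (is.null(eps))
      eps <- interaction_matrix(favorable = params$favorable,
                                unfavorable = params$unfavorable)
    beta <- beta_matrix(cm, types = types, eps = eps)
    H <- hessian_encom(cm, beta, params)
  } else if (model == "cut_anm") {
    H <- hessian_cut_anm(cm, params)
  } else {
    H <- hessian_pd_anm(cm, params)
  }
  modes <- diagonalize(H, cm$coords, params$trivial_tol)
  structure(list(model = model, cm = cm, params = params, beta = beta,
                 hessian = H, modes = modes, call = match.call()),
            class = "enm")
}

#' @export
print.enm <- function(x, ...) {
  cat(sprintf("elastic network model '%s': %d beads, %d modes (%d trivial)\n",
              x$model, x$cm$n, length(x$modes$values), x$modes$n_trivial))
  nt <- x$modes$n_trivial
  lam <- x$modes$values[(nt + 1):min(nt + 5, length(x$modes$values))]
  cat("lowest nontrivial eigenvalues:", paste(signif(lam, 4), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.enm <- function(object, ...) {
  m <- object$modes
  out <- list(model = object$model, n_beads = object$cm$n,
              n_trivial = m$n_trivial,
              eigenvalue_range = range(m$values[(m$n_trivial + 1):
                                                  length(m$values)]),
              msf = msf(object))
  class(out) <- "summary.enm"
  out
}

#' @export
print.summary.enm <- function(x, ...) {
  cat(sprintf("'%s' network, %d beads, %d trivial modes\n", x$model,
              x$n_beads, x$n_trivial))
  cat(sprintf("nontrivial eigenvalues in [%.4g, %.4g]\n",
              x$eigenvalue_range[1L], x$eigenvalue_range[2L]))
  cat("per-bead mean-square fluctuation summary:\n")
  print(summary(x$msf))
  invisible(x)
}

#' @export
plot.enm <- function(x, beta = NULL, ...) {
  y <- if (is.null(beta)) msf(x) else entropic_signature(x, beta)$values
  graphics::plot(seq_along(y), y, type = "h",
                 xlab = "bead", col = c(P = "goldenrod", S = "palegreen3",
                                        B = "darkgreen")[x$cm$beads$role],
                 ylab = if (is.null(beta)) "mean-square fluctuation"
                        else "entropic signature", ...)
  invisible(x)
}
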