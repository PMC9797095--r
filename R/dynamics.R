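# Per-bead fluctuation descriptors derived from normal modes.

modes_of <- function(x) {
  if (inherits(x, "enm")) x$modes
  else if (inherits(x, "mode_set")) x
  else stop("expected an 'enm' fit or a 'mode_set'")
}

#' Mean-square fluctuations per bead
#'
#' Sums the squared xyz components of each bead over the nontrivial modes,
#' weighted by the inverse eigenvalue; the classical B-factor predictor of
#' normal mode analysis.
#'
#' @param x an `enm` fit or `mode_set`
#' @param n_modes number of nontrivial modes to use (default: all)
#' @return numeric vector, one value per bead
#' @export
msf <- function(x, n_modes = NULL) {
  m <- modes_of(x)
  avail <- length(m$values) - m$n_trivial
  if (is.null(n_modes)) n_modes <- avail
  if (n_modes > avail) stop("only ", avail, " nontrivial modes available")
  n <- length(m$values) / 3L
  if (n_modes == 0L) return(numeric(n))
  sel <- m$n_trivial + seq_len(n_modes)
  lam <- m$values[sel]
  if (any(lam <= 0)) stop("nonpositive eigenvalue among selected modes")
  ev2 <- m$vectors[, sel, drop = FALSE]^2
  per_bead <- rowsum(ev2, rep(seq_len(n), each = 3L))
  as.numeric(per_bead %*% (1 / lam))
}

#' Vibrational entropy of one harmonic mode
#'
#' `S(beta*nu) = beta*nu / (exp(beta*nu) - 1) - log(1 - exp(-beta*nu))`,
#' monotone decreasing in `beta*nu`: slow modes carry more entropy.
#'
#' @param nu mode frequency (model units)
#' @param beta thermodynamic scaling factor (> 0); larger values weight
#'   low-frequency modes more strongly
#' @export
vibrational_entropy <- function(nu, beta) {
  bn <- beta * nu
  if (any(bn <= 0)) stop("beta * nu must be positive")
  bn / expm1(bn) - log1p(-exp(-bn))
}

#' Entropic signature of a mode set
#'
#' Scales each mode's squared per-bead fluctuations by the vibrational
#' entropy of the mode and sums over all nontrivial modes.  The scaling
#' factor beta tunes the relative contribution of slow versus fast modes;
#' since the models are pseudo-physical, beta is a unitless multiplier of
#' the mode frequency.
#'
#' @param x an `enm` fit or `mode_set`
#' @param beta thermodynamic scaling factor
#' @param n_modes number of nontrivial modes (default all)
#' @return an `entropic_signature` object: `values` (per bead), `beta`,
#'   `mode_range`
#' @export
entropic_signature <- function(x, beta, n_modes = NULL) {
  m <- modes_of(x)
  avail <- length(m$values) - m$n_trivial
  if (avail < 1L) stop("need at least one nontrivial mode")
  if (is.null(n_modes)) n_modes <- avail
  sel <- m$n_trivial + seq_len(n_modes)
  sv <- vibrational_entropy(m$frequencies[sel], beta)
  n <- length(m$values) / 3L
  ev2 <- m$vectors[, sel, drop = FALSE]^2
  per_bead <- rowsum(ev2, rep(seq_len(n), each = 3L))
  structure(list(values = as.numeric(per_bead %*% sv), beta = beta,
                 mode_range = c(m$n_trivial + 1L, m$n_trivial + n_modes)),
            class = "entropic_signature")
}

#' @export
print.entropic_signature <- function(x, ...) {
  cat(sprintf("entropic signature at beta = %.4g over modes %d..%d\n",
              x$beta, x$mode_range[1L], x$mode_range[2L]))
  print(summary(x$values))
  invisible(x)
}

#' Pearson correlation between predicted and experimental B-factors
#'
#' @param predicted per-bead fluctuation predictor (MSF or entropic
#'   signature values)
#' @param experimental per-bead experimental B-factors, taken from each
#'   bead's center atom
#' @export
bfactor_correlation <- function(predicted, experimental) {
  if (length(predicted) != length(experimental) || length(predicted) < 3L)
    stop("need two equal-length vectors of at least 3 beads")
  if (stats::sd(predicted) == 0 || stats::sd(experimental) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(predicted, experimental)
}

# experimental B-factor of each bead's center atom
bead_bfactors <- function(cm) {
  cm$structure$atoms$bfactor[cm$beads$center]
}

#' Logarithmic grid of thermodynamic scaling factors
#'
#' 41 values by default, log-spaced in natural-log increments of 0.25 and
#' centered on `center` — the sweep protocol used when fitting the scaling
#' factor to a dataset.
#'
#' @param center central beta value
#' @param n number of grid points (odd keeps `center` on the grid)
#' @param step natural-log increment
#' @export
beta_grid <- function(center = exp(0.25), n = 41L, step = 0.25) {
  stopifnot(n >= 1L, step > 0, center > 0)
  k <- seq_len(n) - (n + 1L) / 2
  center * exp(step * k)
}

# default scaling-factor centers per model (B-factor benchmark optima)
default_beta <- function(model) {
  switch(model, encom = exp(0.25), cut_anm = exp(1), pd_anm = exp(9.5),
         stop("unknown model"))
}
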