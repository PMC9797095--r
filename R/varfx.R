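# Variant-effect regression: from per-variant dynamics features to a
# functional readout, with leakage-proof benchmark splits, an L1-regularized
# linear model, and coefficient mapping back onto the structure.

#' Read a variant table from CSV
#'
#' Column names are configurable so supplementary tables with different
#' headers can be consumed directly.  Mutated positions and mutation counts
#' are derived from the reference sequence.
#'
#' @param path CSV file with one row per sequence variant
#' @param reference reference (wild-type) sequence
#' @param sequence_col,efficiency_col,energy_col,mfe_col column names for
#'   the sequence, the functional readout, the optional folding energy and
#'   the optional flag marking variants whose minimum-free-energy structure
#'   matches the wild type
#' @return data frame with columns `id`, `sequence`, `efficiency`,
#'   `fold_energy`, `mfe_matches_wt`, `n_mutations` and a list column
#'   `mutated_positions`
#' @export
read_variants <- function(path, reference,
                          sequence_col = "sequence",
                          efficiency_col = "maturation_efficiency",
                          energy_col = "mcfold_energy",
                          mfe_col = "mfe_matches_wt") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!sequence_col %in% names(d))
    stop("missing sequence column '", sequence_col, "'")
  if (!efficiency_col %in% names(d))
    stop("missing efficiency column '", efficiency_col, "'")
  annotate_variants(data.frame(
    id = if ("id" %in% names(d)) d$id else seq_len(nrow(d)),
    sequence = toupper(d[[sequence_col]]),
    efficiency = d[[efficiency_col]],
    fold_energy = if (energy_col %in% names(d)) d[[energy_col]] else NA_real_,
    mfe_matches_wt = if (mfe_col %in% names(d)) as.logical(d[[mfe_col]])
                     else TRUE,
    stringsAsFactors = FALSE), reference)
}

#' Annotate variants with mutated positions relative to a reference
#'
#' @param variants data frame with at least a `sequence` column
#' @param reference reference sequence of equal length
#' @export
annotate_variants <- function(variants, reference) {
  ref <- check_sequence(reference)
  mut <- lapply(variants$sequence, function(s) {
    v <- check_sequence(s)
    if (length(v) != length(ref))
      stop("variant length differs from the reference")
    which(v != ref)
  })
  variants$mutated_positions <- mut
  variants$n_mutations <- lengths(mut)
  variants
}

#' Position-disjoint benchmark split
#'
#' Reserves variants touching only the middle base pair of their mutation
#' box for the test set and variants touching only the bottom/top base pairs
#' for the training set; variants spanning both are excluded.  By
#' construction the mutated positions of the two sets are disjoint, so no
#' sequence feature at a mutated position can leak from training to test.
#'
#' @param variants annotated variant table (rows with
#'   `mfe_matches_wt == FALSE` or no mutations are dropped)
#' @param boxes list of boxes, each a list with integer position vectors
#'   `bottom`, `middle`, `top`
#' @return list with data frames `train` and `test`
#' @export
split_hard <- function(variants, boxes) {
  v <- variants[variants$mfe_matches_wt & variants$n_mutations > 0L, ,
                drop = FALSE]
  midpos <- sort(unique(unlist(lapply(boxes, `[[`, "middle"))))
  endpos <- sort(unique(unlist(lapply(
    boxes, function(b) c(b$bottom, b$top)))))
  allpos <- sort(unique(c(midpos, endpos)))
  test <- vapply(v$mutated_positions, function(p) all(p %in% midpos), TRUE)
  train <- vapply(v$mutated_positions, function(p) all(p %in% endpos), TRUE)
  uncovered <- vapply(v$mutated_positions,
                      function(p) any(!(p %in% allpos)), TRUE)
  if (any(uncovered))
    stop("box definitions do not cover mutated position(s) of variant(s): ",
         paste(utils::head(v$id[uncovered]), collapse = ", "))
  out <- list(train = v[train, , drop = FALSE],
              test = v[test, , drop = FALSE])
  check_split_disjoint(out)
  out
}

check_split_disjoint <- function(split) {
  tr <- unique(unlist(split$train$mutated_positions))
  te <- unique(unlist(split$test$mutated_positions))
  if (length(intersect(tr, te)))
    stop("leakage: train and test share mutated positions ",
         paste(intersect(tr, te), collapse = ","))
  invisible(split)
}

#' Low-redundancy ("inverted") benchmark split
#'
#' Variants with one or two mutations train the model; variants with three
#' or more are the test set.  The small training set prevents memorization
#' of multi-mutation patterns while still allowing sequence features to be
#' learned.
#'
#' @param variants annotated variant table
#' @export
split_inverted <- function(variants) {
  v <- variants[variants$mfe_matches_wt, , drop = FALSE]
  list(train = v[v$n_mutations %in% c(1L, 2L), , drop = FALSE],
       test = v[v$n_mutations >= 3L, , drop = FALSE])
}

#' One-hot-like sequence encoding on a +/-1 alphabet
#'
#' Each position expands into a block of four entries (A, C, G, U order),
#' exactly one of which is +1 and the rest -1.
#'
#' @param sequence RNA sequence
#' @export
encode_sequence <- function(sequence) {
  v <- check_sequence(sequence)
  out <- rep(-1, 4L * length(v))
  out[4L * (seq_along(v) - 1L) + match(v, RNA_BASES)] <- 1
  out
}

#' @rdname encode_sequence
#' @param encoded a vector produced by [encode_sequence()]
#' @export
decode_sequence <- function(encoded) {
  m <- matrix(encoded, nrow = 4L)
  if (!all(colSums(m == 1) == 1L & colSums(m == -1) == 3L))
    stop("not a valid encoded sequence")
  paste(RNA_BASES[apply(m, 2L, which.max)], collapse = "")
}

#' L1-regularized (lasso) linear regression with frozen standardization
#'
#' Features are standardized with training-set statistics (frozen into the
#' fit and applied unchanged at prediction time); zero-variance training
#' columns are excluded and carry coefficient exactly zero — which is what
#' collapses a sequence-only model to a constant predictor on a
#' position-disjoint split.  The objective is
#' `(1/2n) ||y - Xw - b||^2 + lambda ||w||_1` with an unpenalized
#' intercept, solved by coordinate descent.
#'
#' @param x numeric training feature matrix (rows = observations)
#' @param y numeric response
#' @param lambda regularization strength (>= 0)
#' @return an `l1_fit` with [coef()] and [predict()] methods
#' @export
fit_l1 <- function(x, y, lambda = 0) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L, lambda >= 0)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  keep <- which(scl > 1e-12)
  w_full <- numeric(ncol(x))
  if (length(keep) == 0L) {
    fit <- NULL
    intercept <- mean(y)
  } else {
    xs <- scale(x[, keep, drop = FALSE], center = ctr[keep],
                scale = scl[keep])
    nlam <- sort(unique(c(lambda, max(abs(crossprod(xs, y - mean(y)))) /
                                    length(y) * c(1, 0.5, 0.1))),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(xs, y, alpha = 1, lambda = nlam,
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-12, maxit = 1e6)
    cf <- as.numeric(suppressWarnings(
      glmnet::coef.glmnet(fit, s = lambda, exact = TRUE, x = xs, y = y)))
    intercept <- cf[1L]
    w_full[keep] <- cf[-1L]
  }
  structure(list(coefficients = stats::setNames(w_full, colnames(x)),
                 intercept = intercept, lambda = lambda,
                 center = ctr, scale = scl, keep = keep,
                 train_fitted = NULL), class = "l1_fit")
}

#' @export
coef.l1_fit <- function(object, ...) {
  c(`(intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.l1_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  k <- object$keep
  if (length(k) == 0L) return(rep(object$intercept, nrow(newx)))
  xs <- scale(newx[, k, drop = FALSE], center = object$center[k],
              scale = object$scale[k])
  as.numeric(xs %*% object$coefficients[k] + object$intercept)
}

#' @export
print.l1_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("lasso fit: lambda = %.4g, %d/%d nonzero coefficient(s), intercept %.4g\n",
              x$lambda, nz, length(x$coefficients), x$intercept))
  invisible(x)
}

#' Out-of-sample predictive R-squared
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the
#' test-set mean; negative when the model predicts worse than that mean.
#'
#' @param y_true observed test responses
#' @param y_pred predictions
#' @export
predictive_r2 <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst < 1e-14) stop("undefined predictive R^2: zero test variance")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Scan the scaling-factor and regularization grids
#'
#' For every (beta, lambda) pair, builds the entropic-signature feature
#' matrix at that beta (optionally with a standardized folding-energy
#' column), fits the lasso on the training rows and evaluates predictive
#' R-squared on the test rows.
#'
#' @param es_provider function(beta) returning the n_variants x n_beads
#'   entropic-signature matrix, or a precomputed 3D array
#'   (variant x bead x beta)
#' @param efficiency response vector over all variants
#' @param split list with `train` and `test` integer row indices
#' @param betas,lambdas grids to scan
#' @param fold_energy optional per-variant energy column added as a feature
#' @return a `grid_scan` data frame (`beta`, `lambda`, `r2`) with the argmax
#'   in attributes `best`
#' @export
grid_scan <- function(es_provider, efficiency, split,
                      betas = beta_grid(),
                      lambdas = 2^seq(-15, 0), fold_energy = NULL) {
  get_es <- if (is.function(es_provider)) es_provider
            else function(b) {
              k <- which(abs(dimnames(es_provider)[[3L]] |>
                               as.numeric() - b) < 1e-9)
              es_provider[, , k]
            }
  rows <- NULL
  for (b in betas) {
    X <- as.matrix(get_es(b))
    if (!is.null(fold_energy)) X <- cbind(X, fold_energy = fold_energy)
    if (anyNA(X)) stop("missing entropic signature for variant(s) ",
                       paste(utils::head(which(rowSums(is.na(X)) > 0)),
                             collapse = ","))
    xtr <- X[split$train, , drop = FALSE]
    xte <- X[split$test, , drop = FALSE]
    for (l in lambdas) {
      f <- fit_l1(xtr, efficiency[split$train], lambda = l)
      r2 <- predictive_r2(efficiency[split$test], predict(f, xte))
      rows <- rbind(rows, data.frame(beta = b, lambda = l, r2 = r2))
    }
  }
  best <- rows[which.max(rows$r2), ]
  structure(rows, best = best, class = c("grid_scan", "data.frame"))
}

#' Significance of a combined model against an energy-plus-noise null
#'
#' Repeatedly replaces the dynamics features by pure noise — normal with the
#' training-set mean and half its standard deviation — combined with the
#' folding-energy column in the same two-feature regression, and reports the
#' fraction of replicates whose predictive R-squared reaches the observed
#' combined-model value.
#'
#' @param fold_energy list with `train` and `test` energy vectors
#' @param y_train,y_test responses
#' @param observed_r2 predictive R-squared of the model under test
#' @param n_reps number of noise replicates (>= 1000 for a stable tail)
#' @param seed RNG seed
#' @param lambda regularization of the two-feature fits
#' @return list with `p_value`, `p_label` (reported as "< 1/n" when no
#'   replicate reaches the observed value) and the replicate `r2` vector
#' @export
noise_combination_sim <- function(fold_energy, y_train, y_test, observed_r2,
                                  n_reps = 1000L, seed = 1L, lambda = 2^-8) {
  stopifnot(n_reps >= 1L)
  if (stats::sd(y_train) < 1e-14) stop("degenerate training response")
  set.seed(seed)
  r2 <- numeric(n_reps)
  mu <- mean(y_train); s <- stats::sd(y_train) / 2
  for (k in seq_len(n_reps)) {
    noise_tr <- stats::rnorm(length(y_train), mu, s)
    noise_te <- stats::rnorm(length(y_test), mu, s)
    f <- fit_l1(cbind(energy = fold_energy$train, noise = noise_tr),
                y_train, lambda = lambda)
    r2[k] <- predictive_r2(
      y_test, predict(f, cbind(energy = fold_energy$test, noise = noise_te)))
  }
  p <- mean(r2 >= observed_r2)
  list(p_value = p,
       p_label = if (p == 0) paste0("< ", format(1 / n_reps)) else format(p),
       r2 = r2)
}

#' Map regression coefficients back onto the structure
#'
#' Produces a per-bead coefficient table and, optionally, a PDB file with
#' each bead's coefficient stamped into the B-factor column of its member
#' atoms, for visual inspection of where the model found its signal.
#'
#' @param fit an `l1_fit` whose first `n` coefficients correspond to beads
#' @param cm the `coarse_model` the features came from
#' @param file optional output PDB path
#' @return data frame (chain, resno, base, role, coefficient) with the
#'   coefficient sum and absolute sum in attributes
#' @export
map_coefficients <- function(fit, cm, file = NULL) {
  w <- fit$coefficients
  if (length(w) < cm$n)
    stop("layout error: fewer coefficients than beads")
  wb <- as.numeric(w[seq_len(cm$n)])
  out <- data.frame(cm$beads[, c("chain", "resno", "base", "role")],
                    coefficient = wb)
  attr(out, "sum") <- sum(wb)
  attr(out, "sum_abs") <- sum(abs(wb))
  if (!is.null(file))
    write_rna_pdb(cm$structure, file, bfactor = wb, beads = cm)
  out
}
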