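# Synthetic mutational-scan datasets with planted linear structure, used to
# validate the whole dynamics-to-function regression pipeline end to end.

#' Mutation boxes on an idealized hairpin
#'
#' Partitions the stem of a hairpin (5' strand length `stem_len`, loop
#' length `loop_len`) into boxes of three consecutive base pairs counted
#' from the hairpin bottom.  Each box lists its `bottom`, `middle` and `top`
#' base-pair positions (a 5' position i pairs with position L+1-i).
#'
#' @param stem_len number of stem base pairs
#' @param loop_len loop length (nucleotides)
#' @param n_boxes number of boxes (each consumes 3 stem pairs)
#' @export
hairpin_boxes <- function(stem_len, loop_len, n_boxes = stem_len %/% 3L) {
  if (3L * n_boxes > stem_len) stop("not enough stem pairs for ", n_boxes,
                                    " boxes")
  total <- 2L * stem_len + loop_len
  pair_pos <- function(i) c(i, total + 1L - i)
  lapply(seq_len(n_boxes), function(b) {
    base <- 3L * (b - 1L)
    list(bottom = pair_pos(base + 1L), middle = pair_pos(base + 2L),
         top = pair_pos(base + 3L))
  })
}

box_positions <- function(box) sort(c(box$bottom, box$middle, box$top))

#' Enumerate box-mutant sequence variants
#'
#' For each box, substitutes all possible hexamers at the box positions
#' except the wild-type one; optionally enumerates a small extra position
#' set (e.g. a two-nucleotide bulge) the same way, and appends the wild type
#' once.  Thirteen six-nucleotide boxes plus a dinucleotide position set
#' yield 13 * (4^6 - 1) + (4^2 - 1) + 1 = 53251 distinct variants.
#'
#' @param reference reference sequence (character)
#' @param boxes list from [hairpin_boxes()] (or any list of position sets
#'   with `bottom`/`middle`/`top` components)
#' @param bulge optional integer positions mutated exhaustively as one group
#' @return data frame with `id`, `sequence`, `box`
#' @export
enumerate_variants <- function(reference, boxes, bulge = NULL) {
  ref <- check_sequence(reference)
  out_seq <- character(); out_box <- integer()
  enum_group <- function(pos) {
    wt <- ref[pos]
    grid <- do.call(expand.grid,
                    c(rep(list(RNA_BASES), length(pos)),
                      list(stringsAsFactors = FALSE)))
    keep <- rowSums(grid != matrix(wt, nrow(grid), length(pos),
                                   byrow = TRUE)) > 0L
    grid <- grid[keep, , drop = FALSE]
    vapply(seq_len(nrow(grid)), function(r) {
      s <- ref
      s[pos] <- as.character(grid[r, ])
      paste(s, collapse = "")
    }, "")
  }
  for (b in seq_along(boxes)) {
    pos <- box_positions(boxes[[b]])
    if (any(pos < 1L | pos > length(ref)))
      stop("box ", b, " lies outside the sequence")
    ss <- enum_group(pos)
    out_seq <- c(out_seq, ss)
    out_box <- c(out_box, rep(b, length(ss)))
  }
  if (!is.null(bulge)) {
    ss <- enum_group(sort(bulge))
    out_seq <- c(out_seq, ss)
    out_box <- c(out_box, rep(NA_integer_, length(ss)))
  }
  out_seq <- c(out_seq, paste(ref, collapse = ""))
  out_box <- c(out_box, NA_integer_)
  data.frame(id = seq_along(out_seq), sequence = out_seq, box = out_box,
             stringsAsFactors = FALSE)
}

#' Mutate a structure to carry a given sequence
#'
#' @param x an `rna_structure`
#' @param sequence target sequence (same length as the structure's)
#' @export
mutate_to_sequence <- function(x, sequence) {
  new <- check_sequence(sequence)
  old <- check_sequence(rna_sequence(x))
  if (length(new) != length(old)) stop("sequence length mismatch")
  for (i in which(new != old)) x <- mutate_base(x, i, new[i])
  x
}

#' Synthetic maturation-efficiency dataset with a planted linear model
#'
#' Enumerates box mutants of a reference structure, builds each variant's
#' all-atom model by idealized base replacement, computes entropic
#' signatures at a declared scaling factor beta*, and sets the functional
#' readout to a planted linear combination of the signature plus Gaussian
#' noise.  The returned table uses the same dialect the regression pipeline
#' consumes (including a synthetic folding-energy column and
#' minimum-free-energy flags, both consumed as given, never computed from
#' thermodynamics).
#'
#' @param reference an `rna_structure` (typically from [build_hairpin()])
#' @param boxes mutation boxes over the reference sequence
#' @param planted_weights length-n_beads coefficient vector of the planted
#'   model (sparse for recovery experiments)
#' @param beta_star scaling factor at which the planted model acts
#' @param noise_sd Gaussian noise standard deviation, in units of the
#'   noiseless signal's standard deviation if `noise_relative = TRUE`
#' @param n_variants subsample size (`NULL` keeps the full enumeration)
#' @param seed RNG seed controlling subsampling and noise
#' @param betas scaling-factor grid at which signatures are cached for later
#'   grid scans
#' @param model elastic network flavor used for the signatures
#' @param noise_relative interpret `noise_sd` relative to the signal sd?
#' @return list with `variants` (annotated variant table with `efficiency`),
#'   `es` (variant x bead signature matrix at `beta_star`),
#'   `es_provider` (function(beta) over the cached grid), `reference`,
#'   `coarse` (reference coarse model) and `noise_ceiling_r2`
#' @export
make_maturation_dataset <- function(reference, boxes, planted_weights,
                                    beta_star = exp(0.25), noise_sd = 0.1,
                                    n_variants = NULL, seed = 1L,
                                    betas = beta_grid(center = beta_star),
                                    model = "encom",
                                    noise_relative = TRUE) {
  stopifnot(inherits(reference, "rna_structure"), noise_sd >= 0)
  refseq <- rna_sequence(reference)
  vars <- enumerate_variants(refseq, boxes)
  wt_row <- nrow(vars)
  set.seed(seed)
  if (!is.null(n_variants) && n_variants < nrow(vars)) {
    pick <- sort(sample(setdiff(seq_len(nrow(vars)), wt_row),
                        n_variants - 1L))
    vars <- vars[c(pick, wt_row), , drop = FALSE]
  }
  nv <- nrow(vars)
  cm0 <- coarse_grain(reference)
  if (length(planted_weights) != cm0$n)
    stop("planted_weights must have one entry per bead (", cm0$n, ")")
  if (!beta_star %in% betas) betas <- sort(c(betas, beta_star))
  types <- atom_types()
  eps <- interaction_matrix()
  es_arr <- array(NA_real_, c(nv, cm0$n, length(betas)))
  for (v in seq_len(nv)) {
    s <- mutate_to_sequence(reference, vars$sequence[v])
    fit <- enm(s, model = model, types = types, eps = eps)
    for (k in seq_along(betas))
      es_arr[v, , k] <- entropic_signature(fit, betas[k])$values
  }
  k_star <- which(abs(betas - beta_star) < 1e-12)[1L]
  signal <- as.numeric(es_arr[, , k_star] %*% planted_weights)
  ssd <- stats::sd(signal)
  eff_sd <- if (noise_relative) noise_sd * ssd else noise_sd
  noise <- stats::rnorm(nv, 0, eff_sd)
  vars$efficiency <- signal + noise
  vars$fold_energy <- stats::rnorm(nv)        # synthetic, uninformative
  vars$mfe_matches_wt <- TRUE
  vars <- annotate_variants(vars, refseq)
  tot <- stats::var(vars$efficiency)
  list(variants = vars,
       es = es_arr[, , k_star],
       es_provider = function(beta) {
         k <- which(abs(betas - beta) < 1e-9)
         if (!length(k)) stop("no cached signatures at beta = ", beta)
         es_arr[, , k[1L]]
       },
       betas = betas,
       reference = reference,
       coarse = cm0,
       planted_weights = planted_weights,
       beta_star = beta_star,
       noise_ceiling_r2 = if (tot > 0) 1 - eff_sd^2 / tot else NA_real_)
}
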