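# Synthetic variant tables for split logic (no structures needed).
make_variant_table <- function(ref, muts) {
  refv <- strsplit(ref, "")[[1]]
  seqs <- vapply(muts, function(pos) {
    v <- refv
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "U"), v[p])[1]
    paste(v, collapse = "")
  }, "")
  annotate_variants(data.frame(id = seq_along(seqs), sequence = seqs,
                               efficiency = seq_along(seqs) / 10,
                               fold_energy = 0, mfe_matches_wt = TRUE,
                               stringsAsFactors = FALSE), ref)
}

test_that("the position-disjoint split sorts variants by box layer", {
  ref <- paste(rep("G", 22), collapse = "")
  boxes <- hairpin_boxes(9, 4)    # bottom 1/22, middle 2/21, top 3/20, ...
  vt <- make_variant_table(ref, list(
    3L,            # top of box 1          -> train
    c(1L, 22L),    # bottom pair of box 1  -> train
    2L,            # middle of box 1       -> test
    c(2L, 21L),    # middle pair           -> test
    c(2L, 3L),     # middle + top          -> excluded
    5L))           # middle of box 2       -> test
  sp <- split_hard(vt, boxes)
  expect_setequal(sp$train$id, c(1L, 2L))
  expect_setequal(sp$test$id, c(3L, 4L, 6L))
  # leakage certificate: no shared mutated positions
  expect_length(intersect(unlist(sp$train$mutated_positions),
                          unlist(sp$test$mutated_positions)), 0L)
  # a variant outside every box trips the coverage check
  vt_bad <- make_variant_table(ref, list(11L))     # loop position
  expect_error(split_hard(vt_bad, boxes), "cover")
})

test_that("the low-redundancy split partitions by mutation count", {
  ref <- paste(rep("A", 10), collapse = "")
  vt <- make_variant_table(ref, list(1L, c(1L, 2L), c(1L, 2L, 3L),
                                     c(4L, 5L, 6L, 7L), integer()))
  sp <- split_inverted(vt)
  expect_setequal(sp$train$id, c(1L, 2L))
  expect_setequal(sp$test$id, c(3L, 4L))     # wild type (id 5) excluded
  vt$mfe_matches_wt[1] <- FALSE
  expect_false(1L %in% split_inverted(vt)$train$id)
})

test_that("sequence encoding is the +/-1 block code and round-trips", {
  expect_equal(encode_sequence("A"), c(1, -1, -1, -1))
  expect_equal(encode_sequence("AC"),
               c(1, -1, -1, -1, -1, 1, -1, -1))
  set.seed(6)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(1:12, 1), TRUE),
               collapse = "")
    enc <- encode_sequence(s)
    expect_true(all(enc %in% c(-1, 1)))
    expect_identical(decode_sequence(enc), s)
  }
  expect_error(encode_sequence("ACX"))
})

test_that("the lasso reduces to least squares at lambda zero", {
  set.seed(2)
  X <- matrix(rnorm(120 * 6), 120, 6)
  y <- X %*% c(1, -2, 0.5, 0, 0, 3) + rnorm(120, 0, 0.2)
  f <- fit_l1(X, y, lambda = 0)
  ols <- stats::lm.fit(cbind(1, scale(X)), y)$coefficients
  expect_equal(unname(coef(f)), unname(ols), tolerance = 1e-6)
})

test_that("the soft-threshold bound kills every coefficient", {
  set.seed(3)
  X <- matrix(rnorm(150 * 8), 150, 8)
  y <- rnorm(150)
  lmax <- max(abs(crossprod(scale(X), y - mean(y)))) / length(y)
  expect_true(all(fit_l1(X, y, lambda = lmax * 1.001)$coefficients == 0))
  expect_true(any(fit_l1(X, y, lambda = lmax * 0.8)$coefficients != 0))
})

test_that("zero-variance columns are excluded with coefficient exactly zero", {
  set.seed(4)
  X <- cbind(a = rnorm(60), b = rnorm(60), const = rep(2, 60))
  y <- X[, "a"] - X[, "b"] + rnorm(60, 0, 0.1)
  f <- fit_l1(X, y, lambda = 0.01)
  expect_identical(unname(f$coefficients["const"]), 0)
  expect_false("const" %in% paste(f$keep))
})

test_that("a planted sparse model is recovered from many noisy variants", {
  set.seed(9)
  n <- 2000L; pcols <- 258L
  X <- matrix(rnorm(n * pcols), n, pcols)
  w <- numeric(pcols)
  nz <- sample(pcols, 5L)
  w[nz] <- c(1, -1, 0.5, 2, -0.7)
  signal <- as.numeric(X %*% w)
  y <- signal + rnorm(n, 0, 0.1 * sd(signal))
  f <- fit_l1(X, y, lambda = 0.02)
  supp <- which(f$coefficients != 0)
  expect_true(all(nz %in% supp))
  expect_identical(sign(f$coefficients[nz]), sign(w[nz]))
})

test_that("standardization statistics are frozen at training time", {
  set.seed(5)
  Xtr <- matrix(rnorm(80 * 3), 80, 3)
  ytr <- Xtr %*% c(1, 2, -1) + rnorm(80, 0, 0.1)
  f <- fit_l1(Xtr, ytr, lambda = 1e-4)
  Xte <- matrix(rnorm(40 * 3, mean = 5), 40, 3)   # shifted test data
  manual <- scale(Xte, center = f$center, scale = f$scale) %*%
    f$coefficients + f$intercept
  expect_equal(predict(f, Xte), as.numeric(manual), tolerance = 1e-10)
})

test_that("predictive R-squared uses the test mean and can be negative", {
  y <- c(1, 2, 3, 4)
  expect_equal(predictive_r2(y, y), 1)
  expect_equal(predictive_r2(y, rep(mean(y), 4)), 0)
  expect_lt(predictive_r2(y, c(4, 3, 2, 1)), 0)
  expect_error(predictive_r2(rep(1, 3), c(1, 2, 3)), "variance")
})

test_that("a sequence-only model collapses to a constant on disjoint splits", {
  # encode variants whose test-set columns never move in training
  ref <- paste(rep("G", 12), collapse = "")
  train_muts <- lapply(1:40, function(k) sample(c(1:3, 10:12), 2))
  test_muts <- lapply(1:15, function(k) sample(5:7, 2))
  set.seed(8)
  vt <- make_variant_table(ref, c(train_muts, test_muts))
  enc <- t(vapply(vt$sequence, encode_sequence, numeric(48)))
  tr <- 1:40; te <- 41:55
  y <- rnorm(55)
  f <- fit_l1(enc[tr, ], y[tr], lambda = 2^-8)
  preds <- predict(f, enc[te, ])
  expect_lt(max(preds) - min(preds), 1e-8)        # constant predictor
  expect_lte(predictive_r2(y[te], preds), 0)
})

test_that("the noise-combination simulation is deterministic and ranks as defined", {
  set.seed(10)
  fe <- list(train = rnorm(60), test = rnorm(30))
  ytr <- fe$train * 0.8 + rnorm(60, 0, 0.4)
  yte <- fe$test * 0.8 + rnorm(30, 0, 0.4)
  s1 <- noise_combination_sim(fe, ytr, yte, observed_r2 = 0.99,
                              n_reps = 60, seed = 42)
  s2 <- noise_combination_sim(fe, ytr, yte, observed_r2 = 0.99,
                              n_reps = 60, seed = 42)
  expect_identical(s1$r2, s2$r2)
  expect_match(s1$p_label, "^< ")       # nothing beats 0.99
  low <- noise_combination_sim(fe, ytr, yte,
                               observed_r2 = stats::median(s1$r2) - 0.2,
                               n_reps = 60, seed = 42)
  expect_gt(low$p_value, 0.5)
})

test_that("coefficients map back onto beads with consistent sums", {
  fit <- fx_duplex_fit()
  cm <- fit$cm
  w <- numeric(cm$n); w[5] <- 1.5; w[10] <- -0.5
  l1 <- structure(list(coefficients = w, intercept = 0, lambda = 0,
                       center = rep(0, cm$n), scale = rep(1, cm$n),
                       keep = seq_len(cm$n)), class = "l1_fit")
  path <- tempfile(fileext = ".pdb")
  tab <- map_coefficients(l1, cm, file = path)
  expect_equal(attr(tab, "sum"), 1.0)
  expect_equal(attr(tab, "sum_abs"), 2.0)
  expect_equal(sum(tab$coefficient != 0), 2L)
  stamped <- read_rna_pdb(path)
  expect_equal(unique(stamped$atoms$bfactor[cm$members[[5]]]), 1.5,
               tolerance = 1e-6)
  zero <- map_coefficients(structure(list(coefficients = numeric(cm$n),
                                          intercept = 0, lambda = 0,
                                          center = rep(0, cm$n),
                                          scale = rep(1, cm$n),
                                          keep = integer()),
                                     class = "l1_fit"), cm)
  expect_equal(attr(zero, "sum"), 0)
  expect_equal(attr(zero, "sum_abs"), 0)
})

test_that("variant tables read from CSV with configurable columns", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("seq,eff,energy",
               "ACGU,0.5,-2.2",
               "ACGA,0.9,-1.1"), f)
  v <- read_variants(f, reference = "ACGU", sequence_col = "seq",
                     efficiency_col = "eff", energy_col = "energy")
  expect_equal(v$efficiency, c(0.5, 0.9))
  expect_equal(v$n_mutations, c(0L, 1L))
  expect_equal(v$mutated_positions[[2]], 4L)
  expect_error(read_variants(f, reference = "ACGU"), "sequence")
})
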