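test_that("superposition matches a quaternion-based independent implementation", {
  # Horn's closed-form quaternion solution as the oracle
  horn_rmsd <- function(p, q) {
    cp <- colMeans(p); cq <- colMeans(q)
    pp <- sweep(p, 2, cp); qq <- sweep(q, 2, cq)
    M <- crossprod(qq, pp)
    tr <- sum(diag(M))
    d <- c(M[2, 3] - M[3, 2], M[3, 1] - M[1, 3], M[1, 2] - M[2, 1])
    N <- rbind(c(tr, d), cbind(d, M + t(M) - tr * diag(3)))
    qv <- eigen(N, symmetric = TRUE)$vectors[, 1]
    w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
    R <- rbind(
      c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
      c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
      c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
    moved <- qq %*% t(R)
    sqrt(mean(rowSums((moved - pp)^2)))
  }
  set.seed(31)
  for (rep in 1:3) {
    p <- matrix(rnorm(30), 10, 3)
    q <- matrix(rnorm(30), 10, 3)
    expect_equal(superimpose(p, q)$rmsd, horn_rmsd(p, q), tolerance = 1e-8)
  }
})

test_that("superposition is exact for identical and rigidly moved copies", {
  x <- coarse_grain(fx_duplex())$coords
  s0 <- superimpose(x, x)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)
  rot <- random_rotation_seeded(3)
  s1 <- superimpose(x, sweep(x %*% rot, 2, c(5, 5, 5), "+"))
  expect_equal(s1$rmsd, 0, tolerance = 1e-10)
  expect_error(superimpose(x[1:2, ], x[1:2, ]), "3 points")
})

test_that("overlap is the absolute cosine and cumulative overlap is complete", {
  fit <- fx_duplex_fit()
  m <- fit$modes
  e7 <- m$vectors[, m$n_trivial + 1]
  expect_equal(overlap(e7, 3 * e7), 1)
  expect_equal(overlap(e7, -2 * e7), 1)
  expect_lt(overlap(e7, m$vectors[, m$n_trivial + 2]), 1e-10)
  expect_error(overlap(e7, 0 * e7), "zero")
  set.seed(12)
  for (rep in 1:5) {
    a <- rnorm(30); b <- rnorm(30)
    expect_equal(overlap(a, b),
                 abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)),
                 tolerance = 1e-12)
  }
  # completeness: displacement inside the span of the first two modes
  r <- m$vectors[, m$n_trivial + 1:2] %*% c(1.3, -0.4)
  expect_equal(cumulative_overlap(fit, r, 2), 1, tolerance = 1e-8)
  # monotone in the mode count, and 1 over the complete basis
  set.seed(13)
  rr <- rnorm(3 * fit$cm$n)
  cos <- sapply(1:10, function(k) cumulative_overlap(fit, rr, k))
  expect_true(all(diff(cos) >= -1e-12))
  expect_equal(cumulative_overlap(fit, rr, length(m$values),
                                  include_trivial = TRUE), 1,
               tolerance = 1e-8)
})

test_that("mode-count convention and the 2-Angstrom pair filter hold", {
  expect_equal(mode_count(100, 0.10), 30L)
  expect_equal(mode_count(3, 0.10), 1L)     # never less than one mode
  expect_equal(mode_count(100, 0.05), 15L)
  x <- coarse_grain(fx_duplex())$coords
  expect_false(conformational_pair_ok(x, x + 0.5))   # rmsd < 2 after fit
  big <- x; big[, 1] <- big[, 1] + seq(0, 8, length.out = nrow(big))
  expect_true(superimpose(x, big)$rmsd >= 2 &&
                conformational_pair_ok(x, big))
})

test_that("rigid-body-free PCA recovers a planted internal mode", {
  fit <- fx_duplex_fit()
  m <- fit$modes
  v <- m$vectors[, m$n_trivial + 1]
  ens <- make_ensemble(fit$cm, cbind(v), 1.5, n_conf = 20, seed = 11,
                       rigid_noise = TRUE)
  pc <- nrt_pca(ens)
  expect_gte(abs(sum(pc$components[, 1] * v)), 0.99)
  expect_gte(pc$c[1], 0.99)
  rt <- rnaenm:::rt_basis(fit$cm$coords)
  expect_lt(max(abs(crossprod(rt, pc$components))), 1e-8)
  expect_lt(max(abs(crossprod(pc$components) -
                      diag(ncol(pc$components)))), 1e-8)
})

test_that("two-conformation ensembles give a single rigid-body-free PC", {
  fit <- fx_duplex_fit()
  v <- fit$modes$vectors[, fit$modes$n_trivial + 2]
  ens <- make_ensemble(fit$cm, cbind(v), 1, n_conf = 2, seed = 5)
  pc <- nrt_pca(ens)
  expect_equal(ncol(pc$components), 1L)
  rt <- rnaenm:::rt_basis(fit$cm$coords)
  expect_lt(max(abs(crossprod(rt, pc$components))), 1e-8)
})

test_that("pure rigid-motion ensembles flag a degenerate correction", {
  cm <- coarse_grain(fx_duplex())
  set.seed(9)
  confs <- c(list(cm$coords), lapply(1:6, function(k)
    rnaenm:::apply_rigid(cm$coords, rnaenm:::random_rotation(),
                         rnorm(3, sd = 2))))
  expect_warning(pc <- nrt_pca(confs), "rigid-body")
  expect_true(pc$degenerate)
  expect_error(nrt_pca(list(cm$coords, cm$coords)), "zero-variance")
})

test_that("RMSIP and NCO match their brute-force double sums", {
  fit <- fx_duplex_fit()
  m <- fit$modes
  sel <- m$n_trivial + 1:4
  pcs <- structure(list(components = m$vectors[, m$n_trivial + 2:4],
                        c = c(0.6, 0.3, 0.1), v = c(0.6, 0.3, 0.1),
                        degenerate = FALSE), class = "pc_set")
  # brute force
  rms <- 0; nc <- 0
  for (j in 1:3) {
    cj <- pcs$c[j]
    s <- 0
    for (i in sel) {
      ip <- sum(m$vectors[, i] * pcs$components[, j])^2
      rms <- rms + ip
      s <- s + ip
    }
    nc <- nc + cj * s
  }
  expect_equal(rmsip(fit, pcs, 4), sqrt(rms / 4), tolerance = 1e-10)
  expect_equal(nco(fit, pcs, 4), nc, tolerance = 1e-10)
  # identical subspaces reach 1, orthogonal ones 0
  pcs_id <- structure(list(components = m$vectors[, sel],
                           c = rep(0.25, 4), v = rep(0.25, 4),
                           degenerate = FALSE), class = "pc_set")
  expect_equal(rmsip(fit, pcs_id, 4), 1, tolerance = 1e-10)
  expect_equal(nco(fit, pcs_id, 4), 1, tolerance = 1e-10)
  pcs_orth <- structure(list(components = m$vectors[, m$n_trivial + 10,
                                                    drop = FALSE],
                             c = 1, v = 1, degenerate = FALSE),
                        class = "pc_set")
  expect_equal(rmsip(fit, pcs_orth, 3), 0, tolerance = 1e-12)
  expect_equal(nco(fit, pcs_orth, 3), 0, tolerance = 1e-12)
})
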