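test_that("the analytic Hessian matches finite differences of the energy", {
  cm <- fx_toy3()
  beta <- beta_matrix(cm)
  p <- enm_control()
  H <- hessian_encom(cm, beta, p)
  E <- function(v) energy_encom(matrix(v, ncol = 3, byrow = TRUE), cm, beta, p)
  Hfd <- fd_hessian(E, as.numeric(t(cm$coords)))
  scale <- max(abs(H))
  expect_lt(max(abs(H - Hfd)) / scale, 1e-4)
})

test_that("energy terms behave as prescribed at and around the reference", {
  cm <- fx_toy3()
  beta <- beta_matrix(cm)
  p <- enm_control()
  # at the reference: harmonic terms zero, each long-range pair at its well
  lr <- rnaenm:::longrange_pairs(cm)
  vref <- energy_encom(cm$coords, cm, beta, p)
  expect_equal(vref, -sum(beta[lr] + p$alpha4), tolerance = 1e-10)
  # stretching one terminal bond by delta adds alpha1 * delta^2
  bnd <- cm$bonds[1L, ]                    # P1-S1: P1 is a graph leaf
  x <- cm$coords
  u <- (x[bnd[1L], ] - x[bnd[2L], ])
  u <- u / sqrt(sum(u^2))
  delta <- 0.05
  x2 <- x
  x2[bnd[1L], ] <- x2[bnd[1L], ] + delta * u
  dv_bonded <- p$alpha1 * delta^2
  v2 <- energy_encom(x2, cm, beta, p)
  # moving P1 also perturbs its long-range pairs; isolate with alpha4 tiny
  # and beta zeroed
  p_iso <- enm_control(alpha4 = 1e-12)
  expect_equal(energy_encom(x2, cm, beta * 0, p_iso) -
                 energy_encom(x, cm, beta * 0, p_iso),
               dv_bonded, tolerance = 1e-6)
  expect_gt(v2, vref)                      # full potential rises too
  # quadratic form: V(x0 + d) - V(x0) ~ 0.5 d' H d for small d
  set.seed(21)
  d <- rnorm(3 * cm$n, sd = 1e-3)
  H <- hessian_encom(cm, beta, p)
  vq <- 0.5 * as.numeric(t(d) %*% H %*% d)
  va <- energy_encom(matrix(as.numeric(t(cm$coords)) + d, ncol = 3,
                            byrow = TRUE), cm, beta, p) - vref
  expect_equal(va, vq, tolerance = 1e-2 * abs(vq) + 1e-10)
})

test_that("all three Hessians are PSD, translation-invariant, with 6 trivial modes", {
  h <- fx_duplex()
  for (mdl in c("encom", "cut_anm", "pd_anm")) {
    fit <- enm(h, model = mdl)
    H <- fit$hessian
    n <- fit$cm$n
    for (a in 1:3)
      expect_lt(max(abs(rowSums(H[, seq(a, 3 * n, by = 3)]))), 1e-7)
    expect_equal(fit$modes$n_trivial, 6L)
    expect_gt(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8 * max(abs(H)))
    # trivial modes project onto the analytic rigid-body subspace
    rt <- rnaenm:::rt_basis(fit$cm$coords)
    pr <- colSums((t(rt) %*% fit$modes$vectors[, 1:6])^2)
    expect_true(all(pr >= 0.99))
  }
})

test_that("eigen spectra are invariant under rigid transforms", {
  h <- fx_duplex()
  rot <- random_rotation_seeded(17)
  h2 <- h
  h2$xyz[[1]] <- sweep(h$xyz[[1]] %*% rot, 2, c(10, -4, 2), "+")
  for (mdl in c("encom", "cut_anm", "pd_anm")) {
    v1 <- enm(h, model = mdl)$modes$values
    v2 <- enm(h2, model = mdl)$modes$values
    expect_lt(max(abs(v1 - v2)) / max(v1), 1e-6)
  }
})

test_that("modes reconstruct the Hessian and are orthonormal", {
  fit <- fx_duplex_fit()
  m <- fit$modes
  expect_lt(max(abs(crossprod(m$vectors) - diag(ncol(m$vectors)))), 1e-8)
  Hrec <- m$vectors %*% (m$values * t(m$vectors))
  expect_lt(max(abs(Hrec - fit$hessian)) / max(abs(fit$hessian)), 1e-6)
})

test_that("cutoff network has the closed-form 2-body spectrum and monotone connectivity", {
  # two beads on the x axis within the cutoff: one nonzero eigenvalue 2*gamma
  cm <- fx_toy3()
  cm2 <- cm
  cm2$n <- 2L
  cm2$coords <- rbind(c(0, 0, 0), c(5, 0, 0))
  cm2$bonds <- matrix(integer(), 0, 2)
  H <- hessian_cut_anm(cm2, enm_control(gamma = 1.7, rc = 10))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-10), 1L)
  expect_equal(max(ev), 2 * 1.7, tolerance = 1e-12)
  v <- eigen(H, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(v[c(1, 4)]), c(1, 1) / sqrt(2), tolerance = 1e-10)
  # beyond the cutoff the off-diagonal block vanishes
  cm2$coords <- rbind(c(0, 0, 0), c(12, 0, 0))
  expect_warning(H2 <- hessian_cut_anm(cm2, enm_control(rc = 10)),
                 "disconnected")
  expect_equal(max(abs(H2)), 0)
  # growing the cutoff never disconnects pairs
  cm3 <- coarse_grain(fx_hairpin())
  nz <- function(rc) {
    H <- hessian_cut_anm(cm3, enm_control(rc = rc))
    sum(abs(H[1:3, -(1:3)]) > 0)
  }
  expect_lte(nz(6), nz(10))
  expect_lte(nz(10), nz(16))
})

test_that("power-dependent network follows its inverse-power law", {
  cm <- fx_toy3()
  x <- cm$coords
  p <- enm_control(power = 7)
  # hand-assembled 3-bead oracle with k_ij = r0^-7
  sub <- cm
  sub$n <- 3L
  sub$coords <- x[1:3, ]
  sub$bonds <- matrix(integer(), 0, 2)
  H <- hessian_pd_anm(sub, p)
  Hman <- matrix(0, 9, 9)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    i <- pair[1]; j <- pair[2]
    dx <- sub$coords[j, ] - sub$coords[i, ]
    r <- sqrt(sum(dx^2)); u <- dx / r
    k <- r^-7
    blk <- k * outer(u, u)
    ii <- 3 * (i - 1) + 1:3; jj <- 3 * (j - 1) + 1:3
    Hman[ii, jj] <- Hman[ii, jj] - blk
    Hman[jj, ii] <- Hman[jj, ii] - blk
    Hman[ii, ii] <- Hman[ii, ii] + blk
    Hman[jj, jj] <- Hman[jj, jj] + blk
  }
  expect_equal(H, Hman, tolerance = 1e-12, ignore_attr = TRUE)
  # doubling a pair distance divides its spring constant by 2^x
  k_of <- function(d) {
    s2 <- sub
    s2$coords <- rbind(c(0, 0, 0), c(d, 0, 0), c(0, 50, 0))
    -hessian_pd_anm(s2, p)[1, 4]
  }
  expect_equal(k_of(6) / k_of(3), 2^-7, tolerance = 1e-9)
  # x -> 0 reduces to a uniform fully connected network
  H0 <- hessian_pd_anm(sub, enm_control(power = 1e-9))
  kvals <- sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr) {
    i <- pr[1]; j <- pr[2]
    dx <- sub$coords[j, ] - sub$coords[i, ]
    u <- dx / sqrt(sum(dx^2))
    -H0[3 * (i - 1) + 1, 3 * (j - 1) + 1] / (u[1] * u[1])
  })
  expect_equal(kvals, rep(1, 3), tolerance = 1e-6)
})

test_that("mutating a base changes only the sequence-sensitive Hessian", {
  wt <- build_aform("GCGC", duplex = TRUE)
  mut <- mutate_base(wt, 2, "U", pin_bead = TRUE)
  cmw <- coarse_grain(wt)
  cmm <- coarse_grain(mut)
  expect_identical(cmw$coords, cmm$coords)
  expect_gt(max(abs(hessian_encom(cmw, beta_matrix(cmw)) -
                      hessian_encom(cmm, beta_matrix(cmm)))), 1e-3)
  expect_identical(hessian_cut_anm(cmw), hessian_cut_anm(cmm))
  expect_identical(hessian_pd_anm(cmw), hessian_pd_anm(cmm))
})

test_that("phosphate-only networks cannot feel base identity", {
  wt <- build_aform("GCGC", duplex = TRUE)
  mut <- mutate_base(wt, 2, "U")
  suppressWarnings({
    es_wt <- entropic_signature(enm(wt, model = "cut_anm", scheme = "p"),
                                exp(1))$values
    es_mut <- entropic_signature(enm(mut, model = "cut_anm", scheme = "p"),
                                 exp(1))$values
    es_ewt <- entropic_signature(enm(wt, scheme = "p"), exp(1))$values
    es_emut <- entropic_signature(enm(mut, scheme = "p"), exp(1))$values
  })
  expect_identical(es_wt, es_mut)
  expect_gt(max(abs(es_ewt - es_emut)), 0)
})

test_that("parameter validation and degenerate geometries error or warn", {
  expect_error(enm_control(alpha1 = -1))
  expect_error(enm_control(gamma = 0))
  cm <- fx_toy3()
  w <- capture_warnings(
    diagonalize(suppressWarnings(hessian_cut_anm(cm, enm_control(rc = 3))),
                cm$coords))
  expect_true(any(grepl("near-zero|rigid-body", w)))
})
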