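# The three densities of the embedding pipeline on the water dimer, plus the
# screening data for both modes.
dimer_fock_setup <- function() {
  with_cache("dimer_fock", {
    p <- dimer_partition()
    dens <- assemble_densities(p$ch$C_occ_active, p$ch$C_occ_inactive, p$S)
    Cv <- lowdin_orthonormalize(
      construct_paos(cbind(p$ch$C_occ_active, p$ch$C_occ_inactive), p$S, p$act),
      p$S)
    C_act <- cbind(p$ch$C_occ_active, Cv)
    Dsad <- sad_density(p$sys, p$pr$basis)
    list(p = p, dens = dens, C_act = C_act, Dsad = Dsad)
  })
}

tiny <- scf_thresholds(tau = 1e-300, tau_J = 1e-300, tau_K = 1e-300)

test_that("screened builds equal the dense contraction as thresholds vanish", {
  s <- dimer_fock_setup()
  densities <- list(SAD = s$Dsad, env = s$dens$D_env, active = s$dens$D_active)
  for (nm in names(densities)) {
    D <- densities[[nm]]
    scr <- screening_data(s$p$pr, s$p$pr$basis, C_active = s$C_act, D = D,
                          thresholds = tiny)
    oracle <- g_dense_oracle(s$p$pr, D)
    for (mode in c("active", "env")) {
      res <- combined_build(s$p$pr, D, scr, tiny, mode = mode)
      expect_lt(max(abs(res$J - oracle$J)), 1e-12)
      expect_lt(max(abs(res$K - oracle$K)), 1e-12)
    }
  }
})

test_that("default thresholds keep the MO-basis Fock deviation tiny", {
  s <- dimer_fock_setup()
  th <- scf_thresholds()
  scr <- screening_data(s$p$pr, s$p$pr$basis, C_active = s$C_act,
                        D = s$dens$D_env, thresholds = th)
  res <- combined_build(s$p$pr, s$dens$D_env, scr, th, mode = "env")
  oracle <- g_dense_oracle(s$p$pr, s$dens$D_env)
  expect_lt(max(abs(mo_transform(res$J - oracle$J, s$C_act))), 1e-10)
  expect_lt(max(abs(mo_transform(res$K - oracle$K, s$C_act))), 1e-8)
  expect_lt(max(abs(res$J - t(res$J))), 1e-10)
  expect_lt(max(abs(res$K - t(res$K))), 1e-10)
})

test_that("zero density gives zero matrices and empty counters", {
  s <- dimer_fock_setup()
  th <- scf_thresholds()
  D0 <- matrix(0, 14, 14)
  scr <- screening_data(s$p$pr, s$p$pr$basis, C_active = s$C_act, D = D0,
                        thresholds = th)
  resJ <- coulomb_screened(s$p$pr, D0, scr, th, mode = "active")
  resK <- exchange_screened(s$p$pr, D0, scr, th, mode = "active")
  expect_equal(resJ$J, D0)
  expect_equal(resK$K, D0)
  expect_equal(resJ$counter, 0)
  expect_equal(resK$counter, 0)
})

test_that("combined build equals the separate builds with fewer quartets", {
  s <- dimer_fock_setup()
  th <- scf_thresholds()
  set.seed(5)
  Drand <- matrix(rnorm(196, sd = 0.1), 14)
  Drand <- Drand + t(Drand)
  for (D in list(s$dens$D_env, s$dens$D_active, Drand)) {
    scr <- screening_data(s$p$pr, s$p$pr$basis, C_active = s$C_act, D = D,
                          thresholds = th)
    for (mode in c("active", "env")) {
      comb <- combined_build(s$p$pr, D, scr, th, mode = mode)
      sepJ <- coulomb_screened(s$p$pr, D, scr, th, mode = mode)
      sepK <- exchange_screened(s$p$pr, D, scr, th, mode = mode)
      expect_lt(max(abs(comb$J - sepJ$J)), 1e-12)
      expect_lt(max(abs(comb$K - sepK$K)), 1e-12)
      expect_lte(comb$counter, sepJ$counter + sepK$counter)
      expect_lt(max(abs(comb$J - t(comb$J))), 1e-10)
      expect_lt(max(abs(comb$K - t(comb$K))), 1e-10)
    }
  }
})

test_that("permutation-symmetric accumulation equals the unsymmetrized loop", {
  # exhaustive check on a small system: quadruple loop over all AO indices
  pr <- with_cache("pr_w", integral_provider(generate_water_monomer(), "sto-3g"))
  g <- eri_dense(pr)
  n <- 7
  set.seed(9)
  D <- matrix(rnorm(n * n), n)
  D <- D + t(D)
  Jref <- Kref <- matrix(0, n, n)
  for (a in 1:n) for (b in 1:n) for (cc in 1:n) for (d in 1:n) {
    Jref[a, b] <- Jref[a, b] + D[cc, d] * g[a, b, cc, d]
    Kref[a, cc] <- Kref[a, cc] + D[b, d] * g[a, b, cc, d]
  }
  scr <- screening_data(pr, pr$basis, C_active = NULL, D = D,
                        thresholds = tiny)
  res <- combined_build(pr, D, scr, tiny, mode = "active")
  expect_lt(max(abs(res$J - Jref)), 1e-12)
  expect_lt(max(abs(res$K - Kref)), 1e-12)
})

test_that("compiled and R reference builds agree, including counters", {
  s <- dimer_fock_setup()
  th <- scf_thresholds()
  oe <- list(S = s$p$S, h = s$p$h)
  toy <- toy_provider(s$p$sys, s$p$pr$basis, oe$S, oe$h, eri_dense(s$p$pr))
  for (mode in c("active", "env")) {
    scr_e <- screening_data(s$p$pr, s$p$pr$basis, C_active = s$C_act,
                            D = s$dens$D_env, thresholds = th)
    scr_t <- screening_data(toy, toy$basis, C_active = s$C_act,
                            D = s$dens$D_env, thresholds = th)
    a <- combined_build(s$p$pr, s$dens$D_env, scr_e, th, mode = mode)
    b <- combined_build(toy, s$dens$D_env, scr_t, th, mode = mode)
    expect_lt(max(abs(a$J - b$J)), 1e-11)
    expect_lt(max(abs(a$K - b$K)), 1e-11)
    expect_equal(a$counter, b$counter)
    expect_equal(a$counter_J, b$counter_J)
    expect_equal(a$counter_K, b$counter_K)
  }
})

test_that("dense oracle: bilinearity, symmetry, size guard, H2 cross-check", {
  pr <- with_cache("pr_h2", integral_provider(h2_system(), "sto-3g"))
  set.seed(13)
  D1 <- matrix(rnorm(4), 2); D1 <- D1 + t(D1)
  D2 <- matrix(rnorm(4), 2); D2 <- D2 + t(D2)
  ga <- g_dense_oracle(pr, 0.3 * D1 + 1.7 * D2)$G
  gb <- 0.3 * g_dense_oracle(pr, D1)$G + 1.7 * g_dense_oracle(pr, D2)$G
  expect_lt(max(abs(ga - gb)), 1e-10)
  G <- g_dense_oracle(pr, D1)$G
  expect_lt(max(abs(G - t(G))), 1e-12)

  big <- integral_provider(generate_water_chain(10), "sto-3g")
  expect_error(g_dense_oracle(big, diag(70)), "dense ERI")

  # energy assembled from the oracle G matches the closed-form reference
  ref <- h2_reference_rhf()
  oe <- one_electron_integrals(pr)
  G <- g_dense_oracle(pr, ref$D)$G
  E <- 1 / 1.4 + 2 * sum(oe$h * ref$D) + sum(ref$D * G)
  expect_equal(E, ref$energy, tolerance = 1e-8)
})

test_that("MO transformation: extraction, covariance, triple-loop oracle", {
  s <- dimer_fock_setup()
  G <- g_dense_oracle(s$p$pr, s$dens$D_env)$G
  # identity block extracts a submatrix
  Cid <- diag(14)[, 3:6]
  expect_equal(mo_transform(G, Cid), G[3:6, 3:6], ignore_attr = TRUE)
  # orthogonal rotation covariance
  set.seed(21)
  U <- qr.Q(qr(matrix(rnorm(81), 9)))
  Gmo <- mo_transform(G, s$C_act)
  expect_lt(max(abs(mo_transform(G, s$C_act %*% U) - crossprod(U, Gmo %*% U))),
            1e-12)
  # naive triple-loop summation
  ref <- matrix(0, 9, 9)
  for (p in 1:9) for (q in 1:9) {
    ref[p, q] <- sum(outer(s$C_act[, p], s$C_act[, q]) * G)
  }
  expect_lt(max(abs(Gmo - ref)), 1e-10)
  expect_error(mo_transform(G[1:3, 1:3], s$C_act), "dimension")
})

test_that("MO-to-MO update matches a fresh transform and warns on span drift", {
  s <- dimer_fock_setup()
  G <- g_dense_oracle(s$p$pr, s$dens$D_env)$G
  Gmo <- mo_transform(G, s$C_act)
  # limited by the ~1e-11 S-orthonormality of the Cholesky+PAO coefficients
  expect_lt(max(abs(mo_to_mo_update(Gmo, s$C_act, s$C_act, s$p$S) - Gmo)),
            1e-9)
  set.seed(23)
  U <- qr.Q(qr(matrix(rnorm(81), 9)))
  Cnew <- s$C_act %*% U
  upd <- mo_to_mo_update(Gmo, s$C_act, Cnew, s$p$S)
  expect_lt(max(abs(upd - mo_transform(G, Cnew))), 1e-10)
  # span drift: replace a column by something outside the active space
  Cbad <- Cnew
  Cbad[, 9] <- 0
  expect_warning(mo_to_mo_update(Gmo, s$C_act, Cbad, s$p$S), "span drift")
})
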