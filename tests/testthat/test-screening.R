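test_that("Cauchy-Schwarz bound holds for every quartet (exhaustive)", {
  for (key in c("pr_h2", "pr_w")) {
    pr <- with_cache(key, switch(key,
      pr_h2 = integral_provider(h2_system(), "sto-3g"),
      pr_w = integral_provider(generate_water_monomer(), "sto-3g")))
    g <- eri_dense(pr)
    sp <- schwarz_shell_pairs(pr, pr$basis, tau = 1e-12)
    ats <- pr$basis$ao_to_shell
    n <- pr$basis$n_ao
    Qao <- sp$Q[ats, ats]
    bound <- outer(as.vector(Qao), as.vector(Qao))
    expect_true(all(abs(matrix(g, n * n)) <= bound + 1e-12))
  }
})

test_that("master pair list contains exactly the pairs above tau", {
  pr <- with_cache("pr_w", integral_provider(generate_water_monomer(), "sto-3g"))
  sp <- schwarz_shell_pairs(pr, pr$basis, tau = 1e-12)
  ns <- nrow(sp$Q)
  expect_equal(nrow(sp$master_pairs), ns * (ns + 1) / 2)  # nothing pruned here
  expect_true(all(sp$master_pairs[, 1] >= sp$master_pairs[, 2]))
  # a tau above some pair norms prunes exactly those pairs
  tau <- stats::median(sp$Q[sp$master_pairs])
  sp2 <- schwarz_shell_pairs(pr, pr$basis, tau = tau)
  expect_true(all(sp2$Q[sp2$master_pairs] > tau))
  expect_equal(nrow(sp2$master_pairs), sum(sp$Q[sp$master_pairs] > tau))
  expect_error(schwarz_shell_pairs(pr, pr$basis, tau = 0), "positive")
})

test_that("per-shell MO-coefficient maxima match a brute-force double loop", {
  bas <- with_cache("pr_w", integral_provider(generate_water_monomer(),
                                              "sto-3g"))$basis
  # single nonzero entry
  C <- matrix(0, 7, 3)
  C[4, 2] <- 1  # an O 2p AO
  cs <- shell_max_mo_coefficients(C, bas)
  expect_equal(cs, c(0, 0, 1, 0, 0))
  # homogeneity
  set.seed(7)
  C <- matrix(rnorm(7 * 4), 7)
  expect_equal(shell_max_mo_coefficients(3.5 * C, bas),
               3.5 * shell_max_mo_coefficients(C, bas))
  # brute force
  ref <- vapply(seq_along(bas$shells), function(s) {
    m <- 0
    for (a in which(bas$ao_to_shell == s)) for (p in 1:4) {
      m <- max(m, abs(C[a, p]))
    }
    m
  }, numeric(1))
  expect_equal(shell_max_mo_coefficients(C, bas), ref)
  # NULL disables C-screening: all ones
  expect_equal(shell_max_mo_coefficients(NULL, bas), rep(1, 5))
})

test_that("shell-pair density maxima match a brute-force loop", {
  bas <- with_cache("pr_w", integral_provider(generate_water_monomer(),
                                              "sto-3g"))$basis
  expect_equal(shell_pair_density_max(matrix(0, 7, 7), bas), matrix(0, 5, 5))
  Did <- shell_pair_density_max(diag(7), bas)
  expect_equal(diag(Did), rep(1, 5))
  expect_equal(Did[1, 2], 0)
  set.seed(11)
  D <- matrix(rnorm(49), 7)
  D <- D + t(D)
  Ds <- shell_pair_density_max(D, bas)
  ref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    ref[i, j] <- max(abs(D[bas$ao_to_shell == i, bas$ao_to_shell == j]))
  }
  expect_equal(Ds, ref)
  expect_equal(Ds, t(Ds))
})

test_that("pair orderings are permutations with the documented sort keys", {
  set.seed(3)
  mp <- cbind(s1 = c(1, 2, 2, 3, 3, 3, 4, 4), s2 = c(1, 1, 2, 1, 2, 3, 2, 4))
  Q <- matrix(runif(16, 0.1, 2), 4); Q <- (Q + t(Q)) / 2
  Ds <- matrix(runif(16), 4); Ds <- (Ds + t(Ds)) / 2

  env <- order_pairs_for_coulomb_env(mp, Q, Ds)
  expect_setequal(env$order, seq_len(nrow(mp)))
  prods <- (Q[mp] * Ds[mp])[env$order]
  expect_true(all(diff(prods) <= 1e-15))
  expect_equal(prods[1], max(Q[mp] * Ds[mp]))
  expect_named(env$significant_s2)

  # equal products: stable tie-break by ascending (s1, s2)
  env_tie <- order_pairs_for_coulomb_env(mp, matrix(1, 4, 4), matrix(1, 4, 4))
  expect_equal(env_tie$order, seq_len(nrow(mp)))

  oa <- order_pairs_for_coulomb_active(mp)
  expect_equal(mp[oa, , drop = FALSE],
               mp[order(mp[, 1], mp[, 2]), , drop = FALSE])
  expect_equal(order_pairs_for_coulomb_active(mp[nrow(mp):1, ]),
               rev(seq_len(nrow(mp))))

  ox <- order_pairs_for_exchange(mp)
  key <- mp[ox, 2] * 100 + mp[ox, 1]
  expect_true(all(diff(key) > 0))

  # independent insertion-sort oracle on a random permutation
  perm <- sample(nrow(mp))
  mps <- mp[perm, , drop = FALSE]
  insertion_sort <- function(m, keyfun) {
    idx <- seq_len(nrow(m))
    for (i in seq_along(idx)[-1]) {
      j <- i
      while (j > 1 && keyfun(m[idx[j - 1], ]) > keyfun(m[idx[j], ])) {
        idx[c(j - 1, j)] <- idx[c(j, j - 1)]
        j <- j - 1
      }
    }
    idx
  }
  expect_equal(order_pairs_for_coulomb_active(mps),
               insertion_sort(mps, function(r) r[1] * 1000 + r[2]))
  expect_equal(order_pairs_for_exchange(mps),
               insertion_sort(mps, function(r) r[2] * 1000 + r[1]))
})

test_that("environment ordering puts the globally largest product first", {
  p <- dimer_partition()
  dens <- assemble_densities(p$ch$C_occ_active, p$ch$C_occ_inactive, p$S)
  sp <- schwarz_shell_pairs(p$pr, p$pr$basis, 1e-12)
  Ds <- shell_pair_density_max(dens$D_env, p$pr$basis)
  env <- order_pairs_for_coulomb_env(sp$master_pairs, sp$Q, Ds)
  first <- sp$master_pairs[env$order[1], ]
  expect_equal(sp$Q[first[1], first[2]] * Ds[first[1], first[2]],
               max(sp$Q[sp$master_pairs] * Ds[sp$master_pairs]))
})

test_that("master pair count grows linearly on separated water chains", {
  ns <- c(4, 6, 8)
  counts <- vapply(ns, function(n) {
    pr <- integral_provider(generate_water_chain(n, spacing = 10), "sto-3g")
    nrow(schwarz_shell_pairs(pr, pr$basis, 1e-12)$master_pairs)
  }, numeric(1))
  expect_lt(abs(loglog_slope(ns, counts) - 1), 0.15)
})

test_that("threshold object validates positivity", {
  expect_error(scf_thresholds(tau = 0), "positive")
  expect_error(scf_thresholds(tau_K = -1), "positive")
  th <- scf_thresholds()
  expect_equal(th$tau_J, 1e-12)
  expect_equal(th$tau_K, 1e-10)
  expect_equal(th$gradient, 1e-6)
  expect_equal(th$cholesky, 1e-1)
})
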