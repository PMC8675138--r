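test_that("XYZ reader handles the standard dialect and converts units", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "H 0 0 0"), f)
  sys <- read_xyz(f)
  expect_equal(sys$symbols, "H")
  expect_equal(sys$coords, matrix(0, 1, 3))

  # two H at 0.529177 Angstrom -> 1 Bohr separation
  writeLines(c("2", "comment", "H 0 0 0", "H 0 0 0.52917721"), f)
  sys <- read_xyz(f)
  expect_equal(sqrt(sum((sys$coords[1, ] - sys$coords[2, ])^2)), 1,
               tolerance = 1e-4)

  writeLines(c("2", "", "H 0 0 0", "H 0 0"), f)
  expect_error(read_xyz(f), "line 4")
  writeLines(c("2", "", "H 0 0 0", "H x y z"), f)
  expect_error(read_xyz(f), "line 4")
  writeLines(c("1", "", "Xx 0 0 0"), f)
  expect_error(read_xyz(f), "unknown element")
})

test_that("unit round-trip and nuclear repulsion oracle", {
  w <- generate_water_monomer()
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(w, f)
  w2 <- read_xyz(f)
  expect_equal(w2$coords, w$coords, tolerance = 1e-12)

  # brute-force pairwise Coulomb sum
  ref <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    ref <- ref + w$Z[i] * w$Z[j] / sqrt(sum((w$coords[i, ] - w$coords[j, ])^2))
  }
  expect_equal(w$h_nuc, ref, tolerance = 1e-12)
})

test_that("water chain fixture: geometry, bookkeeping, determinism", {
  expect_equal(length(generate_water_chain(1)$Z), 3L)
  ch <- generate_water_chain(5, spacing = 10)
  oo <- ch$coords[seq(1, 13, 3), ]
  doo <- as.matrix(dist(oo))
  expect_equal(min(doo[doo > 0]), 10, tolerance = 1e-10)
  expect_equal(ch$n_electrons, 50L)
  expect_equal(generate_water_chain(4), generate_water_chain(4))
  expect_error(generate_water_chain(0), "n must be")
  expect_error(generate_water_chain(2, spacing = -1), "spacing")
})

test_that("water cluster fixture: determinism and packing constraint", {
  c1 <- generate_water_cluster(8, seed = 11)
  c2 <- generate_water_cluster(8, seed = 11)
  expect_identical(c1$coords, c2$coords)
  expect_false(identical(c1$coords, generate_water_cluster(8, seed = 12)$coords))
  oo <- c1$coords[seq(1, 22, 3), ]
  doo <- as.matrix(dist(oo))
  expect_true(min(doo[doo > 0]) >= 5.2)
  expect_equal(length(generate_water_cluster(1, seed = 1)$Z), 3L)
  # active molecule is the one nearest the centroid
  act <- c1$active_atoms
  expect_length(act, 3L)
  expect_error(generate_water_cluster(50, seed = 1, min_oo = 50), "pack")
})

test_that("active-atom handling validates and supports shorthands", {
  ch <- generate_water_chain(3)
  expect_equal(set_active_atoms(ch, "first-molecule")$active_atoms, 1:3)
  expect_equal(set_active_atoms(ch, "all")$active_atoms, 1:9)
  expect_error(set_active_atoms(ch, c(1, 1)), "duplicates")
  expect_error(set_active_atoms(ch, 99), "range")
  expect_error(set_active_atoms(ch, integer(0)), "non-empty")
  expect_error(molecular_system("O", matrix(0, 1, 3), charge = 1), "odd")
})

test_that("one-electron integrals are symmetric, normalized, and match quadrature", {
  pr <- with_cache("pr_h2", integral_provider(h2_system(), "sto-3g"))
  oe <- one_electron_integrals(pr)
  expect_lt(max(abs(oe$S - t(oe$S))), 1e-12)
  expect_equal(diag(oe$S), rep(1, 2), tolerance = 1e-10)
  # independent grid-quadrature overlap
  expect_equal(quadrature_overlap(pr, 1, 2), oe$S[1, 2], tolerance = 1e-6)
  # p-function overlap in water
  prw <- with_cache("pr_w", integral_provider(generate_water_monomer(), "sto-3g"))
  Sw <- one_electron_integrals(prw)$S
  # AO 5 is O 2p_z, AO 6 is the first H 1s
  expect_equal(quadrature_overlap(prw, 5, 6), Sw[5, 6], tolerance = 1e-6)
  expect_equal(quadrature_overlap(prw, 3, 6), Sw[3, 6], tolerance = 1e-6)
})

test_that("engine one-electron and ERI s-blocks match independent closed forms", {
  pr <- with_cache("pr_h2", integral_provider(h2_system(), "sto-3g"))
  oe <- one_electron_integrals(pr)
  ref <- h2_reference_rhf()
  expect_equal(oe$S, ref$S, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(oe$h, ref$h, tolerance = 1e-10, ignore_attr = TRUE)
  g <- eri_dense(pr)
  expect_equal(as.vector(g), as.vector(ref$g), tolerance = 1e-10)
})

test_that("p-type primitives equal center-derivatives of s-type integrals", {
  # an unnormalized p_x primitive is d/dAx of the s primitive with the same
  # exponent; check the engine's (p_x s | s s) against a finite difference of
  # the closed-form s quartet
  a <- 1.1; b <- 0.6; cc <- 0.9; d <- 0.4
  A <- c(0.1, -0.2, 0.3); B <- c(0.8, 0.5, -0.1)
  C <- c(-0.4, 0.9, 0.2); D <- c(0.3, -0.7, 0.6)
  prim <- function(e) list(exps = e, coefs = 1)  # unnormalized single primitive
  s_quart <- function(Ax) {
    s_eri(prim(a), c(Ax, A[2], A[3]), prim(b), B, prim(cc), C, prim(d), D)
  }
  h <- 1e-4
  fd <- (s_quart(A[1] + h) - s_quart(A[1] - h)) / (2 * h)

  sys <- molecular_system(c("H", "H", "H", "H"), rbind(A, B, C, D),
                          unit = "bohr")
  basis <- shell_basis(sys, "sto-3g")
  basis$shells[[1]] <- list(atom = 1L, l = 1L, exps = a, coefs = 1,
                            center = A, ao_offset = 0L)
  basis$shells[[2]] <- list(atom = 2L, l = 0L, exps = b, coefs = 1,
                            center = B, ao_offset = 3L)
  basis$shells[[3]] <- list(atom = 3L, l = 0L, exps = cc, coefs = 1,
                            center = C, ao_offset = 4L)
  basis$shells[[4]] <- list(atom = 4L, l = 0L, exps = d, coefs = 1,
                            center = D, ao_offset = 5L)
  basis$cpp <- mlscf:::flatten_shells(basis$shells)
  blk <- mlscf:::cpp_eri_quartet(basis$cpp, 1, 2, 3, 4)
  # p_x primitive = (1/2a) d/dAx of the s primitive
  expect_equal(blk[1, 1, 1, 1], fd / (2 * a), tolerance = 1e-6)
})

test_that("shell quartets agree with the dense tensor and its symmetries", {
  prw <- with_cache("pr_w", integral_provider(generate_water_monomer(), "sto-3g"))
  g <- eri_dense(prw)
  basis <- prw$basis
  idx <- function(s) {
    sh <- basis$shells[[s]]
    sh$ao_offset + seq_len(((sh$l + 1) * (sh$l + 2)) %/% 2)
  }
  for (q in list(c(1, 1, 1, 1), c(3, 2, 4, 1), c(3, 3, 3, 3), c(4, 3, 2, 1))) {
    blk <- eri_shell_quartet(prw, q[1], q[2], q[3], q[4])
    expect_equal(as.vector(blk),
                 as.vector(g[idx(q[1]), idx(q[2]), idx(q[3]), idx(q[4]),
                             drop = FALSE]),
                 tolerance = 1e-12)
  }
  # transposed request related by axis permutation
  b1 <- eri_shell_quartet(prw, 3, 2, 4, 1)
  b2 <- eri_shell_quartet(prw, 2, 3, 4, 1)
  expect_lt(max(abs(aperm(b2, c(2, 1, 3, 4)) - b1)), 1e-12)
  expect_error(eri_shell_quartet(prw, 0, 1, 1, 1), "range")
  expect_error(eri_shell_quartet(prw, 1, 1, 1, 99), "range")

  # 8-fold permutational symmetry of the dense tensor
  set.seed(1)
  for (rep in 1:25) {
    q <- sample(7, 4, replace = TRUE)
    vals <- c(g[q[1], q[2], q[3], q[4]], g[q[2], q[1], q[3], q[4]],
              g[q[1], q[2], q[4], q[3]], g[q[2], q[1], q[4], q[3]],
              g[q[3], q[4], q[1], q[2]], g[q[4], q[3], q[1], q[2]],
              g[q[3], q[4], q[2], q[1]], g[q[4], q[3], q[2], q[1]])
    expect_lt(max(vals) - min(vals), 1e-12)
  }
})

test_that("two-level basis assigns the active basis to active atoms only", {
  d <- generate_water_chain(2)
  bas <- shell_basis(d, "sto-3g", active_basis = "6-31g")
  expect_equal(bas$atom_basis, c(rep("6-31g", 3), rep("sto-3g", 3)))
  # 6-31G water has 13 AOs, STO-3G water 7
  expect_equal(bas$n_ao, 20L)
  expect_error(shell_basis(generate_water_monomer(), "no-such-basis"),
               "unknown basis")
})

test_that("toy provider reproduces the engine behind the provider contract", {
  sys <- h2_system()
  pr <- with_cache("pr_h2", integral_provider(sys, "sto-3g"))
  oe <- one_electron_integrals(pr)
  toy <- toy_provider(sys, pr$basis, oe$S, oe$h, eri_dense(pr))
  expect_equal(one_electron_integrals(toy), oe)
  expect_equal(as.vector(eri_shell_quartet(toy, 1, 2, 1, 2)),
               as.vector(eri_shell_quartet(pr, 1, 2, 1, 2)))
  expect_equal(schwarz_matrix(toy), schwarz_matrix(pr), tolerance = 1e-12)
})
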