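# Shared fixtures (cached across test files) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())
with_cache <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

h2_system <- function() {
  molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)),
                   unit = "bohr", active_atoms = 1:2)
}

# Independent dense restricted HF oracle: full ERI tensor contraction and
# generalized eigenproblem only; no screened code path.
dense_rhf <- function(system, basis, n_occ, iters = 80L) {
  pr <- integral_provider(system, basis)
  oe <- one_electron_integrals(pr)
  n <- pr$basis$n_ao
  g <- eri_dense(pr)
  gm <- matrix(g, n * n)
  Km <- matrix(aperm(array(g, c(n, n, n, n)), c(1, 3, 2, 4)), n * n)
  X <- orthogonalizer(oe$S)
  D <- matrix(0, n, n)
  E <- 0
  for (it in seq_len(iters)) {
    J <- matrix(gm %*% as.vector(D), n)
    K <- matrix(Km %*% as.vector(D), n)
    E <- system$h_nuc + 2 * sum(oe$h * D) + sum(D * (2 * J - K))
    es <- eigen(crossprod(X, (oe$h + 2 * J - K) %*% X), symmetric = TRUE)
    C <- X %*% es$vectors[, order(es$values)[seq_len(n_occ)], drop = FALSE]
    D <- 0.5 * D + 0.5 * tcrossprod(C)
  }
  list(energy = E, D = D, S = oe$S, h = oe$h, provider = pr)
}

# Closed-form s-Gaussian integrals (contracted, normalized independently of
# the package's normalization code).
s_contraction <- function(exps, coefs) {
  cn <- coefs * (2 * exps / pi)^0.75
  p <- outer(exps, exps, "+")
  self <- sum(outer(cn, cn) * (pi / p)^1.5)
  list(exps = exps, coefs = cn / sqrt(self))
}

boys0 <- function(x) {
  ifelse(x < 1e-12, 1 - x / 3,
         0.5 * sqrt(pi / pmax(x, 1e-300)) * (2 * pnorm(sqrt(2 * pmax(x, 0))) - 1))
}

s_overlap <- function(ca, A, cb, B) {
  r2 <- sum((A - B)^2)
  tot <- 0
  for (i in seq_along(ca$exps)) for (j in seq_along(cb$exps)) {
    a <- ca$exps[i]; b <- cb$exps[j]; p <- a + b
    tot <- tot + ca$coefs[i] * cb$coefs[j] * (pi / p)^1.5 * exp(-a * b / p * r2)
  }
  tot
}

s_kinetic <- function(ca, A, cb, B) {
  r2 <- sum((A - B)^2)
  tot <- 0
  for (i in seq_along(ca$exps)) for (j in seq_along(cb$exps)) {
    a <- ca$exps[i]; b <- cb$exps[j]; p <- a + b; q <- a * b / p
    tot <- tot + ca$coefs[i] * cb$coefs[j] *
      q * (3 - 2 * q * r2) * (pi / p)^1.5 * exp(-q * r2)
  }
  tot
}

s_nuclear <- function(ca, A, cb, B, nuclei, charges) {
  tot <- 0
  for (i in seq_along(ca$exps)) for (j in seq_along(cb$exps)) {
    a <- ca$exps[i]; b <- cb$exps[j]; p <- a + b
    P <- (a * A + b * B) / p
    pre <- ca$coefs[i] * cb$coefs[j] * 2 * pi / p * exp(-a * b / p * sum((A - B)^2))
    for (k in seq_len(nrow(nuclei))) {
      tot <- tot - charges[k] * pre * boys0(p * sum((P - nuclei[k, ])^2))
    }
  }
  tot
}

s_eri <- function(ca, A, cb, B, cc, C, cd, D) {
  tot <- 0
  for (i in seq_along(ca$exps)) for (j in seq_along(cb$exps)) {
    a <- ca$exps[i]; b <- cb$exps[j]; p <- a + b
    P <- (a * A + b * B) / p
    eab <- exp(-a * b / p * sum((A - B)^2))
    for (k in seq_along(cc$exps)) for (l in seq_along(cd$exps)) {
      cg <- cc$exps[k]; dg <- cd$exps[l]; q <- cg + dg
      Qc <- (cg * C + dg * D) / q
      ecd <- exp(-cg * dg / q * sum((C - D)^2))
      alpha <- p * q / (p + q)
      tot <- tot + ca$coefs[i] * cb$coefs[j] * cc$coefs[k] * cd$coefs[l] *
        2 * pi^2.5 / (p * q * sqrt(p + q)) * eab * ecd *
        boys0(alpha * sum((P - Qc)^2))
    }
  }
  tot
}

# H2/STO-3G restricted HF assembled entirely from the closed forms above.
h2_reference_rhf <- function(R = 1.4) {
  cs <- s_contraction(c(3.42525091, 0.62391373, 0.16885540),
                      c(0.15432897, 0.53532814, 0.44463454))
  A <- c(0, 0, 0); B <- c(0, 0, R)
  nuc <- rbind(A, B); Z <- c(1, 1)
  ctr <- list(A, B)
  S <- h <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    S[i, j] <- s_overlap(cs, ctr[[i]], cs, ctr[[j]])
    h[i, j] <- s_kinetic(cs, ctr[[i]], cs, ctr[[j]]) +
      s_nuclear(cs, ctr[[i]], cs, ctr[[j]], nuc, Z)
  }
  g <- array(0, c(2, 2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    g[i, j, k, l] <- s_eri(cs, ctr[[i]], cs, ctr[[j]], cs, ctr[[k]], cs, ctr[[l]])
  }
  X <- orthogonalizer(S)
  D <- matrix(0, 2, 2); E <- 0
  for (it in 1:60) {
    J <- matrix(matrix(g, 4) %*% as.vector(D), 2)
    K <- matrix(matrix(aperm(g, c(1, 3, 2, 4)), 4) %*% as.vector(D), 2)
    E <- 1 / R + 2 * sum(h * D) + sum(D * (2 * J - K))
    es <- eigen(crossprod(X, (h + 2 * J - K) %*% X), symmetric = TRUE)
    C <- X %*% es$vectors[, order(es$values)[1], drop = FALSE]
    D <- tcrossprod(C)
  }
  list(energy = E, S = S, h = h, g = g, D = D)
}

# Gauss-Legendre nodes/weights on [lo, hi] via Golub-Welsch.
gauss_legendre <- function(n, lo = -1, hi = 1) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  es <- eigen(J, symmetric = TRUE)
  x <- es$values
  w <- 2 * es$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (x[ord] + 1) / 2 * (hi - lo) + lo,
       weights = w[ord] * (hi - lo) / 2)
}

# Numerical-quadrature overlap of two AOs of an engine provider, evaluated on
# a tensor-product Gauss-Legendre grid (independent of the analytic overlap).
quadrature_overlap <- function(provider, ao_i, ao_j, extent = 9, npts = 140) {
  basis <- provider$basis
  eval_ao <- function(ao, pts) {
    s <- basis$ao_to_shell[ao]
    sh <- basis$shells[[s]]
    comp <- ao - sh$ao_offset  # 1-based within shell
    rel <- sweep(pts, 2, sh$center)
    r2 <- rowSums(rel^2)
    ang <- if (sh$l == 0L) rep(1, nrow(pts)) else rel[, comp]
    val <- numeric(nrow(pts))
    for (ip in seq_along(sh$exps)) {
      val <- val + sh$coefs[ip] * exp(-sh$exps[ip] * r2)
    }
    val * ang
  }
  gl <- gauss_legendre(npts, -extent, extent)
  tot <- 0
  for (iz in seq_len(npts)) {
    pts <- cbind(rep(gl$nodes, each = npts), rep(gl$nodes, npts),
                 gl$nodes[iz])
    w2 <- as.vector(outer(gl$weights, gl$weights))
    tot <- tot + gl$weights[iz] *
      sum(w2 * eval_ao(ao_i, pts) * eval_ao(ao_j, pts))
  }
  tot
}

# log-log slope of counts against sizes
loglog_slope <- function(n, y) {
  unname(coef(lm(log(y) ~ log(n)))[2])
}

# Water dimer split used across test files: SAD-Fock idempotent total density
# partitioned with the first water active.
dimer_partition <- function() {
  with_cache("dimer_partition", {
    d <- generate_water_chain(2)
    pr <- integral_provider(d, "sto-3g")
    oe <- one_electron_integrals(pr)
    Dsad <- sad_density(d, pr$basis)
    ig <- idempotent_guess_via_fock(Dsad, pr, oe$h, oe$S, 10L)
    act <- aos_on_atoms(pr$basis, 1:3)
    ch <- restricted_cholesky_occupied(ig$D, oe$S, act, 1e-1)
    list(sys = d, pr = pr, S = oe$S, h = oe$h, D = ig$D, act = act, ch = ch)
  })
}
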