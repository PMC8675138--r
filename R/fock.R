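# Screened and dense two-electron Fock builds, and the MO transformations.
# Density convention throughout: half-density D = C_occ %*% t(C_occ) with
# S-orthonormal occupied columns, J_ab = sum_cd D_cd (ab|cd),
# K_ac = sum_bd D_bd (ab|cd), G = 2J - K.

fock_mode_orders <- function(screening, mode) {
  switch(mode,
    env = list(bra = screening$order_active, ket = screening$order_env,
               early = TRUE),
    active = list(bra = screening$order_active, ket = screening$order_active,
                  early = FALSE),
    stop("missing ordering for mode '", mode, "'"))
}

fock_build <- function(provider, D, screening, thresholds, mode,
                       do_J, do_K, exchange_order = FALSE) {
  ord <- fock_mode_orders(screening, mode)
  if (exchange_order) ord$bra <- ord$ket <- screening$order_exchange
  if (inherits(provider, "engine_provider")) {
    cpp_fock_screened(
      provider$basis$cpp, D, screening$Q, screening$C_shell, screening$D_shell,
      as.integer(screening$master_pairs[, 1L]),
      as.integer(screening$master_pairs[, 2L]),
      as.integer(ord$bra), as.integer(ord$ket),
      thresholds$tau_J, thresholds$tau_K, do_J, do_K,
      ord$early && do_J)
  } else {
    r_fock_screened(provider, D, screening, thresholds$tau_J, thresholds$tau_K,
                    do_J, do_K, ord$bra, ord$ket, ord$early && do_J)
  }
}

#' Screened Coulomb build
#'
#' Direct build of `J[a,b] = sum_cd D[c,d] (ab|cd)` restricted to shell
#' quartets whose Cauchy-Schwarz bound, weighted by the per-shell active-MO
#' coefficient maxima and the shell-pair density maxima, exceeds `tau_J` for
#' at least one of the symmetry-equivalent targets accumulated from the
#' quartet. In `mode = "env"` the ket list is traversed in descending
#' `Q * D_shell` order with an early exit; in `mode = "active"` in ascending
#' canonical order with cycle-on-fail.
#'
#' @param provider an integral provider (the build requests shell quartets
#'   from the package engine).
#' @param D symmetric AO half-density matrix.
#' @param screening a [screening_data()] object.
#' @param thresholds a [scf_thresholds()].
#' @param mode `"env"` or `"active"`.
#' @return List with the symmetric matrix `J` and `counter`, the number of
#'   shell quartets actually computed.
#' @export
coulomb_screened <- function(provider, D, screening,
                             thresholds = scf_thresholds(),
                             mode = c("active", "env")) {
  mode <- match.arg(mode)
  res <- fock_build(provider, D, screening, thresholds, mode,
                    do_J = TRUE, do_K = FALSE)
  list(J = res$J, counter = res$n_quartets_J)
}

#' Screened exchange build
#'
#' Direct build of `K[a,c] = sum_bd D[b,d] (ab|cd)` under the exchange neglect
#' condition (threshold `tau_K`), with the pair list traversed in ascending
#' `s2` order and cycle-on-fail.
#'
#' @inheritParams coulomb_screened
#' @return List with the symmetric matrix `K` and `counter`.
#' @export
exchange_screened <- function(provider, D, screening,
                              thresholds = scf_thresholds(),
                              mode = c("active", "env")) {
  mode <- match.arg(mode)
  res <- fock_build(provider, D, screening, thresholds, mode,
                    do_J = FALSE, do_K = TRUE, exchange_order = TRUE)
  list(K = res$K, counter = res$n_quartets_K)
}

#' Combined screened Coulomb + exchange build
#'
#' Single construction loop using the Coulomb loop structure with the
#' exchange conditions added: each shell quartet is computed at most once and
#' accumulated to both matrices.
#'
#' @inheritParams coulomb_screened
#' @return List with `J`, `K`, `G = 2J - K`, and the counters
#'   `counter_J`, `counter_K`, `counter` (quartets computed).
#' @export
combined_build <- function(provider, D, screening,
                           thresholds = scf_thresholds(),
                           mode = c("active", "env")) {
  mode <- match.arg(mode)
  res <- fock_build(provider, D, screening, thresholds, mode,
                    do_J = TRUE, do_K = TRUE)
  list(J = res$J, K = res$K, G = 2 * res$J - res$K,
       counter_J = res$n_quartets_J, counter_K = res$n_quartets_K,
       counter = res$n_quartets)
}

#' Dense two-electron build (reference oracle)
#'
#' Unscreened `G = 2J - K` by full four-index contraction of the dense ERI
#' tensor; refuses systems whose tensor would be too large.
#'
#' @param provider an integral provider.
#' @param D symmetric AO half-density.
#' @param max_ao size guard forwarded to [eri_dense()].
#' @return List with `J`, `K`, `G`.
#' @export
g_dense_oracle <- function(provider, D, max_ao = 64L) {
  n <- provider$basis$n_ao
  g <- eri_dense(provider, max_ao = max_ao)
  gm <- matrix(g, n * n)
  J <- matrix(gm %*% as.vector(D), n)
  Km <- matrix(aperm(array(g, c(n, n, n, n)), c(1, 3, 2, 4)), n * n)
  K <- matrix(Km %*% as.vector(D), n)
  list(J = J, K = K, G = 2 * J - K)
}

#' AO-to-MO transformation of a Fock contribution
#'
#' @param G_AO symmetric AO matrix.
#' @param C_active S-orthonormal active MO coefficients.
#' @return `t(C) %*% G_AO %*% C`.
#' @export
mo_transform <- function(G_AO, C_active) {
  if (nrow(G_AO) != nrow(C_active)) stop("dimension mismatch in mo_transform")
  crossprod(C_active, G_AO %*% C_active)
}

#' MO-to-MO update of a stored environment Fock contribution
#'
#' Rotates a matrix stored in an old active MO basis into a new one via
#' `U = t(C_old) %*% S %*% C_new`. Exact when the two coefficient sets span
#' the same space; a span-drift warning is emitted when `t(U) %*% U` deviates
#' from the identity by more than 1e-6.
#'
#' @param G_env_MO_old matrix in the old MO basis.
#' @param C_old,C_new S-orthonormal coefficient sets.
#' @param S AO overlap matrix.
#' @return The matrix in the new MO basis.
#' @export
mo_to_mo_update <- function(G_env_MO_old, C_old, C_new, S) {
  U <- crossprod(C_old, S %*% C_new)
  drift <- max(abs(crossprod(U) - diag(ncol(U))))
  if (drift > 1e-6) {
    warning(sprintf("active-space span drift %.2e in MO-to-MO update", drift))
  }
  crossprod(U, G_env_MO_old %*% U)
}

# R reference implementation of the screened build, used for non-engine
# providers (e.g. the dense toy provider) and as a readable mirror of the
# compiled loop. Same pair-list traversal, screens, early exit, and explicit
# permutation accumulation.
r_fock_screened <- function(provider, D, screening, tau_J, tau_K,
                            do_J, do_K, bra_order, ket_order, early_exit) {
  basis <- provider$basis
  n <- basis$n_ao
  J <- K <- matrix(0, n, n)
  Q <- screening$Q
  Cs <- screening$C_shell
  Ds <- screening$D_shell
  mp <- screening$master_pairs
  npair <- nrow(mp)
  nJ <- nK <- ntot <- 0
  if (npair == 0L) {
    return(list(J = J, K = K, n_quartets_J = 0, n_quartets_K = 0,
                n_quartets = 0))
  }
  maxQD <- max(Q[mp] * Ds[mp])
  maxQ <- max(Q[mp])
  maxD <- max(Ds[mp])
  maxC <- max(Cs)
  # suffix maxima along the ket ordering (sound early exit for both Coulomb
  # targets, at the bra pair and at the ket pair)
  qd_ket <- (Q[mp] * Ds[mp])[ket_order]
  ccq_ket <- (Cs[mp[, 1L]] * Cs[mp[, 2L]] * Q[mp])[ket_order]
  suf_qd <- rev(cummax(rev(qd_ket)))
  suf_ccq <- rev(cummax(rev(ccq_ket)))
  shell_aos <- lapply(seq_along(basis$shells),
                      function(s) which(basis$ao_to_shell == s))
  for (bra in bra_order) {
    s1 <- mp[bra, 1L]; s2 <- mp[bra, 2L]
    C1 <- Cs[s1]; C2 <- Cs[s2]; Q12 <- Q[s1, s2]
    braJ <- do_J && (C1 * C2 * Q12 * maxQD > tau_J ||
                     Ds[s1, s2] * Q12 * suf_ccq[1L] > tau_J)
    braK <- do_K && (max(C1, C2) * maxC * Q12 * maxQ * maxD > tau_K)
    if (!braJ && !braK) next
    jAlive <- braJ
    for (ik in seq_along(ket_order)) {
      ket <- ket_order[ik]
      if (ket > bra) next
      s3 <- mp[ket, 1L]; s4 <- mp[ket, 2L]
      C3 <- Cs[s3]; C4 <- Cs[s4]; Q34 <- Q[s3, s4]
      if (jAlive && early_exit &&
          C1 * C2 * Q12 * suf_qd[ik] <= tau_J &&
          Ds[s1, s2] * Q12 * suf_ccq[ik] <= tau_J) {
        jAlive <- FALSE
        if (!braK) break
      }
      incJ <- jAlive &&
        max(C1 * C2 * Ds[s3, s4], C3 * C4 * Ds[s1, s2]) * Q12 * Q34 > tau_J
      kb <- max(C1 * C3 * Ds[s2, s4], C1 * C4 * Ds[s2, s3],
                C2 * C3 * Ds[s1, s4], C2 * C4 * Ds[s1, s3])
      incK <- braK && kb * Q12 * Q34 > tau_K
      if (!incJ && !incK) next
      blk <- eri_shell_quartet(provider, s1, s2, s3, s4)
      ntot <- ntot + 1
      if (incJ) nJ <- nJ + 1
      if (incK) nK <- nK + 1
      a1 <- shell_aos[[s1]]; a2 <- shell_aos[[s2]]
      a3 <- shell_aos[[s3]]; a4 <- shell_aos[[s4]]
      for (i1 in seq_along(a1)) for (i2 in seq_along(a2)) {
        a <- a1[i1]; b <- a2[i2]
        if (s1 == s2 && b > a) next
        iab <- a * (a + 1) / 2 + b
        for (i3 in seq_along(a3)) for (i4 in seq_along(a4)) {
          cc <- a3[i3]; d <- a4[i4]
          if (s3 == s4 && d > cc) next
          if (bra == ket && cc * (cc + 1) / 2 + d > iab) next
          g <- blk[i1, i2, i3, i4]
          if (g == 0) next
          perms <- unique(list(c(a, b, cc, d), c(b, a, cc, d),
                               c(a, b, d, cc), c(b, a, d, cc),
                               c(cc, d, a, b), c(d, cc, a, b),
                               c(cc, d, b, a), c(d, cc, b, a)))
          for (pm in perms) {
            if (incJ) J[pm[1L], pm[2L]] <- J[pm[1L], pm[2L]] + D[pm[3L], pm[4L]] * g
            if (incK) K[pm[1L], pm[3L]] <- K[pm[1L], pm[3L]] + D[pm[2L], pm[4L]] * g
          }
        }
      }
    }
  }
  list(J = J, K = K, n_quartets_J = nJ, n_quartets_K = nK, n_quartets = ntot)
}
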