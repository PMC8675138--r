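# Starting guesses for the idempotent total density: superposition of atomic
# densities (SAD, followed by one Fock diagonalization) and superposition of
# molecular densities (SMD, followed by McWeeny purification).

.sad_cache <- new.env(parent = emptyenv())

# A single free atom as a system, bypassing the closed-shell check (atomic
# guesses use fractional occupations).
atom_system <- function(symbol) {
  Z <- element_number(symbol)
  structure(list(symbols = symbol, Z = Z, coords = matrix(0, 1, 3),
                 charge = 0L, active_atoms = 1L, n_electrons = Z, h_nuc = 0),
            class = "MolecularSystem")
}

# Spherically averaged atomic Hartree-Fock half-density with fractional
# occupations spread uniformly over degenerate shells (so p^4 oxygen occupies
# each 2p component by 4/3). Damped fixed-point iteration on small dense
# matrices; cached per (element, basis).
atomic_half_density <- function(symbol, basis_name) {
  key <- paste(symbol, tolower(basis_name), sep = "/")
  if (!is.null(.sad_cache[[key]])) return(.sad_cache[[key]])
  sys <- atom_system(symbol)
  pr <- integral_provider(sys, basis_name)
  oe <- one_electron_integrals(pr)
  X <- orthogonalizer(oe$S)
  n <- pr$basis$n_ao
  n_elec <- sys$Z
  D <- matrix(0, n, n)
  for (it in seq_len(500)) {
    G <- g_dense_oracle(pr, D)$G
    Fm <- oe$h + G
    es <- eigen(crossprod(X, Fm %*% X), symmetric = TRUE)
    ord <- order(es$values)
    C <- X %*% es$vectors[, ord, drop = FALSE]
    eps <- es$values[ord]
    occ <- aufbau_fractional(eps, n_elec)
    D_new <- C %*% (diag(occ / 2, length(occ)) %*% t(C))
    delta <- max(abs(D_new - D))
    D <- 0.5 * D + 0.5 * D_new
    if (delta < 1e-9) break
  }
  .sad_cache[[key]] <- D
  D
}

# Occupations (0..2 per orbital) filling n_elec electrons in ascending orbital
# energy, spread uniformly over degenerate groups.
aufbau_fractional <- function(eps, n_elec, degeneracy_tol = 1e-6) {
  occ <- numeric(length(eps))
  groups <- cumsum(c(TRUE, diff(eps) > degeneracy_tol))
  left <- n_elec
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cap <- 2 * length(idx)
    fill <- min(left, cap)
    occ[idx] <- fill / length(idx)
    left <- left - fill
    if (left <= 0) break
  }
  occ
}

#' Superposition of atomic densities (SAD) guess
#'
#' Block-diagonal half-density assembled from spherically averaged
#' fractional-occupation atomic Hartree-Fock densities. The result satisfies
#' the trace condition but is generally not idempotent; it is turned into an
#' idempotent density by [idempotent_guess_via_fock()].
#'
#' @param system a [molecular_system()].
#' @param basis the [shell_basis()] of the full system (its per-atom basis
#'   assignment is respected, including two-level bases).
#' @return Symmetric `n_ao x n_ao` half-density matrix.
#' @export
sad_density <- function(system, basis) {
  D <- matrix(0, basis$n_ao, basis$n_ao)
  for (ia in seq_along(system$Z)) {
    rows <- aos_on_atoms(basis, ia)
    D[rows, rows] <- atomic_half_density(system$symbols[ia],
                                         basis$atom_basis[ia])
  }
  if (system$charge != 0L) {
    # uniform rescale so Tr(D S) matches the ion's occupied count
    pr <- integral_provider(system, basis)
    S <- one_electron_integrals(pr)$S
    D <- D * (system$n_electrons / 2) / sum(D * S)
  }
  D
}

#' Idempotent density from a guess via one Fock diagonalization
#'
#' Builds the Fock matrix of the (non-idempotent) guess density, diagonalizes
#' it in the linear-dependence-cleaned orthonormal basis, and occupies the
#' `n_occ` lowest orbitals (ties at the aufbau boundary are broken by
#' eigenvalue order then index, with a warning).
#'
#' @param D_guess symmetric AO half-density (e.g. from [sad_density()]).
#' @param provider an integral provider.
#' @param h core Hamiltonian.
#' @param S overlap matrix.
#' @param n_occ number of doubly occupied orbitals.
#' @param thresholds a [scf_thresholds()].
#' @return List with `C_occ` (S-orthonormal occupied coefficients), the
#'   idempotent density `D`, the full coefficient set `C_all`, and `counter`
#'   (shell quartets computed for the Fock build).
#' @export
idempotent_guess_via_fock <- function(D_guess, provider, h, S, n_occ,
                                      thresholds = scf_thresholds()) {
  scr <- screening_data(provider, provider$basis, C_active = NULL,
                        D = D_guess, thresholds = thresholds)
  gb <- combined_build(provider, D_guess, scr, thresholds, mode = "active")
  Fm <- h + gb$G
  X <- orthogonalizer(S, thresholds$lindep)
  es <- eigen(crossprod(X, Fm %*% X), symmetric = TRUE)
  ord <- order(es$values)
  eps <- es$values[ord]
  if (n_occ < length(eps) && eps[n_occ + 1L] - eps[n_occ] < 1e-10) {
    warning("degenerate HOMO-LUMO at the aufbau boundary; ",
            "occupying by eigenvalue order then index")
  }
  C_all <- X %*% es$vectors[, ord, drop = FALSE]
  C_occ <- C_all[, seq_len(n_occ), drop = FALSE]
  list(C_occ = C_occ, D = tcrossprod(C_occ), C_all = C_all,
       counter = gb$counter)
}

#' Superposition of molecular densities (SMD) guess
#'
#' Converges a restricted Hartree-Fock density for each fragment in its own
#' AO sub-basis and assembles the fragment half-densities block-diagonally in
#' the full AO ordering. The result is idempotent only in the limit of
#' non-overlapping fragments; [mcweeny_purify()] restores idempotency.
#'
#' @param system a [molecular_system()].
#' @param fragments list of 1-based atom index vectors partitioning all
#'   atoms, or `"auto"` for covalent-radius connectivity detection.
#' @param basis,active_basis basis-set names as in [shell_basis()].
#' @param thresholds a [scf_thresholds()].
#' @return Symmetric `n_ao x n_ao` half-density matrix.
#' @export
smd_density <- function(system, fragments = "auto", basis = "sto-3g",
                        active_basis = NULL, thresholds = scf_thresholds()) {
  if (identical(fragments, "auto")) fragments <- detect_fragments(system)
  flat <- sort(unlist(fragments))
  if (!identical(flat, seq_along(system$Z))) {
    stop("fragments must partition all atoms exactly once")
  }
  full_basis <- shell_basis(system, basis, active_basis)
  D <- matrix(0, full_basis$n_ao, full_basis$n_ao)
  for (fi in seq_along(fragments)) {
    atoms <- sort(fragments[[fi]])
    sub <- molecular_system(system$symbols[atoms],
                            system$coords[atoms, , drop = FALSE],
                            unit = "bohr", charge = 0L)
    sub_active <- which(atoms %in% system$active_atoms)
    if (length(sub_active)) sub <- set_active_atoms(sub, sub_active)
    hf <- tryCatch(
      run_hf(sub, basis = basis,
             active_basis = if (length(sub_active)) active_basis else NULL,
             thresholds = thresholds),
      error = function(e) {
        stop("SCF for fragment ", fi, " (atoms ",
             paste(atoms, collapse = ","), ") failed: ",
             conditionMessage(e))
      })
    rows <- aos_on_atoms(full_basis, atoms)
    D[rows, rows] <- hf$D
  }
  D
}

#' McWeeny purification of a near-idempotent density
#'
#' Iterates the metric-consistent cubic map
#' `D <- 3 D S D - 2 D S D S D` until the idempotency residual
#' `max |D S D - D|` falls below `tol`. Convergence is quadratic from a
#' near-idempotent start and the trace is preserved at the fixed point.
#'
#' @param D symmetric near-idempotent half-density.
#' @param S overlap matrix.
#' @param tol residual bound (default 1e-10).
#' @param max_iter iteration cap (default 50).
#' @return The purified density, with attribute `"residuals"` holding the
#'   residual after each sweep.
#' @export
mcweeny_purify <- function(D, S, tol = 1e-10, max_iter = 50L) {
  residuals <- numeric(0)
  for (it in seq_len(max_iter)) {
    DS <- D %*% S
    res <- max(abs(DS %*% D - D))
    residuals <- c(residuals, res)
    if (res <= tol) {
      attr(D, "residuals") <- residuals
      return(D)
    }
    DSD <- DS %*% D
    D <- 3 * DSD - 2 * DS %*% DSD
    D <- (D + t(D)) / 2
  }
  stop(sprintf(
    "McWeeny purification did not reach %g in %d iterations (residual %g)",
    tol, max_iter, residuals[length(residuals)]))
}
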