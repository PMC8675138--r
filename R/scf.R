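# SCF machinery shared by the conventional restricted HF reference and the
# multilevel driver: energy functional, gradient, Roothaan-Hall step, DIIS.

#' Multilevel Hartree-Fock energy functional
#'
#' `E = h_nuc + 2 Tr[h (D_a + D_e)] + Tr[(D_a + D_e) G_total]` under the
#' half-density convention (`G_total = G(D_a + D_e) = 2J - K`). The value is
#' invariant under any relabeling of active/environment that leaves the total
#' density unchanged.
#'
#' @param h core Hamiltonian.
#' @param D_a,D_e active and environment half-densities.
#' @param G_total two-electron matrix of the total density.
#' @param h_nuc nuclear repulsion energy.
#' @return Total energy, Hartree.
#' @export
mlhf_energy <- function(h, D_a, D_e, G_total, h_nuc = 0) {
  for (nm in c("h", "D_a", "D_e", "G_total")) {
    M <- get(nm)
    if (max(abs(M - t(M))) > 1e-8) stop("asymmetric input matrix ", nm)
  }
  D <- D_a + D_e
  h_nuc + 2 * sum(h * D) + sum(D * G_total)
}

#' SCF gradient norm
#'
#' Maximum absolute element of the occupied x virtual block of the MO-basis
#' Fock matrix; zero at convergence (and trivially zero when there are no
#' virtuals).
#'
#' @param F_MO Fock matrix in the current MO basis, occupied block first.
#' @param n_occ_a number of occupied columns.
#' @return Non-negative scalar.
#' @export
scf_gradient <- function(F_MO, n_occ_a) {
  n <- ncol(F_MO)
  if (n_occ_a >= n || n_occ_a == 0L) return(0)
  max(abs(F_MO[seq_len(n_occ_a), seq(n_occ_a + 1L, n), drop = FALSE]))
}

#' Roothaan-Hall step in the active MO basis
#'
#' Diagonalizes the (active-dimension) MO Fock matrix and rotates the current
#' coefficients by its eigenvectors in ascending eigenvalue order; the lowest
#' eigenvectors become the new occupied orbitals. S-orthonormality is
#' preserved since the rotation is orthogonal.
#'
#' @param F_MO symmetric MO-basis Fock matrix.
#' @param C_active current active MO coefficients.
#' @return List with the rotated `C_active`, the ascending `mo_energies`, and
#'   the rotation matrix `V`.
#' @export
roothaan_hall_step <- function(F_MO, C_active) {
  es <- eigen((F_MO + t(F_MO)) / 2, symmetric = TRUE)
  ord <- order(es$values)
  V <- es$vectors[, ord, drop = FALSE]
  list(C_active = C_active %*% V, mo_energies = es$values[ord], V = V)
}

#' DIIS extrapolation
#'
#' Solves the standard least-squares problem with a sum-to-one constraint on
#' the extrapolation coefficients over the stored (Fock, error) pairs; with a
#' single entry the Fock matrix is returned unchanged. A singular DIIS system
#' drops the oldest entry and retries.
#'
#' @param history list of `list(F = <matrix>, error = <numeric>)` entries,
#'   oldest first; error vectors are the flattened occupied-virtual gradient
#'   blocks.
#' @return The extrapolated Fock matrix, with attribute `"coefficients"`.
#' @export
diis_extrapolate <- function(history) {
  m <- length(history)
  if (m == 0L) stop("empty DIIS history")
  if (m == 1L) {
    out <- history[[1L]]$F
    attr(out, "coefficients") <- 1
    return(out)
  }
  B <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(i)) {
      B[i, j] <- B[j, i] <- sum(history[[i]]$error * history[[j]]$error)
    }
  }
  A <- rbind(cbind(B, 1), c(rep(1, m), 0))
  rhs <- c(rep(0, m), 1)
  coef <- tryCatch(solve(A, rhs)[seq_len(m)],
                   error = function(e) NULL)
  if (is.null(coef) || anyNA(coef)) {
    return(diis_extrapolate(history[-1L]))
  }
  out <- Reduce(`+`, Map(function(hi, ci) ci * hi$F, history, coef))
  attr(out, "coefficients") <- coef
  out
}

#' Conventional restricted Hartree-Fock (reference mode)
#'
#' Direct SCF over the full AO basis with the same integral provider and
#' screened builds as the multilevel driver (Cauchy-Schwarz and density
#' screening only; no MO-coefficient weighting). Starting guess is SAD
#' followed by one Fock diagonalization; convergence is on the maximum
#' occupied-virtual Fock element.
#'
#' @param system a [molecular_system()].
#' @param basis,active_basis basis-set names as in [shell_basis()].
#' @param thresholds a [scf_thresholds()].
#' @param max_iter iteration cap.
#' @param diis use DIIS acceleration (default TRUE).
#' @param diis_depth history depth.
#' @param screening disable to force effectively unscreened builds.
#' @return An object of class `hf_result`: `energy` (Hartree), `converged`,
#'   `iterations`, `energy_trace`, `gradient_trace`, `counters` (quartets per
#'   build), final `C`, `C_occ`, `D`, `mo_energies`, plus `S`, `h`, `n_occ`.
#' @export
run_hf <- function(system, basis = "sto-3g", active_basis = NULL,
                   thresholds = scf_thresholds(), max_iter = 100L,
                   diis = TRUE, diis_depth = 8L, screening = TRUE) {
  if (!screening) {
    thresholds$tau <- thresholds$tau_J <- thresholds$tau_K <- 1e-300
  }
  if (system$n_electrons %% 2L != 0L) {
    stop("odd electron count (", system$n_electrons,
         "): only closed-shell systems are supported")
  }
  pr <- integral_provider(system, basis, active_basis)
  oe <- one_electron_integrals(pr)
  S <- oe$S; h <- oe$h
  n_occ <- system$n_electrons %/% 2L
  X <- orthogonalizer(S, thresholds$lindep)

  D_sad <- sad_density(system, pr$basis)
  guess <- idempotent_guess_via_fock(D_sad, pr, h, S, n_occ, thresholds)
  C <- guess$C_all
  D <- guess$D
  scr <- screening_data(pr, pr$basis, C_active = NULL, D = D,
                        thresholds = thresholds)

  history <- list()
  F_prev <- NULL
  energy_trace <- gradient_trace <- counters <- numeric(0)
  converged <- FALSE
  mo_energies <- NULL
  for (it in seq_len(max_iter)) {
    scr <- refresh_screening(scr, NULL, D, pr$basis)
    gb <- combined_build(pr, D, scr, thresholds, mode = "active")
    counters[it] <- gb$counter
    Fm <- h + gb$G
    energy_trace[it] <- system$h_nuc + 2 * sum(h * D) + sum(D * gb$G)
    occ <- seq_len(n_occ)
    virt <- seq(n_occ + 1L, ncol(C))
    F_mo <- crossprod(C, Fm %*% C)
    gradient_trace[it] <- scf_gradient(F_mo, n_occ)
    if (gradient_trace[it] <= thresholds$gradient) {
      converged <- TRUE
      mo_energies <- diag(F_mo)
      break
    }
    F_orth <- crossprod(X, Fm %*% X)
    if (it <= 2L && !is.null(F_prev)) F_orth <- 0.7 * F_orth + 0.3 * F_prev
    F_prev <- F_orth
    P_orth <- crossprod(X, S %*% D %*% S %*% X)
    err <- F_orth %*% P_orth - P_orth %*% F_orth
    F_use <- F_orth
    if (diis) {
      history <- c(history, list(list(F = F_orth, error = as.vector(err))))
      if (length(history) > diis_depth) history <- history[-1L]
      if (length(history) >= 2L) F_use <- diis_extrapolate(history)
    }
    es <- eigen(F_use, symmetric = TRUE)
    V <- es$vectors[, order(es$values), drop = FALSE]
    C <- X %*% V
    D <- tcrossprod(C[, seq_len(n_occ), drop = FALSE])
  }
  if (!converged) {
    cond <- structure(
      class = c("mlscf_scf_error", "error", "condition"),
      list(message = sprintf(
        "HF did not converge in %d iterations (last gradient %.3e)",
        max_iter, tail(gradient_trace, 1)),
        call = sys.call(-1L),
        energy_trace = energy_trace, gradient_trace = gradient_trace))
    stop(cond)
  }
  structure(list(
    energy = tail(energy_trace, 1), converged = converged,
    iterations = length(energy_trace), energy_trace = energy_trace,
    gradient_trace = gradient_trace, counters = counters,
    C = C, C_occ = C[, seq_len(n_occ), drop = FALSE], D = D,
    mo_energies = mo_energies, S = S, h = h, n_occ = n_occ,
    basis = pr$basis, system = system), class = "hf_result")
}

#' @export
print.hf_result <- function(x, ...) {
  cat(sprintf("Restricted HF: E = %.10f Hartree (%d iterations, gradient %.2e)\n",
              x$energy, x$iterations, tail(x$gradient_trace, 1)))
  invisible(x)
}
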