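#' Run a multilevel Hartree-Fock calculation
#'
#' Executes the full MLHF pipeline: starting guess (SAD with one Fock
#' diagonalization, or SMD with McWeeny purification) giving an idempotent
#' total density; restricted partial Cholesky extraction of the active
#' occupied orbitals and PAO construction of the active virtual space; a
#' one-time screened build of the environment two-electron matrix `G(D_e)`
#' (screening frozen at the initial active MOs), stored in the active MO
#' basis and updated each iteration by an MO-to-MO rotation; then
#' Roothaan-Hall iterations in the active MO basis with per-iteration screened
#' builds of `G(D_a)` and DIIS acceleration, until the maximum
#' occupied-virtual element of the MO Fock matrix falls below the gradient
#' threshold.
#'
#' @param system a [molecular_system()] with active atoms set (or supplied
#'   via `active_atoms`).
#' @param basis basis-set name for the environment atoms.
#' @param active_basis optional basis-set name for the active atoms
#'   (two-level basis).
#' @param active_atoms optional override forwarded to [set_active_atoms()].
#' @param guess `"sad"` or `"smd"`.
#' @param fragments fragment specification for the SMD guess (see
#'   [smd_density()]).
#' @param thresholds a [scf_thresholds()].
#' @param max_iter Roothaan-Hall iteration cap.
#' @param diis use DIIS acceleration.
#' @param diis_depth DIIS history depth.
#' @param screening disable to force effectively unscreened builds
#'   (thresholds driven to zero; every significant quartet computed).
#' @return An object of class `mlhf_result` with the final `energy`
#'   (Hartree), convergence data (`iterations`, `energy_trace`,
#'   `gradient_trace`), the orbital spaces (`C_occ_active`, `C_occ_inactive`,
#'   `C_virt_active`, final active coefficients `C_active`), densities
#'   (`D_active`, `D_env`), active MO energies, and the operation `counters`
#'   (shell quartets computed for the guess Fock, the environment build split
#'   into Coulomb and exchange, and the per-iteration active builds).
#' @export
run_mlhf <- function(system, basis = "sto-3g", active_basis = NULL,
                     active_atoms = NULL, guess = c("sad", "smd"),
                     fragments = "auto", thresholds = scf_thresholds(),
                     max_iter = 100L, diis = TRUE, diis_depth = 8L,
                     screening = TRUE) {
  guess <- match.arg(guess)
  if (!is.null(active_atoms)) system <- set_active_atoms(system, active_atoms)
  if (!length(system$active_atoms)) {
    stop("no active atoms: set system$active_atoms or pass active_atoms")
  }
  if (!screening) {
    thresholds$tau <- thresholds$tau_J <- thresholds$tau_K <- 1e-300
  }
  if (system$n_electrons %% 2L != 0L) {
    stop("odd electron count (", system$n_electrons,
         "): only closed-shell systems are supported")
  }
  pr <- integral_provider(system, basis, active_basis)
  bas <- pr$basis
  oe <- one_electron_integrals(pr)
  S <- oe$S; h <- oe$h
  n_occ <- system$n_electrons %/% 2L
  counters <- list()

  # --- idempotent total density ------------------------------------------
  if (guess == "sad") {
    Dg <- sad_density(system, bas)
    ig <- idempotent_guess_via_fock(Dg, pr, h, S, n_occ, thresholds)
    D_tot <- ig$D
    counters$guess <- ig$counter
  } else {
    Dg <- smd_density(system, fragments, basis, active_basis, thresholds)
    D_tot <- mcweeny_purify(Dg, S, tol = 1e-10)
    attr(D_tot, "residuals") <- NULL
    counters$guess <- 0
  }

  # --- partition into active and environment spaces ----------------------
  act_aos <- aos_on_atoms(bas, system$active_atoms)
  ch <- restricted_cholesky_occupied(D_tot, S, act_aos, thresholds$cholesky)
  if (ch$n_occ_active + ch$n_occ_inactive != n_occ) {
    stop(sprintf("Cholesky rank %d does not match occupied count %d",
                 ch$n_occ_active + ch$n_occ_inactive, n_occ))
  }
  dens <- assemble_densities(ch$C_occ_active, ch$C_occ_inactive, S)
  D_a <- dens$D_active
  D_e <- dens$D_env
  C_occ_full <- cbind(ch$C_occ_active, ch$C_occ_inactive)
  P <- construct_paos(C_occ_full, S, act_aos)
  C_virt <- lowdin_orthonormalize(P, S, thresholds$pao_lindep)
  n_occ_a <- ch$n_occ_active
  C_act <- cbind(ch$C_occ_active, C_virt)
  n_act <- ncol(C_act)

  # --- one-time environment build (screening frozen at initial MOs) ------
  schwarz <- schwarz_shell_pairs(pr, bas, thresholds$tau)
  scr_env <- screening_data(pr, bas, C_active = C_act, D = D_e,
                            thresholds = thresholds, schwarz = schwarz)
  env <- combined_build(pr, D_e, scr_env, thresholds, mode = "env")
  G_e_AO <- env$G
  counters$env_J <- env$counter_J
  counters$env_K <- env$counter_K
  counters$env <- env$counter
  G_env_MO <- mo_transform(G_e_AO, C_act)

  # --- Roothaan-Hall iterations in the active MO basis --------------------
  scr_act <- screening_data(pr, bas, C_active = C_act, D = D_a,
                            thresholds = thresholds, schwarz = schwarz)
  Vtot <- diag(n_act)  # rotation from the initial active MO basis
  history <- list()
  F0_prev <- NULL
  energy_trace <- gradient_trace <- numeric(0)
  counters$active <- counters$active_J <- counters$active_K <- numeric(0)
  converged <- FALSE
  mo_energies <- NULL
  for (it in seq_len(max_iter)) {
    scr_act <- refresh_screening(scr_act, C_act, D_a, bas)
    ab <- combined_build(pr, D_a, scr_act, thresholds, mode = "active")
    counters$active[it] <- ab$counter
    counters$active_J[it] <- ab$counter_J
    counters$active_K[it] <- ab$counter_K
    h_MO <- mo_transform(h, C_act)  # fresh transform every iteration
    F_MO <- h_MO + mo_transform(ab$G, C_act) + G_env_MO
    energy_trace[it] <- mlhf_energy(h, D_a, D_e, ab$G + G_e_AO, system$h_nuc)
    gradient_trace[it] <- scf_gradient(F_MO, n_occ_a)
    if (gradient_trace[it] <= thresholds$gradient) {
      converged <- TRUE
      mo_energies <- roothaan_hall_step(F_MO, C_act)$mo_energies
      break
    }
    # DIIS bookkeeping in the fixed initial MO basis:
    # F0 = Vtot F_MO t(Vtot), occupied projector P0 = Vocc t(Vocc)
    F0 <- Vtot %*% F_MO %*% t(Vtot)
    if (it <= 2L && !is.null(F0_prev)) F0 <- 0.7 * F0 + 0.3 * F0_prev
    F0_prev <- F0
    P0 <- tcrossprod(Vtot[, seq_len(n_occ_a), drop = FALSE])
    err <- F0 %*% P0 - P0 %*% F0
    F_use <- F0
    if (diis) {
      history <- c(history, list(list(F = F0, error = as.vector(err))))
      if (length(history) > diis_depth) history <- history[-1L]
      if (length(history) >= 2L) F_use <- diis_extrapolate(history)
    }
    es <- eigen((F_use + t(F_use)) / 2, symmetric = TRUE)
    U <- es$vectors[, order(es$values), drop = FALSE]
    C_new <- (C_act %*% t(Vtot)) %*% U  # = C0 %*% U
    G_env_MO <- mo_to_mo_update(G_env_MO, C_act, C_new, S)
    C_act <- C_new
    Vtot <- U
    D_a <- tcrossprod(C_act[, seq_len(n_occ_a), drop = FALSE])
  }
  if (!converged) {
    cond <- structure(
      class = c("mlscf_scf_error", "error", "condition"),
      list(message = sprintf(
        "MLHF did not converge in %d iterations (last gradient %.3e)",
        max_iter, tail(gradient_trace, 1)),
        call = sys.call(-1L),
        energy_trace = energy_trace, gradient_trace = gradient_trace),
      counters = counters)
    stop(cond)
  }
  structure(list(
    energy = tail(energy_trace, 1), converged = converged,
    iterations = length(energy_trace), energy_trace = energy_trace,
    gradient_trace = gradient_trace, counters = counters,
    C_occ_active = C_act[, seq_len(n_occ_a), drop = FALSE],
    C_occ_inactive = ch$C_occ_inactive,
    C_virt_active = C_act[, -seq_len(n_occ_a), drop = FALSE],
    C_active = C_act,
    D_active = D_a, D_env = D_e, D_total_initial = D_tot,
    n_occ_active = n_occ_a, n_occ_inactive = ch$n_occ_inactive,
    n_virt_active = n_act - n_occ_a,
    mo_energies = mo_energies, S = S, h = h,
    thresholds = thresholds, basis = bas, system = system),
    class = "mlhf_result")
}

#' @export
print.mlhf_result <- function(x, ...) {
  cat(sprintf("MLHF: E = %.10f Hartree (%d iterations, gradient %.2e)\n",
              x$energy, x$iterations, tail(x$gradient_trace, 1)))
  cat(sprintf("  active space: %d occupied + %d virtual MOs over %d AOs\n",
              x$n_occ_active, x$n_virt_active, nrow(x$C_active)))
  cat(sprintf("  quartets: guess %d, environment %d (J %d, K %d), active/iter %s\n",
              x$counters$guess, x$counters$env, x$counters$env_J,
              x$counters$env_K,
              paste(x$counters$active, collapse = " ")))
  invisible(x)
}
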