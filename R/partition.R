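# Partitioning of the idempotent total density into active and environment
# parts: restricted partial Cholesky for the occupied space, projected atomic
# orbitals (PAOs) for the active virtual space.

# Symmetric orthonormalization of a coefficient block in the S metric
# (preserves the span, minimally perturbs the columns).
symmetric_s_orthonormalize <- function(C, S) {
  if (ncol(C) == 0L) return(C)
  M <- crossprod(C, S %*% C)
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (any(es$values < 1e-12)) {
    stop("coefficient block is numerically rank deficient")
  }
  C %*% (es$vectors %*% (diag(1 / sqrt(es$values), length(es$values)) %*%
                           t(es$vectors)))
}

#' Restricted partial Cholesky decomposition of an idempotent density
#'
#' Pivoted Cholesky of the total half-density where, in a first phase, pivots
#' are restricted to AOs on the active atoms; the phase ends when the largest
#' restricted diagonal drops to `threshold`, and the columns collected so far
#' become the active occupied orbitals. The decomposition then continues with
#' unrestricted pivots on the residual, yielding the inactive occupied
#' orbitals. Pivot selection takes the largest diagonal, ties broken by
#' lowest AO index. Both blocks are symmetrically orthonormalized in the S
#' metric before being returned.
#'
#' @param D_total idempotent total half-density (`D S D = D`).
#' @param S overlap matrix.
#' @param active_aos 1-based AO indices on the active atoms.
#' @param threshold pivot cutoff ending the restricted phase (default 1e-1).
#' @param rank_tol diagonal magnitude at which the residual is considered
#'   exhausted.
#' @return List with `C_occ_active`, `C_occ_inactive` (S-orthonormal, jointly
#'   reproducing `D_total`), and the counts `n_occ_active`, `n_occ_inactive`.
#' @export
restricted_cholesky_occupied <- function(D_total, S, active_aos,
                                         threshold = 1e-1, rank_tol = 1e-8) {
  if (threshold <= 0) stop("threshold must be positive")
  if (length(active_aos) == 0L) stop("active AO set is empty")
  R <- (D_total + t(D_total)) / 2
  n <- nrow(R)
  cols <- list()
  n_active <- 0L

  pivot_step <- function(q) {
    l <- R[, q] / sqrt(R[q, q])
    R <<- R - tcrossprod(l)
    cols[[length(cols) + 1L]] <<- l
  }

  repeat {
    d <- diag(R)
    if (min(d) < -1e-8) {
      stop("density is not positive semidefinite (min diagonal ",
           format(min(d)), "): input may not be idempotent")
    }
    dact <- d[active_aos]
    if (max(dact) <= threshold) break
    pivot_step(active_aos[which.max(dact)])
    n_active <- n_active + 1L
  }
  repeat {
    d <- diag(R)
    if (max(d) <= rank_tol) break
    if (min(d) < -1e-8) {
      stop("density is not positive semidefinite during unrestricted phase")
    }
    pivot_step(which.max(d))
  }

  L <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)
  C_a <- symmetric_s_orthonormalize(L[, seq_len(n_active), drop = FALSE], S)
  C_e <- symmetric_s_orthonormalize(
    L[, setdiff(seq_len(ncol(L)), seq_len(n_active)), drop = FALSE], S)
  list(C_occ_active = C_a, C_occ_inactive = C_e,
       n_occ_active = ncol(C_a), n_occ_inactive = ncol(C_e))
}

#' Projected atomic orbitals on the active atoms
#'
#' For each AO `a` on an active atom, the PAO is the AO with all occupied
#' components (active and inactive) projected out:
#' `PAO_a = (I - C_occ t(C_occ) S) e_a`. The returned columns are redundant
#' and S-orthogonal to every occupied orbital.
#'
#' @param C_occ_full all occupied coefficients (active and inactive).
#' @param S overlap matrix.
#' @param active_aos 1-based AO indices on the active atoms.
#' @return `n_ao x length(active_aos)` matrix of redundant PAO coefficients.
#' @export
construct_paos <- function(C_occ_full, S, active_aos) {
  if (length(active_aos) == 0L) stop("active AO set is empty")
  n <- nrow(S)
  P <- diag(n)[, active_aos, drop = FALSE]
  if (!is.null(C_occ_full) && ncol(C_occ_full) > 0L) {
    P <- P - C_occ_full %*% crossprod(C_occ_full, S %*% P)
  }
  P
}

#' Loewdin orthonormalization of redundant PAOs
#'
#' Eigendecomposition of the PAO metric `M = t(P) S P`; directions with
#' eigenvalue at or below `lindep_cut` are discarded as linearly dependent and
#' the rest scaled to S-orthonormality. The result spans the active virtual
#' space.
#'
#' @param P redundant PAO coefficients.
#' @param S overlap matrix.
#' @param lindep_cut metric eigenvalue cutoff (default 1e-6).
#' @return S-orthonormal `n_ao x n_virt_active` coefficients.
#' @export
lowdin_orthonormalize <- function(P, S, lindep_cut = 1e-6) {
  if (ncol(P) == 0L || max(abs(P)) == 0) stop("PAO block is zero")
  M <- crossprod(P, S %*% P)
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- es$values > lindep_cut
  if (!any(keep)) {
    stop("all PAO metric eigenvalues below ", lindep_cut,
         ": active virtual space is empty")
  }
  V <- es$vectors[, keep, drop = FALSE]
  W <- V %*% diag(1 / sqrt(es$values[keep]), sum(keep))
  if (all(keep)) {
    # full rank: symmetric (Loewdin) M^(-1/2), which leaves an already
    # S-orthonormal input unchanged
    P %*% (W %*% t(V))
  } else {
    P %*% W
  }
}

#' Assemble the active and environment densities
#'
#' @param C_occ_active,C_occ_inactive S-orthonormal occupied coefficient
#'   blocks from [restricted_cholesky_occupied()].
#' @param S overlap matrix (used to verify that the two blocks are mutually
#'   orthogonal before assembling).
#' @return List with `D_active` and `D_env`; their sum reproduces the total
#'   density the blocks came from.
#' @export
assemble_densities <- function(C_occ_active, C_occ_inactive, S) {
  if (ncol(C_occ_active) > 0L && ncol(C_occ_inactive) > 0L) {
    cross <- max(abs(crossprod(C_occ_active, S %*% C_occ_inactive)))
    if (cross > 1e-6) {
      stop(sprintf("active and inactive occupied spaces overlap (%.2e)", cross))
    }
  }
  list(D_active = tcrossprod(C_occ_active),
       D_env = if (ncol(C_occ_inactive) > 0L) tcrossprod(C_occ_inactive)
               else matrix(0, nrow(C_occ_active), nrow(C_occ_active)))
}

#' Active AO set of a coefficient matrix
#'
#' AO `a` is active when `max over MOs p of |C[a, p]| > cutoff`. Diagnostic
#' only: the numerically binding screens are the Coulomb/exchange neglect
#' conditions, not an AO mask.
#'
#' @param C_active active MO coefficients (occupied and virtual).
#' @param cutoff coefficient threshold (>= 0, default 1e-6).
#' @return Sorted integer vector of 1-based AO indices.
#' @export
active_ao_set <- function(C_active, cutoff = 1e-6) {
  if (cutoff < 0) stop("cutoff must be non-negative")
  which(apply(abs(C_active), 1L, max) > cutoff)
}
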