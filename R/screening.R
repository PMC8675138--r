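#' Screening thresholds
#'
#' Thresholds controlling the screened Fock builds and SCF convergence, all in
#' atomic units. `tau` is the integral cutoff defining the master significant
#' shell-pair list; `tau_J` and `tau_K` are the Coulomb and exchange neglect
#' thresholds for contributions to the active-MO Fock matrix; `gradient` is
#' the SCF convergence threshold on the occupied-virtual Fock block;
#' `cholesky` terminates the restricted partial Cholesky extraction of the
#' active occupied orbitals; `pao_lindep` discards linearly dependent
#' projected atomic orbitals; `lindep` removes linear dependence from the AO
#' basis.
#'
#' @param tau master-list integral cutoff.
#' @param tau_J Coulomb neglect threshold.
#' @param tau_K exchange neglect threshold.
#' @param gradient SCF gradient threshold.
#' @param cholesky restricted Cholesky pivot threshold.
#' @param pao_lindep PAO metric eigenvalue cutoff.
#' @param lindep overlap eigenvalue cutoff.
#' @return A list of class `ScreeningThresholds`.
#' @export
scf_thresholds <- function(tau = 1e-12, tau_J = 1e-12, tau_K = 1e-10,
                           gradient = 1e-6, cholesky = 1e-1,
                           pao_lindep = 1e-6, lindep = 1e-8) {
  th <- list(tau = tau, tau_J = tau_J, tau_K = tau_K, gradient = gradient,
             cholesky = cholesky, pao_lindep = pao_lindep, lindep = lindep)
  if (any(unlist(th) <= 0)) stop("all thresholds must be strictly positive")
  structure(th, class = "ScreeningThresholds")
}

#' Master significant shell-pair list from Cauchy-Schwarz norms
#'
#' Builds the shell-pair Schwarz norms `Q` and the master list of significant
#' pairs: all `(s1, s2)` with `s1 >= s2` and `Q[s1, s2] > tau`, in ascending
#' canonical order (position in the list is the pair's canonical rank).
#'
#' @param provider an integral provider.
#' @param basis the corresponding [shell_basis()].
#' @param tau integral cutoff.
#' @return List with `Q` and `master_pairs` (two-column integer matrix).
#' @export
schwarz_shell_pairs <- function(provider, basis = provider$basis, tau = 1e-12) {
  if (tau <= 0) stop("tau must be strictly positive")
  Q <- schwarz_matrix(provider)
  ns <- nrow(Q)
  s1 <- rep(seq_len(ns), times = seq_len(ns))       # s1 >= s2, ascending (s1, s2)
  s2 <- unlist(lapply(seq_len(ns), seq_len))
  keep <- Q[cbind(s1, s2)] > tau
  list(Q = Q, master_pairs = cbind(s1 = s1[keep], s2 = s2[keep]))
}

#' Per-shell maxima of the active MO coefficients
#'
#' `C_shell[s] = max over AOs a in s, over active MOs p, of |C[a, p]|`; zero
#' for shells carrying no active support.
#'
#' @param C_active `n_ao x n_active_mo` coefficient matrix (occupied and
#'   virtual active MOs), or `NULL` for a vector of ones (no C-screening, as
#'   in a conventional Fock build).
#' @param basis a [shell_basis()] supplying the AO-to-shell map.
#' @return Numeric vector over shells.
#' @export
shell_max_mo_coefficients <- function(C_active, basis) {
  ns <- length(basis$shells)
  if (is.null(C_active)) return(rep(1, ns))
  amax <- apply(abs(C_active), 1L, max)
  if (ncol(C_active) == 0L) amax <- rep(0, basis$n_ao)
  vapply(seq_len(ns), function(s) {
    rows <- which(basis$ao_to_shell == s)
    max(amax[rows])
  }, numeric(1))
}

#' Per-shell-pair maxima of a density matrix
#'
#' `D_shell[s3, s4] = max over AOs c in s3, d in s4 of |D[c, d]|`.
#'
#' @param D symmetric AO density matrix.
#' @param basis a [shell_basis()].
#' @return Symmetric `nshell x nshell` matrix.
#' @export
shell_pair_density_max <- function(D, basis) {
  ns <- length(basis$shells)
  rows <- lapply(seq_len(ns), function(s) which(basis$ao_to_shell == s))
  out <- matrix(0, ns, ns)
  aD <- abs(D)
  for (i in seq_len(ns)) {
    for (j in seq_len(i)) {
      m <- max(aD[rows[[i]], rows[[j]]])
      out[i, j] <- out[j, i] <- m
    }
  }
  out
}

#' Pair orderings for the screened builds
#'
#' The three traversal orders of the master pair list used by the screened
#' Coulomb and exchange builds:
#' \describe{
#'   \item{`order_pairs_for_coulomb_env()`}{ket pairs sorted by descending
#'     `Q * D_shell` product, so that a failed Coulomb test at one ket implies
#'     failure at all later kets (enables the early exit of the environment
#'     build). Ties are broken by ascending `(s1, s2)`. Also returns, for each
#'     leading shell, the list of significant partners.}
#'   \item{`order_pairs_for_coulomb_active()`}{ascending `(s1, s2)`.}
#'   \item{`order_pairs_for_exchange()`}{ascending `s2`, then `s1`, the order
#'     in which permutational symmetry is exploited in the exchange build.}
#' }
#'
#' @param master_pairs two-column matrix from [schwarz_shell_pairs()].
#' @param Q Schwarz norm matrix.
#' @param D_shell shell-pair density maxima.
#' @return An integer permutation of `seq_len(nrow(master_pairs))`; for the
#'   environment ordering, a list with `order`, the sorted `product`, and
#'   `significant_s2` (partners by leading shell).
#' @export
order_pairs_for_coulomb_env <- function(master_pairs, Q, D_shell) {
  prod <- Q[master_pairs] * D_shell[master_pairs]
  ord <- order(-prod, master_pairs[, 1L], master_pairs[, 2L])
  list(order = ord, product = prod[ord],
       significant_s2 = split(master_pairs[, 2L], master_pairs[, 1L]))
}

#' @rdname order_pairs_for_coulomb_env
#' @export
order_pairs_for_coulomb_active <- function(master_pairs) {
  order(master_pairs[, 1L], master_pairs[, 2L])
}

#' @rdname order_pairs_for_coulomb_env
#' @export
order_pairs_for_exchange <- function(master_pairs) {
  order(master_pairs[, 2L], master_pairs[, 1L])
}

#' Assemble the screening data consumed by the Fock builds
#'
#' Packages the Schwarz norms, master pair list, per-shell MO-coefficient
#' maxima and shell-pair density maxima, together with the three orderings.
#' For the environment build the MO maxima are frozen at the initial active
#' MOs; for the active build they are refreshed every iteration by calling
#' this constructor (or [refresh_screening()]) with the current quantities.
#'
#' @param provider an integral provider.
#' @param basis a [shell_basis()].
#' @param C_active active MO coefficients (or `NULL` to disable C-screening).
#' @param D the density to be contracted.
#' @param thresholds a [scf_thresholds()].
#' @param schwarz optional precomputed result of [schwarz_shell_pairs()]
#'   (Q is geometry-only and is reused across iterations).
#' @return An object of class `ScreeningData`.
#' @export
screening_data <- function(provider, basis = provider$basis, C_active = NULL,
                           D, thresholds = scf_thresholds(),
                           schwarz = NULL) {
  if (is.null(schwarz)) {
    schwarz <- schwarz_shell_pairs(provider, basis, thresholds$tau)
  }
  D_shell <- shell_pair_density_max(D, basis)
  structure(list(
    Q = schwarz$Q,
    master_pairs = schwarz$master_pairs,
    C_shell = shell_max_mo_coefficients(C_active, basis),
    D_shell = D_shell,
    order_env = order_pairs_for_coulomb_env(schwarz$master_pairs, schwarz$Q,
                                            D_shell)$order,
    order_active = order_pairs_for_coulomb_active(schwarz$master_pairs),
    order_exchange = order_pairs_for_exchange(schwarz$master_pairs)),
    class = "ScreeningData")
}

#' @rdname screening_data
#' @param screening an existing `ScreeningData` whose geometry-dependent parts
#'   (Q, master list) are kept.
#' @export
refresh_screening <- function(screening, C_active, D, basis) {
  screening$C_shell <- shell_max_mo_coefficients(C_active, basis)
  screening$D_shell <- shell_pair_density_max(D, basis)
  screening$order_env <- order_pairs_for_coulomb_env(
    screening$master_pairs, screening$Q, screening$D_shell)$order
  screening
}

#' @export
print.ScreeningData <- function(x, ...) {
  cat(sprintf("ScreeningData: %d master pairs of %d shells; max Q = %.3e\n",
              nrow(x$master_pairs), nrow(x$Q), max(x$Q)))
  invisible(x)
}
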