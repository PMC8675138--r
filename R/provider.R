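#' Integral providers
#'
#' All AO integrals reach the algorithm modules through a provider object, so
#' the screened Fock builds are agnostic of where integrals come from. Two
#' providers are included: the package's own Gaussian integral engine
#' ([integral_provider()]), and a dense "toy" provider backed by precomputed
#' matrices and a full four-index tensor ([toy_provider()]), used to test the
#' algorithms in isolation.
#'
#' @param system a [molecular_system()].
#' @param basis a [shell_basis()] or a basis-set name.
#' @param active_basis optional basis name for the active atoms (two-level
#'   basis), used when `basis` is a name.
#' @return An object inheriting from class `IntegralProvider`.
#' @export
integral_provider <- function(system, basis = "sto-3g", active_basis = NULL) {
  if (is.character(basis)) basis <- shell_basis(system, basis, active_basis)
  structure(list(system = system, basis = basis),
            class = c("engine_provider", "IntegralProvider"))
}

#' @rdname integral_provider
#' @param S,hcore,eri precomputed overlap, core Hamiltonian and dense ERI
#'   tensor (chemists' notation, `dim = c(n,n,n,n)`) consistent with `basis`.
#' @export
toy_provider <- function(system, basis, S, hcore, eri) {
  n <- basis$n_ao
  stopifnot(all(dim(S) == n), all(dim(hcore) == n), all(dim(eri) == n))
  structure(list(system = system, basis = basis, S = S, hcore = hcore,
                 eri = eri),
            class = c("toy_provider", "IntegralProvider"))
}

#' @export
print.IntegralProvider <- function(x, ...) {
  cat(sprintf("%s over %d AOs (%d shells)\n", class(x)[1L], x$basis$n_ao,
              length(x$basis$shells)))
  invisible(x)
}

#' One-electron integrals
#'
#' @param provider an integral provider.
#' @return List with the overlap matrix `S` and core Hamiltonian `h`
#'   (kinetic + nuclear attraction), both symmetric `n_ao x n_ao`.
#' @export
one_electron_integrals <- function(provider) {
  UseMethod("one_electron_integrals")
}

#' @export
one_electron_integrals.engine_provider <- function(provider) {
  sh <- provider$basis$cpp
  S <- cpp_overlap(sh)
  h <- cpp_kinetic(sh) +
    cpp_nuclear(sh, provider$system$coords, as.numeric(provider$system$Z))
  list(S = S, h = h)
}

#' @export
one_electron_integrals.toy_provider <- function(provider) {
  list(S = provider$S, h = provider$hcore)
}

#' Electron-repulsion integrals for one shell quartet
#'
#' Returns the contracted block `(s1 s2 | s3 s4)` in chemists' notation as a
#' four-dimensional array with dimensions equal to the shell AO counts.
#'
#' @param provider an integral provider.
#' @param s1,s2,s3,s4 1-based shell indices.
#' @export
eri_shell_quartet <- function(provider, s1, s2, s3, s4) {
  UseMethod("eri_shell_quartet")
}

#' @export
eri_shell_quartet.engine_provider <- function(provider, s1, s2, s3, s4) {
  cpp_eri_quartet(provider$basis$cpp, s1, s2, s3, s4)
}

#' @export
eri_shell_quartet.toy_provider <- function(provider, s1, s2, s3, s4) {
  ns <- length(provider$basis$shells)
  if (any(c(s1, s2, s3, s4) < 1L) || any(c(s1, s2, s3, s4) > ns)) {
    stop("shell index out of range")
  }
  idx <- function(s) {
    sh <- provider$basis$shells[[s]]
    sh$ao_offset + seq_len(((sh$l + 1L) * (sh$l + 2L)) %/% 2L)
  }
  provider$eri[idx(s1), idx(s2), idx(s3), idx(s4), drop = FALSE]
}

#' Dense ERI tensor
#'
#' Full four-index tensor in chemists' notation; intended for oracles and
#' small systems only.
#'
#' @param provider an integral provider.
#' @param max_ao guard against accidentally materializing a huge tensor.
#' @export
eri_dense <- function(provider, max_ao = 64L) {
  n <- provider$basis$n_ao
  if (n > max_ao) {
    stop("dense ERI tensor requested for ", n, " AOs (limit ", max_ao,
         "): ", n^4, " elements")
  }
  UseMethod("eri_dense")
}

#' @export
eri_dense.engine_provider <- function(provider, max_ao = 64L) {
  cpp_eri_dense(provider$basis$cpp)
}

#' @export
eri_dense.toy_provider <- function(provider, max_ao = 64L) {
  provider$eri
}

#' Shell-pair Cauchy-Schwarz norms
#'
#' `Q[s1, s2] = max over AO pairs (a in s1, b in s2) of (ab|ab)^(1/2)`, from
#' the diagonal shell quartets `(s1 s2 | s1 s2)`.
#'
#' @param provider an integral provider.
#' @return Symmetric `nshell x nshell` matrix.
#' @export
schwarz_matrix <- function(provider) {
  UseMethod("schwarz_matrix")
}

#' @export
schwarz_matrix.engine_provider <- function(provider) {
  cpp_schwarz(provider$basis$cpp)
}

#' @export
schwarz_matrix.toy_provider <- function(provider) {
  ns <- length(provider$basis$shells)
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(i)) {
      blk <- eri_shell_quartet(provider, i, j, i, j)
      d <- dim(blk)
      m <- 0
      for (a in seq_len(d[1])) {
        for (b in seq_len(d[2])) m <- max(m, blk[a, b, a, b])
      }
      Q[i, j] <- Q[j, i] <- sqrt(max(m, 0))
    }
  }
  Q
}

#' Overlap orthogonalizer with linear-dependence removal
#'
#' Eigendecomposition of S; directions with eigenvalue below `lindep_cut` are
#' discarded and the rest scaled to give `X` with `t(X) %*% S %*% X = I`.
#'
#' @param S overlap matrix.
#' @param lindep_cut eigenvalue cutoff (default 1e-8).
#' @return Matrix `X` (`n_ao x n_kept`).
#' @export
orthogonalizer <- function(S, lindep_cut = 1e-8) {
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > lindep_cut
  if (!any(keep)) stop("overlap matrix has no eigenvalues above the cutoff")
  es$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(es$values[keep]),
                                            sum(keep))
}
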