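#' Build a shell-structured basis for a system
#'
#' Expands the named Gaussian basis over all atoms into a list of contracted
#' Cartesian shells with contiguous AO offsets. A two-level basis (one set for
#' the active atoms, another for the environment) is selected with
#' `active_basis`.
#'
#' Contraction coefficients are stored fully normalized: each primitive is
#' normalized, and the contracted function is rescaled to unit self-overlap.
#' Only s and p shells are supported by the integral engine.
#'
#' @param system a [molecular_system()].
#' @param basis basis-set name (see [available_bases()]); used for the
#'   environment atoms when `active_basis` is given.
#' @param active_basis optional basis-set name for the active atoms.
#' @return An object of class `ShellBasis` with elements `shells` (list of
#'   per-shell records), `n_ao`, `ao_to_shell`, `shell_atom`,
#'   `active_atom_shells`, and `cpp` (the flat representation consumed by the
#'   compiled engine).
#' @export
shell_basis <- function(system, basis = "sto-3g", active_basis = NULL) {
  if (!is.null(active_basis) && length(system$active_atoms) == 0L) {
    stop("active_basis given but the system has no active atoms")
  }
  shells <- list()
  atom_basis <- character(length(system$Z))
  for (ia in seq_along(system$Z)) {
    bname <- if (!is.null(active_basis) && ia %in% system$active_atoms)
      active_basis else basis
    atom_basis[ia] <- tolower(bname)
    for (sh in basis_shells_for_element(bname, system$symbols[ia])) {
      if (sh$l > 1L) {
        stop("integral engine supports s and p shells only (got l=", sh$l, ")")
      }
      shells[[length(shells) + 1L]] <- list(
        atom = ia, l = sh$l,
        exps = sh$exps,
        coefs = normalize_contraction(sh$l, sh$exps, sh$coefs),
        center = system$coords[ia, ])
    }
  }
  n_per <- vapply(shells, function(s) ((s$l + 1L) * (s$l + 2L)) %/% 2L, integer(1))
  offsets <- cumsum(c(0L, head(n_per, -1L)))
  for (i in seq_along(shells)) shells[[i]]$ao_offset <- offsets[i]
  n_ao <- sum(n_per)
  ao_to_shell <- rep(seq_along(shells), n_per)
  shell_atom <- vapply(shells, `[[`, integer(1), "atom")
  structure(list(
    shells = shells, n_ao = n_ao, ao_to_shell = ao_to_shell,
    shell_atom = shell_atom, atom_basis = atom_basis,
    active_atom_shells = which(shell_atom %in% system$active_atoms),
    cpp = flatten_shells(shells)), class = "ShellBasis")
}

# Normalized contraction coefficients for a single-axis Cartesian component
# (all components of an s or p shell share the same normalization).
normalize_contraction <- function(l, exps, coefs) {
  prim_norm <- (2 * exps / pi)^0.75 * (4 * exps)^(l / 2)
  c_raw <- coefs * prim_norm
  p <- outer(exps, exps, "+")
  s_pair <- (pi / p)^1.5
  if (l == 1L) s_pair <- s_pair / (2 * p)
  self <- drop(crossprod(c_raw, s_pair %*% c_raw))
  c_raw / sqrt(self)
}

flatten_shells <- function(shells) {
  nprim <- vapply(shells, function(s) length(s$exps), integer(1))
  list(
    l = vapply(shells, `[[`, integer(1), "l"),
    nprim = nprim,
    prim_ptr = as.integer(cumsum(c(0L, head(nprim, -1L)))),
    ao_offset = vapply(shells, function(s) as.integer(s$ao_offset), integer(1)),
    exps = unlist(lapply(shells, `[[`, "exps")),
    coefs = unlist(lapply(shells, `[[`, "coefs")),
    centers = vapply(shells, `[[`, numeric(3), "center"))
}

#' @export
print.ShellBasis <- function(x, ...) {
  cat(sprintf("ShellBasis: %d shells, %d AOs on %d atoms\n",
              length(x$shells), x$n_ao, length(unique(x$shell_atom))))
  invisible(x)
}

#' AO indices of shells centered on given atoms
#'
#' @param basis a [shell_basis()].
#' @param atoms 1-based atom indices.
#' @return Sorted integer vector of 1-based AO indices.
#' @export
aos_on_atoms <- function(basis, atoms) {
  which(basis$shell_atom[basis$ao_to_shell] %in% atoms)
}
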