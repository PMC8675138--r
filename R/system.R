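#' Construct a molecular system
#'
#' A `MolecularSystem` holds atoms, Cartesian coordinates (stored internally in
#' Bohr), the total charge, and the ordered subset of active atoms used by the
#' multilevel partitioning. The nuclear repulsion energy is computed on
#' construction.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric n x 3 matrix of coordinates.
#' @param unit unit of `coords`: `"angstrom"` (default, converted to Bohr) or
#'   `"bohr"`.
#' @param charge integer total charge; the resulting electron count must be
#'   even (closed shell).
#' @param active_atoms integer vector of 1-based atom indices forming the
#'   active region (may be set later with [set_active_atoms()]).
#' @param closed_shell require an even electron count (the SCF drivers only
#'   support closed shells; [read_xyz()] defers the check until a calculation
#'   is attempted).
#' @return An object of class `MolecularSystem`.
#' @export
molecular_system <- function(symbols, coords, unit = c("angstrom", "bohr"),
                             charge = 0L, active_atoms = integer(0),
                             closed_shell = TRUE) {
  unit <- match.arg(unit)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(symbols) != nrow(coords)) {
    stop("number of symbols and coordinate rows differ")
  }
  Z <- element_number(symbols)
  if (unit == "angstrom") coords <- coords * ANGSTROM_TO_BOHR
  n_elec <- sum(Z) - charge
  if (closed_shell && n_elec %% 2 != 0) {
    stop("odd electron count (", n_elec, "): only closed-shell systems are supported")
  }
  sys <- structure(
    list(symbols = symbols, Z = Z, coords = coords, charge = as.integer(charge),
         active_atoms = integer(0), n_electrons = n_elec,
         h_nuc = nuclear_repulsion(Z, coords)),
    class = "MolecularSystem")
  if (length(active_atoms)) sys <- set_active_atoms(sys, active_atoms)
  sys
}

nuclear_repulsion <- function(Z, coords_bohr) {
  n <- length(Z)
  if (n < 2) return(0)
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      e <- e + Z[i] * Z[j] / sqrt(sum((coords_bohr[i, ] - coords_bohr[j, ])^2))
    }
  }
  e
}

#' Set the active atoms of a system
#'
#' @param system a [molecular_system()].
#' @param active_atoms 1-based atom indices, or the shorthand
#'   `"first-molecule"` / `"solute"` (atoms of the first molecule as detected
#'   by covalent-radius connectivity), or `"all"`.
#' @return The system with `active_atoms` set.
#' @export
set_active_atoms <- function(system, active_atoms) {
  if (is.character(active_atoms)) {
    active_atoms <- switch(active_atoms,
      "all" = seq_along(system$Z),
      "first-molecule" = , "solute" = detect_fragments(system)[[1L]],
      stop("unknown active-atom shorthand '", active_atoms, "'"))
  }
  active_atoms <- as.integer(active_atoms)
  if (length(active_atoms) == 0L) stop("active_atoms must be non-empty")
  if (anyDuplicated(active_atoms)) stop("active_atoms contains duplicates")
  if (any(active_atoms < 1L | active_atoms > length(system$Z))) {
    stop("active_atoms out of range")
  }
  system$active_atoms <- active_atoms
  system
}

#' @export
print.MolecularSystem <- function(x, ...) {
  cat(sprintf("MolecularSystem: %d atoms (%s), charge %d, %d electrons\n",
              length(x$Z), paste(unique(x$symbols), collapse = ","),
              x$charge, x$n_electrons))
  cat(sprintf("  active atoms: %s\n",
              if (length(x$active_atoms)) paste(x$active_atoms, collapse = " ")
              else "<unset>"))
  cat(sprintf("  nuclear repulsion: %.10f Hartree\n", x$h_nuc))
  invisible(x)
}

#' Read a molecular geometry in XYZ format
#'
#' Standard XYZ dialect: an atom-count line, a comment line, then one
#' `symbol x y z` row per atom with coordinates in Angstrom (converted to Bohr
#' internally). The active-atom set is left empty.
#'
#' @param path path to the file.
#' @param charge total charge passed on to [molecular_system()].
#' @return A `MolecularSystem`.
#' @export
read_xyz <- function(path, charge = 0L) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("XYZ parse error at line 1: empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("XYZ parse error at line 1: expected atom count")
  if (length(lines) < n + 2L) {
    stop("XYZ parse error: expected ", n + 2L, " lines, found ", length(lines))
  }
  symbols <- character(n)
  coords <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 4L) {
      stop("XYZ parse error at line ", ln, ": expected 'symbol x y z'")
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    }
    symbols[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  molecular_system(symbols, coords, unit = "angstrom", charge = charge,
                   closed_shell = FALSE)
}

#' Write a system to an XYZ file
#'
#' @param system a `MolecularSystem`.
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(system, path, comment = "") {
  ang <- system$coords / ANGSTROM_TO_BOHR
  rows <- sprintf("%-3s %18.12f %18.12f %18.12f",
                  system$symbols, ang[, 1], ang[, 2], ang[, 3])
  writeLines(c(as.character(length(system$Z)), comment, rows), path)
  invisible(path)
}

# Rigid water monomer: O-H 0.9572 Angstrom, H-O-H 104.52 degrees, oxygen at
# the origin, bisector along +z, molecule in the xz-plane.
water_monomer_coords <- function() {
  r <- 0.9572
  half <- 104.52 / 2 * pi / 180
  rbind(c(0, 0, 0),
        c(r * sin(half), 0, r * cos(half)),
        c(-r * sin(half), 0, r * cos(half)))
}

#' Water monomer fixture
#'
#' @return A one-water `MolecularSystem` with all atoms active.
#' @export
generate_water_monomer <- function() {
  molecular_system(c("O", "H", "H"), water_monomer_coords(),
                   unit = "angstrom", active_atoms = 1:3)
}

#' Linear chain of rigid water monomers
#'
#' A one-dimensional homologous series: `n` copies of the rigid water monomer
#' translated along the x axis. The default spacing, 5.2917721 Bohr
#' (2.8 Angstrom), is the oxygen-oxygen hydrogen-bond distance in ice, so
#' neighboring monomers interact appreciably while remote ones do not -- the
#' regime in which the screened Fock builds display their asymptotic scaling.
#' The first monomer is active by default.
#'
#' @param n number of monomers (>= 1).
#' @param spacing translation between consecutive oxygens, Bohr (> 0).
#' @return A `MolecularSystem` with `3n` atoms.
#' @export
generate_water_chain <- function(n, spacing = 5.2917721) {
  if (n < 1) stop("n must be >= 1")
  if (spacing <= 0) stop("spacing must be positive")
  mono <- water_monomer_coords() * ANGSTROM_TO_BOHR
  coords <- do.call(rbind, lapply(seq_len(n) - 1L, function(k) {
    sweep(mono, 2, c(k * spacing, 0, 0), "+")
  }))
  molecular_system(rep(c("O", "H", "H"), n), coords, unit = "bohr",
                   active_atoms = 1:3)
}

#' Pseudo-random cluster of rigid water monomers
#'
#' Oxygen positions are drawn uniformly in a sphere sized for a number density
#' slightly below that of liquid water, with rejection sampling enforcing a
#' minimum oxygen-oxygen distance; each monomer gets a random rigid rotation.
#' The generator is a pure function of `(n, seed)`; the monomer whose oxygen is
#' closest to the centroid is the active molecule.
#'
#' @param n number of waters (>= 1).
#' @param seed integer seed; the global RNG state is restored on exit.
#' @param min_oo minimum O-O distance, Bohr.
#' @return A `MolecularSystem` with `3n` atoms.
#' @export
generate_water_cluster <- function(n, seed = 1L, min_oo = 5.2) {
  if (n < 1) stop("n must be >= 1")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  radius <- max(3, (3 * n / (4 * pi * 0.003))^(1 / 3))  # ~0.003 waters / Bohr^3
  centers <- matrix(0, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 20000L) {
      stop("failed to pack ", n, " waters with min O-O distance ", min_oo,
           " Bohr; increase the radius (lower the density) or reduce min_oo")
    }
    p <- runif(3, -1, 1)
    if (sum(p^2) > 1) next
    p <- p * radius
    if (placed > 0L) {
      d2 <- colSums((t(centers[seq_len(placed), , drop = FALSE]) - p)^2)
      if (min(d2) < min_oo^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- p
  }

  mono <- water_monomer_coords() * ANGSTROM_TO_BOHR
  coords <- do.call(rbind, lapply(seq_len(n), function(i) {
    R <- random_rotation()
    sweep(mono %*% t(R), 2, centers[i, ], "+")
  }))
  centroid <- colMeans(centers)
  active_mol <- which.min(colSums((t(centers) - centroid)^2))
  molecular_system(rep(c("O", "H", "H"), n), coords, unit = "bohr",
                   active_atoms = (3L * (active_mol - 1L)) + 1:3)
}

# Uniform random rotation (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Detect molecular fragments by covalent connectivity
#'
#' Two atoms are bonded when their distance is below 1.3 times the sum of
#' their covalent radii; fragments are the connected components, ordered by
#' their first atom.
#'
#' @param system a `MolecularSystem`.
#' @return List of integer vectors of 1-based atom indices.
#' @export
detect_fragments <- function(system) {
  n <- length(system$Z)
  radii <- element_covalent_radius(system$symbols) * ANGSTROM_TO_BOHR
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- sqrt(sum((system$coords[i, ] - system$coords[j, ])^2))
      if (d < 1.3 * (radii[i] + radii[j])) {
        ci <- comp[i]; cj <- comp[j]
        comp[comp == max(ci, cj)] <- min(ci, cj)
      }
    }
  }
  unname(split(seq_len(n), match(comp, unique(comp))))
}
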