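---
title: "Multilevel Hartree-Fock with screened Fock builds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel Hartree-Fock with screened Fock builds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlscf)
```

## The model

Multilevel Hartree-Fock (MLHF) targets closed-shell systems in which the
chemistry of interest is localized: a solute in a solvent shell, an active
site in a larger assembly. The spinless one-particle density is split as

$$ D = D^{a} + D^{e}, $$

where the *active* density $D^a$ is optimized and the *environment* density
$D^e$ is determined once, at the start of the calculation, and then frozen.
All three matrices are required to satisfy the usual N-representability
conditions separately: hermiticity, the trace condition
$\mathrm{Tr}(D S) = n_\mathrm{occ}$, and idempotency $D S D = D$ in the
non-orthogonal AO metric $S$. Throughout the package the *half-density*
convention $D = C_\mathrm{occ} C_\mathrm{occ}^T$ is used, with S-orthonormal
occupied columns, so that the closed-shell energy reads

$$ E = h_\mathrm{nuc} + 2\,\mathrm{Tr}(h D) + \mathrm{Tr}\big(D\,G(D)\big),
\qquad G(D) = 2J(D) - K(D), $$

with $J_{\alpha\beta} = \sum_{\gamma\delta} D_{\gamma\delta}
(\alpha\beta|\gamma\delta)$ and $K_{\alpha\gamma} = \sum_{\beta\delta}
D_{\beta\delta}(\alpha\beta|\gamma\delta)$ contracted from four-index
electron-repulsion integrals in chemists' notation.

The MLHF equations are solved in a reduced molecular-orbital basis spanned by
the active occupied and active virtual orbitals. The Fock matrix seen by the
optimization is the projection

$$ F_{pq} = \big[C^T (h + G(D^e) + G(D^a))\, C\big]_{pq}, $$

so only contributions *visible in the active MO basis* need to be computed
accurately. This is the central observation behind the screened builds: an AO
contribution can be neglected whenever all of its images in the MO Fock
matrix are below threshold, and the MO images are bounded by products of
per-shell maxima of the active MO coefficients.

## Orbital spaces

**Active occupied orbitals** come from a restricted partial Cholesky
decomposition of the initial idempotent total density: pivoted Cholesky in
which, during the first phase, pivots are restricted to AOs centered on the
active atoms. The phase terminates when the largest restricted diagonal
element falls to the `cholesky` threshold (default $10^{-1}$); the columns
collected so far become the active occupied orbitals, and the decomposition
continues with unrestricted pivots to produce the inactive (environment)
occupied orbitals. Termination is by residual magnitude, not by a preset
orbital count: the number of active occupied orbitals is an output. Pivot
ties are broken by the lowest AO index so the decomposition is deterministic.

In exact arithmetic the Cholesky columns of an idempotent density are already
S-orthonormal; the finite stopping threshold leaves deviations at the
$10^{-8}$ level, so each block is symmetrically re-orthonormalized in the S
metric (a span-preserving, minimal-perturbation correction) before densities
are assembled. The partition identities $D^a + D^e = D$, $D^a S D^e = 0$, and
per-block idempotency then hold to $10^{-8}$ or better, and are asserted on
every end-to-end test.

**Active virtual orbitals** are projected atomic orbitals (PAOs): the AOs on
active atoms with all occupied components (active *and* inactive) projected
out, $P_{\bar\alpha} = (I - C_\mathrm{occ} C_\mathrm{occ}^T S)
e_{\bar\alpha}$. The redundant PAO set is orthonormalized through the metric
$M = P^T S P$: eigendirections with eigenvalue at or below `pao_lindep`
(default $10^{-6}$) are discarded. When nothing is discarded the symmetric
(Loewdin) inverse square root is used, so an already orthonormal input passes
through unchanged; otherwise the truncated eigenbasis is returned and the
output dimension equals the numerical rank.

Linear dependence in the AO basis itself is removed by eigendecomposition of
$S$ with cutoff `lindep` = $10^{-8}$ wherever a full-basis orthogonalizer is
needed (guess diagonalization, reference HF).

## Starting guesses

Two routes produce the initial idempotent total density:

* **SAD** (superposition of atomic densities): per-element spherically
  averaged atomic Hartree-Fock densities with fractional occupations spread
  uniformly over degenerate shells (oxygen occupies each 2p component by
  4/3), assembled block-diagonally. The SAD density satisfies the trace
  condition but is not idempotent; one Fock build and diagonalization
  produces the idempotent guess. Aufbau ties at the occupied-virtual boundary
  are resolved by eigenvalue order then index, with a warning.
* **SMD** (superposition of molecular densities): a converged restricted HF
  density per fragment, embedded block-diagonally. Fragments are supplied
  explicitly or detected by covalent-radius connectivity ("auto-molecules"),
  which is the natural mode for solvated systems; fragmentation of covalently
  bound macromolecules is out of scope. Overlapping fragments make the SMD
  density only approximately idempotent; McWeeny purification restores
  idempotency.

**McWeeny purification** iterates the metric-consistent cubic map
$D \leftarrow 3 DSD - 2\,DSDSD$ until $\max|DSD - D| \le$ `tol` (default
$10^{-10}$, cap 50 sweeps — both implementation choices, as no standard
criterion exists). From a near-idempotent start the residual decays
quadratically; the acceptance suite fits the observed order (about 2.0) on a
perturbed converged density.

A practical consequence of the frozen environment deserves emphasis: the
converged MLHF energy depends on the quality of the initial total density,
because $D^e$ is extracted from it and never relaxed. On a water dimer with
one active water the SAD and SMD routes differ by about 0.03 Hartree — real
physics of the method, not an implementation artifact. The two routes agree
to $10^{-7}$ Hartree exactly when the optimized active space covers the
difference, i.e. in the all-atoms-active configuration, and that is the
regime in which the guess-agreement check is run.

## Screening

All screening quantities are shell-based, because integrals are computed in
shell quartets:

* $Q_{s_1 s_2} = \max_{\alpha\in s_1,\beta\in s_2}
  (\alpha\beta|\alpha\beta)^{1/2}$ — shell-pair Cauchy-Schwarz norms,
  computed once per geometry;
* $C_s = \max_{\alpha\in s,\,p} |C_{\alpha p}|$ — per-shell maxima of the
  active MO coefficients;
* $D_{s_3 s_4} = \max_{\gamma\in s_3,\delta\in s_4} |D_{\gamma\delta}|$ —
  per-shell-pair density maxima.

The *master pair list* contains all $(s_1, s_2)$, $s_1 \ge s_2$, with
$Q_{s_1 s_2} > \tau$ (default $10^{-12}$), stored in ascending canonical
order so a pair's list position is its canonical rank. The Cauchy-Schwarz
inequality $|(\alpha\beta|\gamma\delta)| \le Q_{s_1 s_2} Q_{s_3 s_4}$ is
verified exhaustively in the tests.

A shell quartet, visited once as an ordered (bra, ket) combination of master
pairs with rank(ket) $\le$ rank(bra), is accumulated to *all* of its distinct
index permutations. Its Coulomb part is kept when

$$ \max\big(C_{s_1} C_{s_2} D_{s_3 s_4},\; C_{s_3} C_{s_4} D_{s_1 s_2}\big)
   \, Q_{s_1 s_2} Q_{s_3 s_4} > \tau_J $$

— the maximum runs over the symmetry-equivalent Coulomb targets actually
accumulated (at the bra pair and at the ket pair). Its exchange part is kept
when the analogous maximum over the four exchange targets
$(s_1 s_3), (s_1 s_4), (s_2 s_3), (s_2 s_4)$, each weighted by the density
maximum of the complementary pair, exceeds $\tau_K$. Defaults are $\tau_J =
10^{-12}$ and $\tau_K = 10^{-10}$, chosen together with the SCF gradient
threshold of $10^{-6}$. At outer loop levels, where not all four shells are
known, the unknown factors are replaced by their maxima over the remaining
indices, which preserves soundness.

The three traversal orders of the master list are: ascending canonical for
the active-density build; ascending $s_2$ for the exchange build (the order
in which permutational symmetry is exploited); and, for the environment
Coulomb build, kets sorted by descending $Q \cdot D$ product to allow an
early exit. Because a quartet accumulates Coulomb contributions at *both*
its bra and its ket pair, and only the bra-target bound is monotone under
the descending product order, the exit condition also consults suffix maxima
of $C C Q$ along the ordering: the loop is left only when neither Coulomb
target can pass at any later ket. Without this the exit silently discards
order-one ket-target contributions (an error of roughly 1 Hartree on a water
dimer when triggered).

For the environment build $G(D^e)$, the coefficient maxima $C_s$ are frozen
at the initial active MOs; the resulting error is proportional to, rather
than bounded by, the threshold — in practice the screened and effectively
unscreened MLHF energies agree to a few times $10^{-7}$ Hartree on water
trimers and clusters (measured by the acceptance script). For the iterative
$G(D^a)$ build, $C_s$, the density maxima, and the descending ordering are
refreshed every iteration; the master list and $Q$ are geometry-only and are
reused. The per-$s_1$ significant-partner lists are likewise rebuilt per
iteration, a size-independent cost.

Accumulation order is fixed by the list orderings, so serial results are
bit-reproducible; permutational degeneracy is handled by explicit
enumeration and deduplication of the up to eight index images of each unique
AO quartet, which is verified against an unsymmetrized quadruple-loop oracle.

## The SCF driver

Each iteration: build $G(D^a)$ screened in the AO basis and transform it
with the current coefficients; transform $h$ afresh (its cost is immaterial
at these sizes, and a fresh transform avoids accumulating rotation error);
rotate the stored $G(D^e)$ MO matrix to the current basis by the exact
MO-to-MO update $U^T G U$ with $U = C_\mathrm{old}^T S C_\mathrm{new}$; form
$F_{MO}$; check convergence; DIIS-extrapolate; diagonalize. The
Roothaan-Hall diagonalization lives entirely in the active MO space, whose
dimension is independent of the system size.

Convergence is on the gradient only — the maximum absolute element of the
occupied-virtual block of $F_{MO}$, below $10^{-6}$ — matching the stated
criterion; the max-element norm is our choice where the norm is not
specified. DIIS uses the standard sum-to-one constrained least-squares over
(Fock, gradient) pairs with history depth 8, starts at the second iteration,
and a 0.3 damping is applied to the Fock matrix on the first two iterations;
a singular DIIS system drops its oldest entry and retries. Because
successive Fock matrices live in rotated MO bases, the DIIS bookkeeping is
done in the fixed initial active basis (an exact orthogonal change of
representation), which keeps the extrapolation well defined.

The conventional `run_hf()` reference mode uses the same integral provider
and the same screened builds with all coefficient maxima set to one
(Schwarz-plus-density screening only), a SAD-Fock guess, and AO-basis
Roothaan-Hall with the same DIIS settings. The all-active MLHF limit
reproduces it to better than $10^{-10}$ Hartree, and MLHF energies are
variational with respect to it.

## Integral engine and providers

All algorithm modules consume integrals through a provider interface. The
default provider is the package's McMurchie-Davidson Gaussian engine
(compiled, s and p shells, Hermite expansion coefficients by recursion,
Hermite Coulomb integrals on Boys functions evaluated by a convergent
downward-recursion series with an asymptotic branch). STO-3G and 6-31G
parameters for H, O and Ne are built in; contractions are renormalized to
unit self-overlap. A two-level basis (`active_basis`) assigns a richer basis
to the active atoms. A dense *toy provider* backed by precomputed matrices
and a full four-index tensor implements the same interface and runs the same
R-level reference of the screened loop, which pins the compiled loop's
matrices and counters exactly in the tests.

The engine is validated against independent routes: closed-form s-Gaussian
formulas (overlap, kinetic, nuclear attraction, repulsion) reassembled into
an independent H2 restricted HF; Gauss-Legendre quadrature overlaps for s
and p functions; the identity that a p primitive is the center-derivative of
an s primitive (finite differences of the closed forms); and eight-fold
permutational symmetry of the dense tensor.

## Synthetic systems and what they do (not) show

`generate_water_chain(n, spacing)` builds a one-dimensional homologous
series of rigid water monomers (O-H 0.9572 Å, H-O-H 104.52°) translated
along one axis; the default spacing of 5.2917721 Bohr (2.8 Å) is the
oxygen-oxygen hydrogen-bond distance in ice, giving physically interacting
neighbors. `generate_water_cluster(n, seed)` places rigid monomers with
random orientations in a sphere at slightly below liquid-water number
density, with a minimum O-O separation of 5.2 Bohr, deterministically per
seed; the monomer nearest the centroid is active.

These fixtures emulate the *topology* of solvated systems — a 1-D series for
chain-length scaling and 3-D clusters for the embedding tests — not relaxed
molecular geometries: monomers are rigid, orientations are not optimized,
and there is no thermal ensemble. Passing tests therefore establish
algorithmic correctness (oracle equivalence, partition identities,
variationality, scaling of quartet counts), not the chemical accuracy of any
particular solvation model.

**Scaling study.** Quartet counters are recorded on chains of n = 2…10
waters in the minimal basis with the first water active. The asymptotic
claims — size-independent $G(D^a)$, constant environment exchange, linear
environment Coulomb — concern the regime where the active MO coefficient
tails have decayed within the chain; at the hydrogen-bond spacing that
regime is not reached by n = 10 (the tails still span most of the chain), so
the study is run at 10 Bohr spacing, where saturation occurs by n = 4.
Because the counts are affine in n (a constant head plus a linear term), the
log-log slopes are fitted over n = 4…10. Measured values: active build slope
0.00, environment exchange slope 0.00 (the build is local around the active
region and plateaus), environment Coulomb slope about 1.25 and falling
toward 1 with n, master-pair count slope about 1.11. The problem sizes used
throughout the test and acceptance suites (up to 70 AOs, 10 water molecules)
are the package's choice of desk-scale study conditions.

## Degenerate and adversarial inputs

Non-idempotent input to the restricted Cholesky is detected through negative
residual diagonals. An empty active AO set, an empty PAO space after rank
truncation, fragments that fail to partition the atom list, odd electron
counts, out-of-range shell indices, and oversized dense-tensor requests all
raise immediate, specific errors. SCF non-convergence raises a condition
object carrying the energy and gradient traces. Span drift in the MO-to-MO
update (coefficients that no longer span the stored space) triggers a
warning with the measured deviation.

## Known limitations

Only s and p shells (STO-3G, 6-31G; no d functions, hence no cc-pVDZ);
closed shells only; no point-group symmetry; no nuclear gradients; no
correlation treatment on top of the reference; serial execution (the
accumulation contract — associative addition to a shared matrix within
$10^{-12}$ — is what a threaded implementation would have to honor); and no
fragmentation scheme for covalently bound macromolecules in the SMD guess.
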