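---
title: "Perturbation response scanning: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation response scanning: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prscan)
```

## The model and its assumptions

`prscan` implements perturbation response scanning (PRS): an anisotropic
elastic network model (ENM) of the C-alpha trace coupled with linear
response theory (LRT).  The physical picture is that an arriving ligand
exerts forces on the binding-pocket residues of the *unbound* structure;
residues whose displacements respond disproportionately to those forces are
candidates for allosteric roles, and residues that respond *along a common
axis* form the route by which the mechanical signal travels.

Assumptions worth keeping in mind:

* **Harmonicity.** Displacements are first-order responses about a single
  minimum.  Binding events that require barrier crossing or partial
  unfolding are outside the model.
* **Topology only.**  Spring constants depend on geometry alone; residue
  chemistry enters only through the positions of the C-alpha atoms.
* **Equilibrium response.** `dR = H^+ dF` is the static limit; no kinetics.

### The network

Nodes are one C-alpha per residue.  Two spring classes:

* *bonded*: author residue numbers differing by exactly 1 in the same
  chain, spring constant `gamma_b = 1`.  Sequence adjacency is the only
  defensible reading of "bonded" at C-alpha resolution, and tying it to
  author numbering (rather than file adjacency) prevents spurious stiff
  springs across gaps in the crystal model.
* *non-bonded*: every other pair, `k_ij = c / r_ij^2` with `c = 8` and
  `r_ij` in Angstrom.  The constant is treated as a bare numeric in
  Angstrom-based coordinates.  There is **no interaction cutoff** — the
  distance weighting plays that role smoothly.  (An optional cutoff flag
  exists in `enm_params()` for experimentation; it is off by default and
  never cuts bonded springs.)

The 3N x 3N Hessian has off-diagonal blocks
`-(k_ij / r_ij^2) (r_ij o r_ij)` and diagonal blocks equal to minus the row
sums, which makes uniform translations exact zero modes.  The same matrix
is also assembled through the truss factorization `H = B K B^T`
(`build_bkb_hessian()`), kept as a permanent cross-check of the block
assembly: the two constructions agree to machine precision on every
fixture.

### Inversion

`compute_compliance()` eigendecomposes the symmetric `H` and drops
eigenvalues below `1e-8` times the largest (symmetric eigendecomposition
rather than a general SVD, since `H` is symmetric positive semidefinite).
For a generic three-dimensional structure exactly 6 modes are dropped.
Degenerate geometries genuinely have more zero modes and the function warns
rather than fails:

* a collinear chain has no first-order transverse stiffness;
* a *planar* point set has no out-of-plane stiffness at all — a ring of
  `n` residues drops `n + 3` modes (all out-of-plane displacements plus the
  three in-plane rigid motions).

This is physics, not numerics: the inverse-square ANM block along a pair
direction vanishes perpendicular to the plane containing all pairs.  Tests
assert 6 modes only for genuinely 3D fixtures (helix, random cloud) and
assert the exact larger counts for the degenerate ones.

A consequence of pseudo-inversion worth spelling out: an unbalanced force
on a single residue has its net-translation content projected away.  For
the two-node spring with constant `k`, a unit axial force on node 1 is
equivalent to the balanced pair (+1/2, -1/2), so the *relative*
displacement is `1/(2k)`, not `1/k` — and each node moves symmetrically by
`1/(4k)`.  The independent dense-solver oracle
(`analytic_response_oracle()`, built on the truss factorization plus an
SVD-based Moore-Penrose inverse) confirms this on every small fixture.

## Scanning and the response ratio

Forces are unit vectors along 7 canonical directions: `x`, `y`, `z`, the
three face diagonals and the body diagonal, each normalized (a "unit vector
along x and y" is `(1,1,0)/sqrt(2)`).  For each direction `d` and perturbed
residue `i`, `A_ij` is the **squared** magnitude of residue `j`'s
displacement 3-vector.  The squared convention is the default because the
response ratio is defined on mean *square* fluctuation responses; a
plain-magnitude mode (`squared = FALSE`) exists for sensitivity analysis
and changes hot sets only marginally.

The allosteric response ratio of residue `j` in direction `d` is

```
chi_j^(d) = mean_{i in pocket} A_ij^(d) / mean_{i in all residues} A_ij^(d)
```

and the reported `chi_j` is the maximum over directions (an
direction-averaged variant is available via `aggregate = "mean"`).  The
self-response `A_ii` is included in both sums — nothing in the ratio's
definition excludes it.  No row normalization of `A` is applied: the ratio
is already scale-free, and with the pocket equal to the full residue set it
is identically 1, which is used as a normalization check in every test
fixture.  Hot residues are those with `chi_j` strictly above the threshold,
default 1.0.

The denominator averages over *all resolved residues of the analyzed
chain*; when constructs differ (tags, disordered termini) this universe
changes, which shifts `chi` values slightly — one reason hot sets, not raw
`chi` magnitudes, are the unit of comparison.

**Direction-set robustness.** Replacing the 7 canonical directions by 50
random unit directions leaves hot sets largely intact on structured
fixtures (Jaccard 0.86 on a 40-residue helix with an interior pocket).
Because `chi` takes a maximum over directions, adding directions can only
inflate per-residue maxima, so the hot set grows somewhat with the
direction count; on unstructured random clouds this inflation is strong
enough that the overlap can fall near 0.5.  Robustness claims should
therefore be read as claims about secondary-structured geometries.

## Pathways

For residue `k` and pocket residue `i`, the 3x3 compliance block coupling
them is generally asymmetric; its SVD gives the dominant response direction
of `k` (left singular vector of the largest singular value) — a robust
choice for non-symmetric off-diagonal blocks.  Singular-vector signs are
arbitrary, so directions are canonicalized (first nonzero component
positive) and compared by the **absolute** dot product: antiparallel motion
counts as "in line".

Hot residues are expanded by a window of 3 (residue `r` contributes
`r-1, r, r+1` where those exist).  For each candidate pair `a < b` in
sequence, the pair overlap is the mean over pocket residues of the
direction cosine (a max-over-sites variant exists); pairs at or above the
cutoff 0.98 become edges of a sequence-ordered DAG.  Any candidate pair may
link regardless of spatial separation — an optional maximum C-alpha
distance filter exists but defaults to off.

**Which pathways compete.**  With product weights in `(0, 1]`, the maximum
over *all* subpaths would always be the single heaviest edge, which would
make multi-residue pathways impossible; the published three-residue example
(0.99 x 0.98 = 0.97 beating a bare 0.99 edge) rules that reading out.  The
search is therefore over **maximal** monotone paths: chains that cannot be
extended by prepending or appending an edge.  Among those, exact dynamic
programming over increasing sequence position (provably equivalent to
exhaustive enumeration, and tested against it on hundreds of random DAGs)
selects the largest product; ties prefer more residues, then the smaller
start residue.  One consequence: deleting a trailing weak link can *raise*
the best weight by exposing a shorter maximal chain — the all-subpaths
monotonicity intuition does not apply under maximal-path semantics.

An edgeless graph yields a single-node pathway of weight 1 with a warning
rather than an error, so pipelines degrade gracefully on rigid or
featureless inputs.

## Ensembles

`generate_conformers()` displaces the model along response fields:
conformer = base + `s * dR(site, direction)` with `s` chosen so the largest
per-residue displacement equals the `amplitude`.  Sites x directions are
swept deterministically; once the sweep is exhausted, seeded random
(site, direction) draws continue, so generation is reproducible
bit-for-bit for a fixed seed.  Conformer 1 is always the unperturbed
model.  Conformers bringing two C-alphas closer than 1 Angstrom are
rejected (warning) and replaced by seeded draws, with a hard stop after 200
failed attempts.

Defaults `amplitude = 2.0` Angstrom and `n_conformers = 50` are free
parameters: the amplitude is chosen to bracket the backbone changes seen
between bound and unbound PDZ crystal structures (about 0.5-0.7 Angstrom
backbone RMSD) while sampling beyond them, and 50 receptor conformations is
a conventional ensemble size for flexible docking.  Output is C-alpha only;
all-atom rebuilding for actual docking is delegated to external tools.

## Evaluation utilities

Predictions are compared against reference residue sets (experimental or
coevolution-derived lists, one author residue number per line) through a
2x2 contingency table over a stated universe — all resolved residues of the
chain — and Fisher's exact test.  The two-sided p-value follows the
probability-mass rule (the test suite checks it against exhaustive
hypergeometric enumeration to 1e-12); a one-sided option is exposed since
enrichment questions are directional, and reported p-values are sensitive
to the choice of universe.  Matching is by exact author-number identity by
default; a `near = 1` mode counts off-by-one neighbours, reflecting the
coarse-grained resolution, and is off by default.

Structural benchmarks use Kabsch least-squares superposition (via
`bio3d::fit.xyz`) with pairing by author residue number over common
residues; backbone selection is N, CA, C, O.  A quaternion-based
superposition oracle in the test suite provides the independent check.

## Numerical choices and degenerate inputs

* Pseudo-inverse tolerance: `1e-8` relative to the largest eigenvalue.
* Coincident nodes (pair distance below 0.1 Angstrom) are an error naming
  the residue pair.
* Altloc C-alphas: highest occupancy wins; ties break by altloc letter.
* Insertion codes are part of residue identity; reports use author
  numbering throughout, matrices use dense 0-based blocks internally.
* Dominant-direction ties and zero blocks: an all-zero 3x3 block yields an
  `NA` ("no response") entry that simply contributes no pair overlaps.
* Degenerate chain/planar geometries warn (see above) but all downstream
  operations remain well-defined on the non-null subspace.

## What the synthetic fixtures do and do not show

The generator (`make_fixture()`) produces linear chains (degenerate
geometry stress test), rings (planar degeneracy; bent-open-chain bond
topology), ideal alpha-helices (3.6 residues/turn, 1.5 Angstrom rise,
2.3 Angstrom radius — consecutive C-alpha spacing about 3.83 Angstrom),
seeded random clouds (minimum separation 80% of the nominal spacing), and
the two-node spring.  These validate the mechanics exactly — Hessian
assembly, response solves, normalization, pathway optimality — but none of
them has tertiary structure: no packed core, no secondary-structure
contacts between sequence-distant regions, hence no realistic allosteric
transmission between remote sites.  Passing fixture tests demonstrates
that the machinery is correct, not that hot residues on a helix mean
anything biologically.  Reproduction of published PDZ-domain results
(hot-set overlaps with experimental residue lists, the PSD-95 pathway and
its change upon removing the distal third helix, bound/unbound RMSD
benchmarks) is wired into the acceptance tests but requires the crystal
structures 3LNX/1BFE/1BE9 under `inst/extdata/`, which are not
redistributed with the package.

Problem sizes used by the tests and the acceptance script — fixtures of
8-40 residues, 200 random DAGs, a dense sweep of small contingency tables —
were chosen so the whole suite completes in well under a minute while still
exercising every code path; all scale linearly or cubically in ways that
make a 100-residue PDZ domain (3N = 300) comfortable on a laptop.

## Known limitations

* C-alpha resolution: side-chain dynamics, which dominate some experimental
  allostery readouts, are invisible; predictions are expected to land
  "near" (within a residue of) side-chain-defined hot spots.
* The inverse-square spring law has no solvent, no chemistry, and one free
  constant (`c = 8`) absorbing units.
* Pathways are restricted to sequence-monotone chains; physically plausible
  back-and-forth routes are out of scope.
* The Fisher p-values depend on the residue universe of the construct;
  cross-study comparisons should match universes before comparing
  significance.
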