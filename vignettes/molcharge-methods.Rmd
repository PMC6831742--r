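---
title: "Partial-charge prediction by per-element machine learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-charge prediction by per-element machine learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Molecular-dynamics force fields need a partial charge (in units of the
elementary charge *e*) on every atom of a small molecule.  Reference tools
compute these from quantum-chemical calculations or database lookup, at a
cost ranging from seconds to days per molecule.  `molcharge` takes the
machine-learning route: it encodes every atom of a molecule as a fixed
61-slot numeric vector describing its chemical environment, and predicts
its charge with a regression model trained separately for each chemical
element.  The package restricts itself to organic molecules over the
elements C, H, N, O, P, S, F, Cl, Br and I.

The package is a complete, self-contained pipeline: structure parsing
(PDB, SDF V2000, a SMILES subset), graph construction and ring
perception, feature encoding, per-element model training and evaluation,
charge post-processing for united-atom simulation setups, path-fragment
fingerprints for dataset-diversity analysis, and a synthetic-molecule
generator with a deterministic charge oracle so that the entire
train-predict-evaluate loop can be exercised and tested without any
external data.

## Molecular graphs

A molecule is held as a cyclic undirected graph: atoms are vertices with
element, optional 3D coordinates (Å) and formal charge; bonds are edges
with an integer order and an aromatic flag.  Construction validates
element membership, index sanity and per-element valence caps (C 4, H 1,
N 4, O 2, P 5, S 6, halogens 1, counting bond orders).

**Bond perception.**  PDB files frequently omit CONECT records, so bonds
are then perceived from geometry: atoms `i`, `j` are bonded when
`0.4 Å ≤ d(i,j) ≤ r_cov(i) + r_cov(j) + 0.45 Å`, with standard single-bond
covalent radii (C 0.76, H 0.31, N 0.71, O 0.66, P 1.07, S 1.05, F 0.57,
Cl 1.02, Br 1.20, I 1.39 Å).  The 0.4 Å floor rejects coordinate clashes;
the 0.45 Å tolerance is the common distance-perception slack.  Valence
caps are enforced by accepting the shortest candidate bonds first.
Perceived bonds carry order 1 and are flagged as order-unknown, which
switches the hybridization rules to their geometric fallback.

**Ring perception.**  Rings are found by depth-first search: the DFS
spanning tree (rooted at the lowest-index atom, children visited in index
order) turns every non-tree edge into exactly one fundamental cycle, so
the number of reported rings always equals `|E| − |V| + #components`.
This is a *cycle basis*, not the smallest-set-of-smallest-rings; the
choice is deliberate — it is deterministic, matches the DFS formulation,
and its size law makes it directly verifiable against graph-theoretic
ground truth.  Fused ring systems are the transitive closure of rings
sharing at least one atom.

**Coordinates for SMILES input.**  SMILES carries no geometry, but five of
the feature families below are graph-only; only the radial counts need
coordinates.  A deterministic greedy embedder places atoms in
breadth-first order, each 1.5 Å from its parent along whichever of 26
fixed lattice directions maximizes the clearance from already-placed
atoms.  The resulting geometry is approximate by construction (uniform
bond lengths, lattice angles), and molecules carry a `coords_approx`
flag.  The intent is a dependency-free, reproducible stand-in for a
proper 3D builder, good enough for coarse radial environment counts;
users with real conformers should supply them via SDF or PDB.

## The 61-feature encoding

The encoding is a fixed schema of 61 named slots per atom
(61 = 10 + 3 + 6 + 10 + 1 + 10 + 15 + 3 + 1 + 1 + 1):

| slots | family |
|-------|--------|
| 1–10  | element one-hot (C, H, N, O, P, S, F, Cl, Br, I) |
| 11–13 | carbon hybridization one-hot (sp, sp2, sp3) |
| 14–19 | ring block: in-ring flag, ring count, min/max ring size, fused-system ring count and atom count |
| 20–29 | level-1 neighbor element counts |
| 30    | heavy+H degree |
| 31–40 | level-2 neighbor element counts (graph distance exactly 2) |
| 41–55 | radial counts: three radii × five bins (C, N, O, other-heavy, H) |
| 56–58 | counts of single/double/triple bonds at the atom |
| 59    | aromatic-bond flag |
| 60    | formal charge |
| 61    | molecule heavy-atom count |

Design notes, in the order the decisions came up:

* **Radii.**  The radial search uses 2, 4 and 6 Å (configurable).  At
  typical organic geometry these span the bonded shell, the second
  shell, and the through-space environment.  Counts are cumulative, so
  they are monotone non-decreasing across the triple — a property the
  tests assert on every generated molecule.  The distance comparison
  carries a 1e-9 Å tolerance so that rigid-body transforms of the
  coordinates never flip a count away from a bin boundary; feature
  vectors are invariant under rotation and translation.
* **Level-2 trace.**  Neighbor counts at graph distance exactly 2 use
  shortest-path semantics: an atom reachable at distances 1 and 2 counts
  only at distance 1.
* **Hybridization.**  Carbon only; other elements report `n/a` (all-zero
  one-hot).  With known bond orders: any triple bond gives sp, any
  double/aromatic bond sp2, else sp3.  With perceived (order-unknown)
  bonds the rule falls back to geometry and degree: two neighbors with a
  mean bond angle ≥ 155° gives sp, three neighbors sp2, else sp3.
* **Aromaticity** is honored only when the input declares it (SDF order
  4, SMILES lowercase/`:`); no aromaticity perception model is applied.

The schema's FNV-1a digest is recorded in every trained model and checked
at prediction time, so a model can never silently consume features laid
out differently from its training data.

## Per-element models

One regressor per element, trained on the labeled rows of that element
only (at least 10 rows; models for elements absent from the input are
simply not built).  Defaults follow the reference setup: random forests
with 500 trees (via `ranger`, single-threaded and seeded for
reproducibility); k-nearest neighbors with k = 7 under a Minkowski
distance of order 2, i.e. Euclidean (via `caret::knnreg`); and ordinary
least squares as the `"linear"` baseline.

Data are split by a uniformly random, seed-reproducible permutation with
a train share of 0.2 — the literal reading of a train:test ratio of 1:4.
The direction of that ratio is ambiguous in common usage, so the share is
configurable (`p_train`); the default is deliberately the data-poor
direction, which is also the harder test of the models.  No
stratification is applied.

Evaluation reports, per element and as an unweighted cross-element mean:

* **RMSE** `= sqrt(mean((ŷ − y)²))`, in e;
* **NRMSE** `= RMSE / (max(y) − min(y)) × 100`, i.e. RMSE as a percentage
  of the realized charge range, which makes elements with different
  charge ranges comparable;
* **R²**, reported as the squared Pearson correlation (the convention of
  regression in `caret`); the coefficient of determination is computed
  alongside (`r2_cod`) because the two diverge for biased predictions,
  and the package does not assume which one a downstream consumer wants.

All three metrics are checked against independent direct-summation
implementations to 1e-12 in the test suite.

## Charge post-processing

United-atom force fields absorb nonpolar hydrogens into their parent
carbon.  `merge_nonpolar_hydrogens()` removes every hydrogen bonded to a
carbon and adds its charge onto that carbon — charge is conserved exactly
— while hydrogens on N, O or S are polar and retained.  "Nonpolar" =
"bonded to carbon" is the GROMOS-style convention.

Atom-wise prediction does not guarantee an integer net charge.
`redistribute_excess()` subtracts the per-atom share
`(net − target_net)/n` from every atom, after which the net equals the
target to 1e-9.  The correction is applied equally per atom (not
charge-weighted), is idempotent, and preserves every pairwise charge
difference.  The default target is the sum of formal charges.  When the
united-atom merge is requested, redistribution runs after the merge, over
the remaining atoms.

Output formats are PQR (coordinates + charge + radius; charges recovered
to 1e-4 on re-parsing) and a per-atom charge CSV.  Force-field topology
generation (bonded terms, charge groups) is out of scope.

## Fingerprints and dataset diversity

Dataset diversity is measured with linear path fragments of 2–7 heavy
atoms: every simple path in the heavy-atom graph is rendered as
alternating element symbols and bond marks (`-`, `=`, `#`, `:`),
canonicalized as the lexicographic minimum of its two directions, and
collected into a set.  The Tanimoto coefficient of two molecules is
`|A∩B| / |A∪B|` over these exact sets — no hashed bitvector, hence no
collision artifacts, at the price of exact-match semantics.  Pairwise
matrices come with median and quartiles over the strict upper triangle.

## The synthetic generator and its charge oracle

The generator stands in for a large training corpus.  Its defaults are
the package's fixed study conditions: 5–25 heavy atoms per molecule
(spanning the ~19 heavy-atom average of typical small-molecule screening
corpora), heavy-element sampling weights C 0.70, O 0.13, N 0.09, S 0.03,
P 0.01, F 0.015, Cl 0.015, Br 0.005, I 0.005 (dominantly carbon and
oxygen, mirroring reported corpus compositions), and a 0.6 probability of
attempting ring closures (one or two extra edges between
valence-available atoms at graph distance 3–6, giving 4–7-membered
rings).  Molecules are grown as random trees under valence constraints,
hydrogen-filled, and embedded with the deterministic embedder.  Identical
spec and seed give byte-identical output.

Labels come from a deterministic charge oracle so that supervised
recovery can be measured against known ground truth.  The oracle is a
damped electronegativity equalization in the PEOE (Gasteiger) spirit,
with one deliberate addition — a finite per-atom charge capacity:

1. Start from the formal charges.  In pass `k` (k = 1, 2), each bond
   `(i, j)` transfers `0.5^k · (χ_j(q) − χ_i(q)) / 3` units of e toward
   the more electronegative partner, with `χ(q) = χ_Pauling + 2q`, so
   accumulating charge opposes further transfer.
2. An atom's charge resists exceeding the capacity `q_max = 0.22` e: a
   pass that would overshoot scales all transfers touching that atom down
   by the largest feasible factor, each bond taking the smaller factor of
   its two endpoints.  Rescaling acts on both ends of a bond at once, so
   transfers stay pairwise antisymmetric and total charge is conserved
   exactly (the bond-wise coupling can let mixed-sign transfers overshoot
   the capacity moderately; magnitudes stay within about 1.5 q_max).

Two design properties matter more than the specific constants:

* **Horizon match.**  With two passes, an atom's label is an exact
  deterministic function of its one- and two-bond environment — the same
  horizon the neighbor-trace features observe.  More passes would couple
  the label to shells the encoding cannot resolve and turn that coupling
  into irreducible label noise.
* **Non-additivity.**  The capacity makes the label a genuinely
  non-additive function of the neighbor counts (which transfers are
  rescaled depends on their sum).  A purely per-bond transfer rule —
  however nonlinear in the electronegativity difference — collapses to a
  *linear* function of the per-element neighbor counts once hydrogens
  fill all valences, and would be fit perfectly by least squares.  The
  capacity term is what gives tree ensembles their expected advantage
  over the linear baseline, which is the qualitative ordering the
  evaluation is designed to reproduce.

The oracle is *not* a reproduction of any reference tool's charges; it is
a labeled stand-in with the right structure: deterministic, graph-local,
charge-conserving, chemically plausible in sign (carbon positive against
oxygen, hydrogens slightly positive against carbon).

**What passing tests do and do not show.**  The generator's molecules
have idealized lattice-like geometry, no conformational variation, only
single/perceived bonds (no aromatic systems unless parsed from input),
and charge labels from a two-shell oracle.  Model-recovery results on
this corpus demonstrate that the encoder captures the bonded environment
and that the training machinery works end to end; they do not certify
accuracy on quantum-chemically derived charges of real molecules, whose
labels depend on geometry and electronic effects beyond two bonds.

## Study sizes and numerical choices

The model-recovery experiment generates molecules in batches of 1,000
until nitrogen — the scarcest of the four headline elements — has at
least 20,000 encoded atoms (about 16,000 molecules, ~600,000 atoms), so
that under the 1:4 split every one of C, H, N, O trains on at least 4,000
atoms while abundant elements train on their full 20% share.  At these
sizes the random forests reach held-out R² ≈ 0.91–0.98 per element and
beat the linear baseline on mean RMSE by ~13%.  Property sweeps (encoding
contract, charge conservation, ring law) use 1,000 generated molecules
and 200 random graphs; diversity statistics use 200 molecules.  These
sizes are the package's chosen study conditions: large enough for stable
estimates, small enough to rerun routinely.

Other numerical decisions: distance comparisons in radial counts use a
1e-9 Å tolerance (see above); charge conservation in post-processing is
asserted to 1e-12 (floating summation over atoms), net-charge targets to
1e-9; bond-perception candidates are accepted shortest-first under
valence caps; ties in the embedder's direction choice resolve to the
first direction in the fixed ordering; the DFS visits children in atom
index order, making ring perception deterministic for a fixed atom
ordering.

## Known limitations

* The SMILES reader covers the organic subset plus brackets, ring
  closures and aromatic lowercase atoms; stereochemistry is rejected, and
  no aromaticity perception is applied beyond what the input declares.
* The embedder's geometry is schematic; radial features from embedded
  (rather than experimental) coordinates carry correspondingly coarse
  information.
* The cycle basis can represent a fused polycycle by a larger enclosing
  cycle rather than the chemist's smallest rings; ring-size features
  should be read with that convention in mind.
* Models are per-element; molecules containing an element unseen in
  training are rejected rather than extrapolated.
* k-NN models store their training data (lazy learners); bundles with
  k-NN models are correspondingly large.
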