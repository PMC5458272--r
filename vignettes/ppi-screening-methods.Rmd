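---
title: "Methods: a testable virtual-screening cascade for PPI inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a testable virtual-screening cascade for PPI inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscreen)
```

# The problem and the model system

Kinases such as Aurora-A are classically inhibited at the ATP site, which
is highly conserved and therefore hard to hit selectively. An alternative
is to block the protein–protein interaction with an activator: for
Aurora-A, the TPX2 N-terminus. Its residues 7–11 (SYSYD) bind a shallow
groove on the kinase N-lobe (the PIF pocket), with Tyr 8 and Tyr 10 buried
as twin aromatic anchors. A small molecule that reproduces the anchor
peptide's interaction pattern competes with activator binding and thereby
switches the kinase off allosterically.

`ppiscreen` implements the computational side of such a campaign as
separable, contract-tested stages. This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic test
bed does and does not establish.

# Hot-spot scoring

Two independent signals identify anchor residues worth templating.

**Conservation.** Given an alignment of anchor-segment homologs, each
column receives (A) a Shannon-entropy score over the 20-letter alphabet
and (B) the mean pairwise BLOSUM62 similarity (via `bio3d::conserv`).
Each scheme is min–max normalized over columns, the two are averaged, and
the mean is binned into ten equal-width bins, giving the familiar 0
(variable) to 9 (invariant) ConsScore scale; an invariant column is pinned
to 9 by definition. Duplicate sequences are collapsed first — a copied
sequence carries no independent evolutionary signal — which also makes
the profile invariant under row permutation and duplication. The original
campaign used two conservation web servers whose homolog retrieval is not
reproducible; these two transparent schemes keep the structure (mean of
two normalized scores) while remaining fully deterministic.

**Alanine-scan surrogate.** Instead of a force-field ΔΔG, the package
counts the cross-interface heavy-atom contacts (≤ 4.5 Å) lost when a side
chain is truncated past Cβ and reports `ddg = k · n_contacts` in kJ/mol.
`k = 0.15` was calibrated so that a fully buried tyrosine — which loses
20–26 contacts in the synthetic groove — scores 3–4 kJ/mol, the range
conventionally associated with interface hot spots. This surrogate is
*not* expected to reproduce server energetics, only the ranking: buried,
conserved aromatics at the top. Ala and Gly score exactly 0 (nothing
beyond Cβ to lose); missing side chains are flagged rather than scored.

**Ranking.** A hot spot is a residue with ConsScore ≥ `cons_min`
(default 7) and `ddg` inside `ddg_window` (default 2–4). The window is
deliberately configurable and unit-agnostic: the hot-spot literature
quotes the 2–4 criterion in kcal/mol while reporting per-residue values
in kJ/mol, and the package takes no position on which the original
analysis intended — with the shipped surrogate the window operates on the
surrogate's own kJ/mol scale.

# Pharmacophore construction

From a receptor–peptide complex the builder emits, per anchor residue:

* **aromatic** — ring centroid (plane fit by SVD); the projection point
  sits 3 Å along the ring normal, with the normal's sign chosen toward
  the nearer receptor side, so the feature encodes which face stacks
  against the groove;
* **donor** — N–H and O–H groups with a receptor acceptor heavy atom
  within 3.5 Å; backbone amides are directional (the acceptor must lie
  within 70° of the N–H direction, reconstructed from N, Cα and the
  preceding carbonyl carbon), hydroxyls and amines are orientation-free
  because their hydrogen positions are rotameric; the projection point is
  the partner-atom position;
* **acceptor** — carbonyl-type oxygens with a receptor donor within
  3.5 Å inside a 90° fan of the C=O axis (carbonyl lone pairs accept over
  a wide arc); projection at the donor position.

Feature radii default to 1.0 Å and projection radii to 1.4 Å, the
conventional query-sphere tolerances for atom-based features and
projected points. Excluded volumes are one 1.0 Å sphere per receptor
heavy atom within 4 Å of any anchor atom; the 4 Å shell is the same
convention used for the interface-atom operation. Features sourced from
caller-designated residues (Tyr 8 and Tyr 10 in the model system) are
flagged essential. Six moieties, each with a projection, give the
twelve-point hypothesis; exclusion spheres are not counted as points.

## Matching semantics

A ligand point satisfies a feature iff its (transformed) position lies
within the feature radius of the feature center — query-sphere semantics,
not sum-of-radii. Projections are satisfied through projected points at
3 Å: along explicit X–H directions for donors with hydrogens, along the
bond-opposed lone-pair proxy for acceptors, along ±normal for rings, and
isotropically (any direction) for points whose orientation is undefined,
e.g. implicit-hydrogen hydroxyls. A conformer matches when a
kind-compatible injective correspondence exists that covers every
essential feature, has at least `min_match = 3` pairs, and no ligand
heavy atom penetrates an exclusion sphere.

`absolute` mode evaluates the identity transform only — this is the
post-docking refilter, where poses already live in the receptor frame and
must not be translated or rotated. `align` mode seeds rigid
superpositions from triplets of compatible feature/point pairs whose
distance matrices agree within summed radii, solves each by Kabsch (proper
rotations only), and keeps the correspondence maximizing the match count
with ties broken by feature RMSD. The correspondence search is exact
branch-and-bound up to a 10^5-node budget per conformer, beyond which it
degrades to the best correspondence found; at the hypothesis sizes this
package targets (≤ 12 features) the budget is never approached. The test
suite proves the matcher equal to an exhaustive-enumeration oracle on
210 randomized instances in both modes.

# Conformer enumeration

The enumeration contract is scan → minimize → filter → dedupe → cap:
systematic rotation of all non-ring rotatable bonds in fixed increments
(default 60°), minimization of every grid point, a 4 kcal/mol strain
window relative to the set minimum, duplicate removal at best-fit
heavy-atom RMSD < 0.15 Å (the lower-energy member survives), and an
energy-ordered cap of 250 conformers. Duplicate RMSD is minimized over
graph automorphisms, so topologically equivalent atom orderings cannot
hide duplicates; heavy atoms only, since the published duplicate criterion
ignores hydrogens elsewhere in the protocol and hydrogen placement is
rotameric anyway.

The energy model is deliberately pluggable: a minimizer is any
`function(mol, coords, max_iter, grad_tol)` returning minimized
coordinates, an energy in kcal/mol, a convergence flag and an iteration
count (defaults 200 iterations, 0.001 gradient). The shipped default is a
transparent torsion potential (one-fold plus three-fold cosine terms,
anti below gauche, 0.8/2.9 kcal/mol barriers) with a 12th-power steric
repulsion between atom pairs four or more bonds apart, minimized over the
torsions by BFGS. Two numerical details matter: the search runs in
radians (in degrees the gradients are ~60× smaller and BFGS stalls), and
each grid start is offset by 0.5° because increments that divide 360°
land exactly on torsion *maxima*, which are stationary points that would
otherwise pin the optimizer. A harmonic-well minimizer ships alongside
purely to test the contract. No published force field is reimplemented;
the algorithm, not the physics, is the tested contract.

# The screening cascade

The funnel is a monotone filter chain; each stage consumes the previous
stage's survivors.

1. **Pharmacophore screen** — a compound survives iff any conformer
   matches in align mode.
2. **Docking adapters** — docking itself is out of scope; engines are
   adapters that return scored poses (predicted pKi). The mock engine
   used in tests perturbs a known pose per engine and draws scores from
   configurable normal distributions (defaulting to mean 5.89, SD 0.93,
   the drug-like score distribution of the original screen). The original
   grid and genetic-algorithm settings are recorded as adapter
   configuration defaults and passed through verbatim, never interpreted.
3. **z-score selection** — compounds with score strictly greater than
   mean + 2 SD of the realized distribution. The sources state the rule
   both as "≥ 2 SD" and "> 2.0 SD"; the strict form is implemented. A
   zero-variance distribution selects nothing (with a warning) rather
   than everything.
4. **Consensus filter** — per compound, the top pose of each engine
   (highest score, ties to the first pose) must agree pairwise below
   2.0 Å RMSD. Pose RMSD uses heavy atoms, no re-superposition (poses
   share the receptor frame), minimized over graph automorphisms so that,
   e.g., a 180° phenyl flip counts as zero. The reference pose — first
   engine by default, configurable, since the sources do not say which
   engine's pose was refiltered — must additionally match the hypothesis
   in absolute mode.
5. **Clustering** — single-linkage components of the Tanimoto similarity
   graph (ChemmineR atom-pair fingerprints) at threshold 0.7, a
   conventional similarity cut, with the highest-scoring member of each
   cluster (ties lexicographic) as representative.

# SPR simulation and fitting

Binding follows 1:1 Langmuir kinetics with the analyte supplied by flow
(no depletion): `dR/dt = kon·C(t)·(Rmax − R) − koff·R`, `koff = kon·Kd`.
Over each constant-concentration interval of a stepwise (FastStep)
injection program the solution is a single exponential, so the simulator
integrates exactly, interval by interval; the test suite checks this
piecewise solution against an independent numerical ODE solve to 10⁻⁶ RU.
`kon` defaults to 10⁵ M⁻¹s⁻¹, a typical small-molecule association rate,
because the experiments report only affinities. Gaussian noise of given
SD is added on top; 1% of Rmax is the level used throughout the recovery
studies.

The simulator reports per-step responses two ways: the response at the
step end, and the true equilibrium response of that step's concentration.
The standard FastStep schedule (25 s doubling steps) sits far from
equilibrium at slow kinetics — with `kon = 1e5` and nanomolar analyte the
observed rate constant is ~10⁻³ s⁻¹, time constant minutes — so step-end
responses are biased low. Exposing both makes the bias measurable;
affinity recovery (and the acceptance script) fits equilibrium responses,
which is what a steady-state Scatchard analysis assumes.

**Scatchard fitting** regresses RU/C on RU; slope = −1/Kd, x-intercept =
Rmax. Non-positive responses are dropped (the transform needs RU > 0) and
a non-negative slope returns a flagged fit failure instead of an
exception — under 1% noise with weak binders a few percent of replicates
fail this way, and medians are taken over the successful fits. A direct
nonlinear saturation fit (`minpack.lm`) ships as cross-check; the two
agree exactly on noiseless data.

**Competition.** With activator (concentration T, affinity Kd) and
inhibitor (I, Ki) both held at fixed flow concentrations, activator-site
occupancy is `(T/Kd) / (1 + T/Kd + I/Ki)`; the signal reflects activator
mass only (rapid small-molecule binding is subtracted, read at a fixed
10 s post-association point). Halving the no-inhibitor signal gives
exactly `IC50 = Ki (1 + T/Kd)` — the competitive-binding Cheng–Prusoff
relation, which the tests verify against numerical root-finding. IC50s
are estimated by a four-parameter logistic in log10 concentration
(top, bottom, IC50, Hill); the log parameterization is not cosmetic — in
raw molar units the Jacobian is numerically singular. A series with no
statistically significant decrease (slope ≥ 0 or p > 0.01 against log
concentration) or a fitted drop below 10% of signal returns a
"non-competing" verdict, the behavior expected of binders that do not
occupy the activator site.

# The synthetic test bed

The synthetic module generates every fixture deterministically from
(spec, seed):

* **Toy complex** — a geometric stand-in for the kinase/activator
  interface: the SYSYD anchor in an idealized extended conformation and
  receptor partner atoms (with the published author numbering: Val 206,
  Glu 170, Leu 178, Val 182, Tyr 199, Glu 183) placed so the six
  documented contacts hold, including the shared Tyr 199 hydroxyl that
  both accepts from the Tyr 10 amide and donates to the Tyr 8 carbonyl.
  The generator validates its own output: every declared contact must
  satisfy the builder's distance/cone rules and no undeclared polar
  pairing may exist, so the declared feature bookkeeping is guaranteed
  rather than assumed. It emulates contact geometry only — no
  stereochemistry, B-factors, crystallographic noise, or alternate
  conformations — so builder tests establish geometric correctness, not
  robustness to real crystallographic artefacts.
* **Libraries** — actives realize every hypothesis feature with a
  matching chemical group at the feature center plus uniform-in-sphere
  jitter strictly below the feature radius (default 0.4 Å); decoys are
  feature-free alkanes. Actives are geometric constructs, not
  synthesizable chemistry; screen tests therefore demonstrate the
  matcher's discrimination contract, not enrichment on realistic
  libraries.
* **Mock docking** — consistent compounds get sub-Ångström pose
  perturbations, inconsistent ones a 6 Å displacement on one engine;
  scores are seeded normal draws. Planted hits are boosted 4.5 SD above
  the mean so they remain above the *realized* mean + 2 SD threshold even
  in small libraries, where the hits themselves inflate the estimated
  spread (at a realistic hit fraction of ~10⁻⁵ this self-inflation is
  negligible; at test scale it is not).
* **Sensorgrams** — wrappers over the simulators with the truth table
  written beside the data.

Default problem sizes (100-compound libraries, 100-replicate recovery
studies, 10-point titrations) keep the full suite around a minute of
compute while leaving every statistical check well-powered; the original
campaign's 8×10⁶-compound scale is explicitly not emulated, and the
published funnel counts that depend on it are covered by the funnel's
property suite (all planted actives recovered, all decoys rejected,
monotone filter chain) rather than by count reproduction.

# Known limitations

* The conservation schemes are alignment-local; no phylogenetic rate
  model, no automatic homolog retrieval.
* The ΔΔG surrogate is contact-counting; it ranks but does not predict
  energies.
* Aromatic annotation handles isolated rings typed with aromatic bonds;
  fused systems and Kekulé-typed rings are outside the shipped pattern
  set.
* The matcher's align mode requires at least three features; hypotheses
  below that size only support absolute mode.
* Mass-transport limitation, surface heterogeneity and immobilization
  chemistry are outside the SPR model, and analyte depletion is assumed
  negligible (flow conditions).
* The insertion-code-free, single-model PDB policy matches prepared
  structures; raw multi-conformer crystallographic files must be cleaned
  first.
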