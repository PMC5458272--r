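# ppiscreen

Structure-based discovery of protein–protein interaction (PPI) inhibitors,
packaged as a reusable, fully testable R pipeline. The model system is the
mitotic kinase Aurora-A and its activator TPX2: residues 7–11 of TPX2
(Ser-Tyr-Ser-Tyr-Asp, with Tyr 8 and Tyr 10 as the anchoring hot spots) bind
a shallow hydrophobic groove on the kinase N-lobe — the PIF pocket — and
small molecules that mimic this anchor peptide can block kinase activation.

The package is aimed at computational chemists and method developers who
want each stage of such a campaign as an inspectable, unit-tested component
rather than a chain of external servers and commercial programs:

* **Hot-spot identification** — per-column conservation of an anchor-peptide
  alignment (mean of a Shannon-entropy score and a BLOSUM62 similarity
  score, normalized to the 0–9 ConsScore convention) combined with an
  alanine-scanning surrogate ΔΔG = k·(cross-interface heavy-atom contacts
  lost on truncation past Cβ). Hot spots are conserved residues with ΔΔG
  inside a configurable window (default 2–4 kJ/mol).
* **Pharmacophore construction** — from the receptor–peptide complex:
  aromatic centroids with normal projections, donor/acceptor points with
  projections at their hydrogen-bond partners (feature radius 1.0 Å,
  projection radius 1.4 Å), plus excluded-volume spheres on every receptor
  heavy atom within 4 Å of the anchor.
* **Matching and screening** — a conformer matches when all essential
  features (everything sourced from Tyr 8/Tyr 10) and at least 3 features
  overall are satisfied with no excluded-volume violation; `align` mode
  searches rigid superpositions (Kabsch over triplet seeds), `absolute`
  mode tests docked poses in place.
* **Conformer enumeration** — systematic torsion scan over non-ring
  rotatable bonds, per-point minimization through a pluggable minimizer
  contract (max 200 iterations, gradient 0.001), 4 kcal/mol strain window,
  0.15 Å symmetry-aware RMSD dedupe, 250-conformer cap.
* **Consensus docking post-filter** — engines are adapters (a seeded mock
  engine ships for tests); selection keeps compounds scoring > mean + 2 SD
  of the predicted pKi distribution, then requires pairwise pose RMSD
  < 2.0 Å (heavy atoms, no re-superposition, minimized over graph
  automorphisms) across engines plus an absolute-mode pharmacophore
  refilter, and finally single-linkage Tanimoto clustering with the most
  potent representative per cluster.
* **SPR analysis** — FastStep stepwise-injection sensorgrams under 1:1
  Langmuir kinetics `dR/dt = kon·C·(Rmax − R) − koff·R` (exact piecewise
  integration), Scatchard (`RU/C` vs `RU`, slope = −1/Kd) and nonlinear
  saturation fits, equilibrium competition against 1 µM activator fragment
  with four-parameter-logistic IC50 estimation, and the competitive-binding
  relation IC50 = Ki·(1 + [TPX2]/Kd).

Because the original crystal structure, compound libraries and docking
engines are external resources, a first-class synthetic-data module
generates every fixture with recorded ground truth: a geometric stand-in
for the Aurora-A/TPX2-7-11 interface, active/decoy libraries engineered
against a hypothesis, mock docking output, and noisy sensorgrams.

## Worked example

```r
library(ppiscreen)

# synthetic receptor-peptide interface and its pharmacophore
tc  <- make_toy_complex()
hyp <- build_hypothesis(tc$structure, tc$anchor, essential_residues = c(8, 10))
print(hyp)
#> pharmacophore: 6 features / 12 points ( acceptor=1, aromatic=2, donor=3 )
#>   essential: 5 | exclusion spheres: 11 | min_match: 3
#>   - aromatic   TYR8:ring -> VAL206 [essential]
#>   - donor      TYR8:OH -> GLU170 [essential]
#>   - acceptor   TYR8:O -> TYR199 [essential]
#>   - aromatic   TYR10:ring -> TYR199/VAL182/LEU178 [essential]
#>   - donor      TYR10:N -> TYR199 [essential]
#>   - donor      ASP11:N -> GLU183
```

The six moieties / twelve points are derived from geometry alone: two
tyrosine ring centroids with normals pointing into the groove, the Tyr 8
hydroxyl donating to Glu 170, the Tyr 10 and Asp 11 backbone amides
donating to Tyr 199 and Glu 183, and the Tyr 8 carbonyl accepting from
Tyr 199.

```r
# FastStep titration of a 42 uM binder, 1% noise, Scatchard fit
prog <- faststep_program(0.94e-6)         # 0.94 -> 30 uM doubling steps
s    <- simulate_faststep(kd = 42e-6, rmax = 100, program = prog,
                          noise_sd = 1, seed = 1)
scatchard_fit(s$eq_RU, prog$conc)
#> binding_fit: Kd = 3.147e-05 M, Rmax = 84.18 RU (r2 = 0.5086)

# competition against 1 uM activator fragment (Kd 80 nM), truth IC50 20 uM
d <- simulate_competition(80e-9, 1e-6, ki_from_ic50(20e-6, 80e-9, 1e-6),
                          c(1, 2, 5, 10, 20, 50, 100) * 1e-6, 200,
                          noise_sd = 2, seed = 1)
ic50_fit(d$conc, d$RU)
#> competition_fit: IC50 = 1.994e-05 M (se 2e-06), top 182, bottom 4.61 RU
```

A single noisy titration scatters around the truth (31 µM here for a 42 µM
binder); medians over replicates converge to it — that is what the
acceptance script measures. The full cascade runs end to end with

```r
run_pipeline(pipeline_config(seed = 1), "run1")
#> [ppiscreen] hotspot    2 hot spot(s): TYR 10, TYR 8
#> [ppiscreen] build_ph   6 features / 12 points, 11 exclusions
#> [ppiscreen] screen     20/100 survive the pharmacophore
#> [ppiscreen] zselect    2/20 above mean + 2SD
#> [ppiscreen] summary    funnel 100 -> 20 -> 2 -> 2 -> 1
```

writing per-stage manifests and a funnel summary under `run1/`. A thin
shell wrapper lives in `inst/scripts/ppiscreen`
(`ppiscreen run --config cfg.yaml --out DIR`, `ppiscreen interface`,
`ppiscreen hotspot`, `ppiscreen spr-sim`, `ppiscreen spr-fit`).

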