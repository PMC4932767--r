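---
title: "Separation capacity of hydrophobicity scales: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separation capacity of hydrophobicity scales: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrosep)
```

# The question and the model

A hydrophobicity scale is a 20-entry table `h` assigning each amino acid
a real value.  `hydrosep` quantifies how well such a table separates
pools of peptides that differ in secondary structure (helix `H`, sheet
`E`, coil `C`) and membrane topology (membrane `M`, soluble `S`).  The
underlying assumption is that if hydrophobicity carries structural
signal, peptides of one structural class should occupy a distinct region
of a low-dimensional hydrophobicity-parameter space, and the degree to
which two pools' regions overlap measures what the scale cannot
distinguish.

## Window parameters

Five parameters are computed in every sliding window of `window_len`
residues (default 10, step 1), and the per-peptide maximum and minimum
of each form a 10-component extrema vector (indices 0–9):

* **Average hydrophobicity** `(1/L) Σ hᵢ` — bulk hydrophobic content.
* **Hydrophobic moment** at angular offset δ,
  `(1/L) √[(Σ hᵢ sin iδ)² + (Σ hᵢ cos iδ)²]`, with δ = 100°
  (α-helical periodicity) and δ = 180° (β-strand alternation).  δ is
  given in degrees at the interface and converted internally.
* **Alternating hydrophobicity** `(1/L) |Σ (−1)ⁱ hᵢ|` — the polar/apolar
  face alternation typical of membrane-embedded β-strands.  Under these
  definitions it coincides *exactly* with the 180° moment (the sine
  terms vanish); the redundancy is kept deliberately because the exact
  historical formula behind this parameter is not fixed, both parameter
  slots are part of the 10-extrema interface, and the analysis must
  remain well-defined when two coordinates coincide (see *Joint affine
  reduction* below).
* **Exact β-strand score (EBSS)** for windows of ≥ 10 residues: residues
  are assigned alternately to the outward (lipid-facing) and inward
  (pore-facing) strand face, the score is the mean log propensity of
  each residue on its face, and the better of the two phases is taken.

All window statistics are normalized by the window length `L`, so values
are comparable across configurations; this normalization is a package
choice.  Position indices start at 0 at the window's first residue.

The bundled EBSS propensities are a documented **synthetic stand-in**:
they are derived from the bundled Kyte–Doolittle values as
`outward = exp(+h/4)`, `inward = exp(−h/4)` (each normalized to mean 1),
which gives the qualitative β-barrel behaviour — hydrophobic residues
favour the lipid face, polar residues the pore face.  Published
propensity tables can be supplied through `ebss_propensities()`; a
strictly neutral table would make the EBSS coordinate constant and is
therefore not used as a default.

## Scenarios, clouds, and the score

A *scenario* is one scale, one combination mask (each of the five
parameters contributes either its max or its min; 32 masks) and one pool
pair.  Peptides become 5-D points, pools become convex clouds, and

S = Sv · Sp, with Sv = 1 − 2·Vov/(V1 + V2) and Sp = 1 − Pov/(P1 + P2),

so S = 0 for coinciding clouds and S = 1 when the clouds are disjoint
and no peptide lies in the overlap.

**Convex envelope stripping.**  Before scoring, the boundary points of
each cloud (the peptides forming its convex envelope) are removed
exactly once and the hull is rebuilt.  A handful of outlying peptides
can inflate a hypervolume drastically; removing the envelope makes the
volume represent the bulk of the pool.  The stripping statistics
(fraction of points removed, fraction of volume lost) are attached to
every stripped cloud; on typical 200-point 5-D clouds a small share of
peptides carries a disproportionate share of volume, which is the
phenomenon the step is designed to suppress.  Peptide counts `P` and the
overlap count `Pov` refer to the stripped clouds (a configuration flag
on `evaluate_scenario()`'s building blocks allows scoring without
stripping).  Iterated stripping is deliberately not the default: the
envelope is removed once and volumes recomputed once.

# Geometry

## Hull construction

Clouds are built by incremental insertion (a beneath–beyond scheme): a
seed simplex of affinely independent points is expanded point by point;
facets a new point lies beyond are replaced by the cone from the point
to the horizon ridges.  The result is independent of insertion order
(verified by permutation tests).  Facets are stored as half-spaces
(outward unit normal, offset); the volume is the exact sum of facet
simplices against an interior reference point.  The kernel is compiled
(RcppArmadillo) because 5-D hulls of a few hundred points are built many
thousands of times in sweeps and evolutionary runs.

Numerical choices: the visibility and membership tolerance is
`1e-9 × coordinate scale` (membership is boundary-inclusive, which is
conservative for `Pov`); affine rank is decided by singular values
against the same tolerance.  Affinely degenerate input never crashes:
the cloud is flagged, its d-volume is 0, and the hull is built
recursively inside the spanned subspace so that membership and envelope
queries remain meaningful.

## Joint affine reduction

Because the default alternating hydrophobicity equals the 180° moment,
every mask that picks the same extremum for both parameters places all
points in a fixed hyperplane of the 5-D space.  Before building hulls,
the two point sets of a scenario are therefore jointly projected onto
the affine span of their union whenever that span has lower dimension;
volumes are then measured within the common span.  This keeps all 32
masks well-defined and is the natural generalization of the score to
coordinate-redundant parameter sets.

## Overlap estimation

`Pov` is exact (membership tests).  The overlap volume `Vov` is
estimated by seeded Monte-Carlo rejection sampling by default
(`mc_samples = 1e5` per direction): uniform draws in one hull's bounding
box, kept if inside that hull, counted if also inside the other; the two
directional estimates are averaged, a binomial standard error is
reported in the result metadata, and the estimate is clamped at
`min(V1, V2)`.  Runs with fewer than 1000 samples record a warning.  For
d ≤ 3 an exact method is available and serves as the oracle in the test
suite: the intersection polytope's vertices are enumerated from all
d-subsets of the combined (deduplicated) facet planes, and its volume is
computed by pyramid decomposition over the active constraint faces —
robust to the many-coplanar-vertex configurations that intersection
polytopes always contain.

## Degenerate conventions

When both clouds have zero volume, `Sv` is defined as 1 if their affine
supports are disjoint and 0 otherwise; a cloud stripped of all its
points supports no separation claim and is never treated as disjoint,
and with no points at all `Sp` is 1 by convention (there is nothing in
any overlap).  These conventions only matter for very small pools.

# Pools

Two construction strategies mirror how annotated proteins are reduced to
peptides:

* **Structure dissection**: maximal runs of one SSE letter.  Soluble
  runs map to `s-helix`, `s-sheet`, `random`; runs containing any
  membrane residue map to `tm-helix`/`tm-sheet`.  Membrane runs shorter
  than 10 residues are extended with flanking parent residues
  (alternating right then left; at a sequence end the remaining side
  absorbs the deficit) — the topology annotation does not always
  coincide with the SSE run, and transmembrane peptides are too precious
  to discard.  Soluble runs shorter than 10 are dropped, as are membrane
  coil runs (no such pool exists).
* **In-silico tryptic digest**: cleavage after every K and R, then
  classification of each ≥ 10-residue fragment.  Fragments with any
  membrane residue become `krtm-helix`/`krtm-sheet` by the majority SSE
  among membrane residues (tie → helix, a documented arbitrary choice);
  krtm takes precedence over every other label.  Otherwise a fragment
  whose leading SSE exceeds 70 % of residues (strictly — exactly 70 % is
  not dominated) is `dc-` (one contiguous block) or `dd-`
  (discontinuous); fragments with exactly two SSE letters are `no-X`
  (X = the absent structure); the rest are `all`.

The minimal peptide length of 10 matches the EBSS window requirement and
applies to every pool.  Only exact duplicate sequences are removed
within a pool; homology-based redundancy filtering is out of scope.
Coordinates are 1-based closed intervals throughout (the R convention);
exported tables state this.

# The synthetic generator

Real structure-annotated pools derive from curated structure databases
the package does not ship.  The generator replaces them with seeded
synthetic data that reproduces the statistical structure the analysis
relies on:

* transmembrane helices sample a strongly hydrophobic profile
  (L, I, V, F, A, M; 18–25 residues, a bilayer crossing);
* transmembrane sheets alternate hydrophobic and polar
  (D, E, K, R, N, Q, S, T) profiles position by position (10–14
  residues, a barrel strand);
* soluble helices and sheets carry only the mild composition biases of
  globular proteins (helix formers A/E/L/M vs sheet formers V/I/Y/T/F),
  so they are intentionally hard to separate — as in real data;
* coil is a near-uniform background with a small G/P/S/N bias.

Segment joints become tryptic sites with probability `kr_spacer_rate`
(the earlier segment's last residue is replaced by K or R), motifs can
be planted at recorded positions, and a ground-truth ledger of segment
coordinates and plants is returned.  `generate_pool_pair()` exposes a
single `separation_strength` dial: at 0 both pools draw from the
identical position-wise mixture (exchangeable, downstream S ≈ 0), at 1
each pool uses its kind's full profile.  One RNG stream is split
deterministically per protein, so enlarging a batch never changes
earlier proteins, and a fixed seed reproduces output byte for byte.

What the generator does **not** emulate: residue autocorrelation along
real chains, homology between sequences, database composition biases,
and annotation errors.  Tests passing on synthetic pools therefore show
that the machinery measures what it claims to measure under controlled
conditions — not that any particular published scale is best on real
proteomes.

# Scale comparison and clustering

Scales are compared by the sign-blind correlation dissimilarity
`√(1 − r²)` over the 20 paired values in fixed alphabetical residue
order; constant scales are rejected outright rather than patched.
Values of `1 − r²` below 1e−12 are snapped to exact zero so that a scale
and its inversion (r = −1) are exactly coincident.  UPGMA
(average-linkage) is implemented natively with a deterministic
tie-break — among equally close pairs, the pair whose lexicographically
smallest member ids come first is merged — so trees are reproducible;
`stats::hclust(method = "average")` serves as the independent oracle in
the tests.  Join heights are half the merge-time average distance
(ultrametric); clusters are the leaf groups whose join height does not
exceed the threshold.  The default threshold is 0.05; 0.07 appears in
parts of the literature and is available as a configuration value.
Cluster labels `a`, `b`, … follow the tree's left-to-right leaf order.

# Pattern statistics

Overlapping k-mers (k = 2–5) are counted per pool and normalized to
frequencies of occurrence (FO).  Enrichment of a pattern in a focal pool
is reported against two references: the union of all remaining pools and
the union of remaining pools built by the same strategy (GBSS).  By
default the focal pool is excluded from the pooled reference (a flag
includes it).  A zero reference frequency is floored at one pseudo-count
over the reference total, so "absent elsewhere" yields a large finite
fold.  Significance uses the one-sided Fisher exact test (enrichment
direction) on the 2×2 table of pattern vs other k-mers in pool vs
reference, with Benjamini–Hochberg correction applied within each
(pool, k) family; 50× and 500× fold flags mark strong enrichment in
either reference.  An add-one-smoothed Markov background model
(default order 1) is provided for pattern probability calculations; its
conditional distributions normalize exactly, so fixed-length pattern
probabilities sum to one.

# Evolutionary scale optimization

Random scales draw each residue value uniformly from the global
min/max interval of the input corpus (200 scales by default).  Six
rounds of single-residue perturbation of the current best follow; each
child changes exactly one amino acid by a uniform draw from the round's
interval, and elitism guarantees a non-decreasing best-fitness
trajectory.  The default schedule perturbs all 20 residues positively
then negatively (50 children each, ±[0.001, 5]; read as two sequential
rounds, each re-centred on the current best), then narrows to the
residues found influential (E, Y positive / A, H, F, L negative at ±10;
E / A, H at ±20; E alone at ±40) and finishes with a broad ±[0.001, 5]
round of 25 + 25 children per residue — 1000, 1000, 600, 600, 400, 1000
children per round.  The residue sets of the narrowed rounds are
schedule parameters, not constants.  Perturbed values may leave the
original corpus interval by design.  Fitness is the mean separation
score over all pool pairs of an evaluation pool set at one fixed
combination mask (default: all maxima) — a tractability choice; a
best-of-32 fitness is available via configuration.  After the first two
rounds the top 100 children are summarized per residue as an influence
report.

# Problem sizes and runtime choices

The shipped tests and the results script run at desk scale, chosen so
the full suite completes in a few minutes on one CPU: synthetic pools of
200 peptides for separation and null checks, 60-peptide pools for the
evolutionary benchmark (20 random scales, 50 children per round),
Monte-Carlo overlap at 2×10⁴–10⁵ samples, and oracle comparisons on
12–14-point polytopes in 2-D/3-D.  All of these are parameters, not
limits of the implementation.

# Known limitations

* Exact overlap volumes are provided for d ≤ 3 only; in 4-D/5-D the
  Monte-Carlo estimate (with reported standard error) is the only
  route.
* The alternating hydrophobicity and 180° moment are identical under
  the default definitions; users with a distinct published alternating
  formula should treat that parameter slot as a hook.
* The bundled EBSS propensities are synthetic stand-ins, not the
  published β-barrel frequencies.
* Aggregating 32 masks and many pool pairs into one per-scale score has
  no canonical definition; three modes are provided
  (`best-combo-mean` default, `mean-mean`, `fixed-combo`) and results
  should state which was used.
* Very small pools (under ~30 peptides in 5-D) are dominated by
  hull-boundary effects: after envelope stripping few interior points
  remain and the degenerate-cloud conventions take over.
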