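---
title: "Computer-assisted structure elucidation with nmrcase: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computer-assisted structure elucidation with nmrcase: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrcase)
```

## The problem

Given a molecular formula and tabulated NMR data — a ¹³C peak list with
multiplicities, a one-bond ¹H–¹³C correlation table (HSQC-type), long-range
¹H–¹³C correlations (HMBC-type) and optionally ¹H–¹H COSY — computer-assisted
structure elucidation (CASE) asks for **every** constitutional isomer
consistent with those data, ranked by how well predicted ¹³C shifts match the
observed ones. The promise of the exhaustive approach is negative evidence:
if the generator is complete, no plausible candidate has escaped
consideration, and the ranked list quantifies how decisively the data single
out the best structure.

`nmrcase` implements that workflow end to end: dereplication (library
pre-screening), data-quality triage, construction of a molecular connectivity
diagram (MCD), exhaustive constrained generation, HOSE-code shift prediction
and deviation ranking, plus a simulator that fabricates peak tables from
known structures so the whole pipeline can be validated by round-trip
recovery.

## The molecular connectivity diagram

The MCD has one skeleton atom per heavy atom of the formula. Carbons are
matched to ¹³C signals; when the peak list shows fewer signals than the
formula has carbons, integer multiplicities are assigned per signal
(intensity-guided, summing to the carbon count) and the atoms are
duplicated — this is how coincident shifts from molecular symmetry enter the
search. Each carbon carries:

* **attached hydrogens**, from DEPT/edited-HSQC multiplicity labels, or 0/1
  inferred from presence in the one-bond table;
* a **hybridization set** from shift windows: below 60 ppm sp³; 60–90 ppm
  {sp³, sp} (heteroatom-bearing sp³ or alkyne); 90–115 ppm {sp², sp};
  115–160 ppm sp²; at and above 160 ppm sp² of carbonyl type. The windows
  are config-overridable; they follow standard ¹³C interpretation practice
  and never produce an empty set;
* a **heteroatom-neighbour flag**: `forbidden` for CH₂/CH₃ below 36 ppm
  (pure-hydrocarbon region), `obligatory` at/above 160 ppm, `undefined`
  otherwise.

Hydrogens not placed on carbons are **exchangeable** (OH/NH); their positions
are never pre-assigned — the generator explores all distributions over
heteroatom free valences, which is exactly the OH/NH combinatorics that makes
mixed-heteroatom unknowns hard.

Correlations become **bond-distance windows** between skeleton atoms. COSY
cross-peaks are read strictly as vicinal couplings: adjacent carbons, window
[1,1]. Long-range CH correlations are 2–3-bond H–C couplings: window [1,2]
between the proton-bearing carbon and the target, widened to [1,3] when
`nonstandard` lengths are expected (a global flag, since no per-peak
detection rule exists). A 2D coordinate matching several atoms within
tolerance (default 0.5 ppm ¹³C, 0.05 ppm ¹H — well below typical signal
separation, above digitisation error) yields an *ambiguous* constraint whose
candidate set is the full match; its semantics are existential (one satisfied
candidate suffices), the natural reading of dashed correlation lines as
alternatives.

Ambiguity on the *proton* axis is subtler, because a constraint is anchored
at a single atom. Emission per coincident carbon copy is sound only when the
copies are genuinely symmetric — detectable as one shared proton shift for
the signal. When several distinct protons map to the same carbon coordinate,
the constraint is re-anchored at the target when that is a single atom
(distance windows are symmetric), and otherwise set aside as an orphan.
Orphans are reported, never silently dropped: discarding information is
sound (it can only enlarge the candidate set), whereas mis-anchoring could
eliminate the true structure.

## The generator

Structure generation is backtracking bond placement over free valences.
For each exchangeable-H distribution, atoms are processed in a deterministic
order and each atom's remaining valence is distributed over later atoms as
bond orders 1–3. Pruning is strictly sound:

* valence bookkeeping (remaining capacity of later partners);
* a π-bond budget per atom derived from its hybridization set
  (sp³ = 0, sp² = 1, sp = 2 π bonds; the final count must match one
  admissible state);
* `forbidden`/`obligatory` heteroatom-neighbour flags;
* unambiguous [1,1] constraints are *forced bonds*: branches that spend the
  anchor's valence elsewhere are never entered, and demanded partners are
  allocated first;
* [1,1] and [1,2] windows are decided exactly as soon as the involved atoms
  are saturated (a saturated atom's adjacency is final, and any 1–2-bond
  path uses only edges incident to the endpoints);
* a saturated proper subgraph means an inevitable disconnection — prune.

Every completed graph is verified against **all** constraints by shortest
bond paths (`check_constraints()`), so in-search pruning can be incomplete
without ever being wrong, and the emitted set is exhaustive whenever the
run completes. Candidates are deduplicated by a canonical key computed via
BLISS canonical labelling on a coloured encoding (atom colour = element +
attached H; each bond contributes an auxiliary vertex coloured by order).
The key deliberately ignores the shift assignment, collapsing duplicate
structures that differ only in NMR assignment.

Atoms are processed in a constraint-graph breadth-first order (most
constrained first; ties by descending free valence, then index). An order
based on free valence alone scatters constraint partners across the
sequence, postponing every window check to the bottom of the tree; keeping
partners adjacent lets the exact [1,1]/[1,2] decisions fire near the top.
The order is static and deterministic, so identical inputs give
byte-identical results; the `seed` option exists for interface parity and
does not influence the search.

With `use_symmetry` on, branches that only permute *interchangeable* atoms
(same element, valence, hybridization, signal, heteroatom flag and
constraint roles; both still untouched) are pruned by a canonical-allocation
rule. This never changes the candidate set — only the nodes explored — and
the suite asserts set equality with the option off.

Resource guards (`max_structures`, `time_budget`) return partial results
with an `aborted_cap`/`aborted_time` status rather than raising, so long
runs degrade the way real elucidations do.

## HOSE codes, prediction and ranking

¹³C prediction is by HOSE-code lookup. The dialect is frozen as
`"<El><h>;<sphere1>;<sphere2>;…"`: concentric spheres around the focus
carbon, neighbour tokens `<bond><El><h>` with bond prefixes (`=`, `%`),
siblings ordered by bond order (descending), element priority, then
recursively by subtree; ring closures re-enter the expansion as unrolled
trees. Hierarchical sibling ordering makes the sphere-k code a literal
prefix of the sphere-(k+1) code, so one stored string serves all lookup
depths. Golden-file tests pin the dialect.

Prediction walks spheres outward-in (default 4 down to 1); the first
non-empty match pool gives the prediction as the mean of its observed
shifts. Unmatched carbons fall back to class baselines (sp³ 30, sp³ with
O/N 70, sp² 125, carbonyl 175, sp 80 ppm) and are flagged `n_matches = 0`.

Candidates are ranked ascending by `d13c`, the mean absolute deviation
between experimental and predicted shifts; `stdd13c` is the standard
deviation of the per-atom absolute deviations (the alternative reading —
standard deviation of *signed* deviations — is noted here for
completeness; the absolute-deviation version is what the ranking reports).
Because duplicates differing only in assignment were collapsed, the default
comparison is assignment-free: experimental and predicted shift multisets
are matched in sorted order, which is the exact cost-minimising bijection
for absolute differences in one dimension. Ties in `d13c` are broken by
prediction support — the mean matched sphere, deeper first — then
`stdd13c`, then canonical key. The support tie-break matters in
self-referential validation: a decoy can reach `d13c = 0` by borrowing the
true structure's shallow-sphere pools, but only the true environment
matches at full depth. A top-ranked deviation at or below 2.2 ppm is
labelled `good` in reports — an advisory benchmark, never a filter.

## Dereplication

Shift search matches the query set one-to-one against each record's
per-orbit shifts within a tolerance (default 2 ppm, the conventional
red-flag threshold for library hits; matched pairs deviating by more are
counted in `flagged_over_2ppm`). Because the cost |Δδ| is one-dimensional,
a maximum-cardinality, minimum-cost matching always exists among monotone
pairings and is found exactly by dynamic programming over the sorted lists —
no greedy approximation. Records matching less than `min_match_fraction`
(default 0.9) of the query are dropped; results sort by unmatched count,
then score. Formula and monoisotopic-mass searches are exact filters.
Fragment search requires *every* fragment shift to match a distinct query
shift; accepted fragments freeze their bonds as [1,1] constraints for the
generator, and bonds whose both endpoints map ambiguously are skipped
rather than guessed.

## The simulator and what round-trip success shows

`simulate_dataset()` emits exactly the minimum-data tables: a ¹³C peak list
(one signal per symmetry orbit, intensity proportional to orbit size,
multiplicity from attached H, Gaussian noise of `noise_sigma`), a ¹H list,
one-bond rows, long-range CH rows for all H-carbon→carbon pairs at bond
distance 1–2 (sampled at `hmbc_coverage`, plus distance-3 pairs at
`nonstandard_rate`), and COSY rows for vicinal protonated pairs. Carbon
coordinates closer than `ambiguity_merge` (default 0.1 ppm, the order of
digital resolution) are reported as one coordinate, creating genuine
assignment ambiguity; only same-multiplicity signals merge, since edited
experiments would resolve the rest. Exchangeable protons emit no
correlations (fast exchange) — deliberately reproducing the hardest real
situation, where nothing ties OH/NH protons to the skeleton.

Shift emulation is structural, not physical: each carbon environment
(sphere-4 HOSE code) maps deterministically to a value inside its
hybridization-class window, the windows being chosen consistent with the
MCD typing rules (plain sp³ below 36 ppm, carbonyl at/above 160 ppm, and so
on). Distinct environments thus get distinct, reproducible shifts, and
noiseless simulated data can never contradict the true structure — a
property the suite asserts. Round-trip ranking uses a database holding a
fixture library plus the truth's own noiseless shifts, so the truth's
`d13c` is exactly 0 by construction. **Passing round trips therefore
demonstrate completeness of the generator, soundness of constraint
extraction, and self-consistency of the ranking machinery — not predictive
accuracy on real spectra**, which would require a curated experimental
shift library.

`random_molecule()` draws the study molecules: connected valence-legal
graphs over C/N/O with at least half the skeleton carbon (typical organic
compositions; skeletons dominated by N/O with few protons are chemically
implausible and, as the hydrogen-deficit discussion predicts, explode the
candidate space), a random spanning tree, a few ring closures or bond
upgrades, hydrogens filling the remaining valence.

## Validation scale and numerical choices

The suite validates at sizes a single CPU handles in minutes, chosen once:

* generator completeness against a fully naive enumerate-everything oracle
  (every bond-order grid point materialised) for formulas up to 5 heavy
  atoms, and against a structurally independent pair-major recursive
  oracle up to 8 heavy atoms;
* round-trip recovery on 50 random molecules of 4–12 heavy atoms,
  noiseless, full coverage: 100% recovered at rank 1;
* the symmetric panel: benzene, p-xylene, cyclohexane free; and a
  C₂-symmetric bis-aryl scaffold of formula C₂₀H₂₀Br₂N₄O₂ (ten carbon
  environments for twenty carbons) with both halves frozen as
  library-retrieved fragments — free generation at 28 heavy atoms produces
  thousands of candidates and is not a desk-scale set-equality experiment,
  so the fragment-assisted route (the workflow's own mechanism for exactly
  such cases) is used;
* dereplication identity retrieval over a 40-record synthetic library, and
  ≥ 99% rank-1 retrieval under 0.5 ppm query noise;
* noise scaling: with per-signal Gaussian noise σ the true structure's mean
  `d13c` equals the half-normal mean σ·√(2/π) within 10% for
  σ ∈ {0.5, 1, 2}.

Degenerate inputs are handled explicitly: an odd total free valence fails
fast with a reason; an empty constraint set enumerates all isomers of the
formula; a ¹³C-only dataset supports dereplication but refuses MCD
construction; reject-level triage (e.g. more carbon-attached hydrogens than
the formula allows) aborts before generation, with distinct classes of
issues and the purity grades (fewer than 5 incidences good, 5–10 average,
11–20 poor, over 20 bad) reported either way. "Incidences" are counted as
triage issues — superfluous signals, unmatched 2D coordinates,
near-degenerate duplicates — since no formal unit exists for them.

## Known limitations

* Prediction is HOSE-lookup ¹³C only; no ¹H/¹⁵N/¹⁹F/³¹P ranking, no
  incremental or neural predictors, no solvent or temperature corrections.
* No stereochemistry; aromaticity is represented by Kekulé forms, and
  tautomers are distinct candidates (no collapse).
* Standard valences only by default (no hypervalent S/P); charged species,
  adducts and salt dissociation are out of scope, with Na a monovalent
  placeholder.
* The shipped libraries are small synthetic fixtures plus a curated handful
  of common molecules; interfaces accept arbitrarily large libraries but
  none are distributed.
* Raw spectrum processing (Fourier transform, phasing, peak picking) is
  upstream of this package: input is tabulated peaks, full stop.
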