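---
title: "Ambiguous distance restraints and iterative assignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ambiguous distance restraints and iterative assignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Magic-angle-spinning (MAS) NMR of a membrane protein in lipid bilayers
yields cross peaks that report through-space proximities, but a cross peak
does not come labelled with the atom pair that produced it: any pair of
assigned nuclei whose chemical shifts fall within the matching tolerances
of the peak position is a candidate. `adriter` implements the standard
treatment of this situation: every peak becomes an *ambiguous distance
restraint* (ADR) carrying a list of candidate assignment options and a
distance class, restraints are progressively disambiguated over an
iterative calculation (violation analysis against the lowest-energy
structures, ambiguity pruning, restraint combination), and the ensemble of
structures and the assignments converge together.

The package covers, end to end:

* isotope labeling schemes (forward / reverse amino-acid-type selective,
  uniform, 2-/1,3-glycerol-derived) and the observability filter for
  carbon pairs;
* readers/writers for shift lists (tabular and an NMR-STAR subset),
  Sparky-style peak lists, TALOS-style torsion prediction tables,
  CNS-style `.tbl` restraint files and multi-model PDB coordinates;
* shift-matching of the paired 3D amide-amide spectra and of 2D
  carbon-carbon spectra, redundancy-based option pruning, intensity-based
  distance classes, hydrogen-bond and torsion restraint emission;
* the iterative assignment loop (`run_protocol()`), driven by a desk-scale
  simulated-annealing refiner written in C++;
* a synthetic data generator (ideal antiparallel sheets and barrels, shift
  and peak simulation) so that every stage is testable without
  experimental data.

# Restraint generation

## Amide-amide matching

The paired 3D experiments transfer magnetization between amide protons
through space; their dimensions are \(^{15}\)N, an indirect \(^1\)H and
the directly detected \(^1\)H, with the spectrum type deciding which
residue of the transfer each dimension reports. Matching tolerances
default to 0.4 ppm for \(^{15}\)N, 0.1 ppm for the indirect \(^1\)H and
0.7 ppm for the direct \(^1\)H, boundary inclusive. Peaks on the
\(^1\)H–\(^1\)H diagonal (within 0.05 ppm) are excluded as
auto-correlation peaks; the 0.05 ppm half-width is a linewidth-scale mask,
deliberately narrower than the matching tolerance so that near-diagonal
cross peaks survive.

A spatially close amide pair produces up to four cross peaks: two transfer
directions in each of the two spectra. The *support* of an assignment
option is the number of these four (spectrum × direction) slots in which
at least one observed peak is consistent with the option. The redundancy
rule then prunes options: when an option reaches support 4, options with
support 1 or 2 are removed; when the best support present is 3, options
with support 1 are removed.

Restraints are divided into two distance classes, 1.0–3.5 Å and
1.0–5.5 Å, by sorting the peak list by intensity: the threshold is the
most intense peak for which a sequential assignment (|i−j| = 1) could be
found, peaks strictly stronger go into the short class. In a β-sheet the
sequential amide-amide distance (~4.3 Å) is longer than the cross-strand
facing distance (~3.3 Å), so this intensity split separates the two
contact types when the option lists are clean. With heavy shift overlap a
strong facing peak can carry a spurious sequential option, which pushes
the threshold up and sends everything into the conservative wide class;
the classification never produces bounds outside the two classes.

## Carbon-carbon matching

Carbon peaks are picked in the aliphatic region (5–75 ppm in both
dimensions by default); peaks also present in a short-mixing spectrum are
removed as intra-residue correlations before matching. Matching uses
0.4 ppm in both dimensions, intra-residue candidate pairs are excluded,
and an option is retained only when the joint labeling probability of its
two carbons — the product of the per-atom enrichment fractions of the
sample's labeling scheme — strictly exceeds 10%. By default all carbon
restraints form a single 1.5–8.0 Å class; a two-class mode (1.5–5.5 Å
for medium and 1.5–7.0 Å for long mixing) is selectable because both
conventions are in use.

The glycerol enrichment tables shipped in `inst/extdata/` are approximate,
biosynthesis-based reconstructions (glycolytic amino acids carry clean
pyruvate-derived patterns; TCA- and pentose-phosphate-derived ones are
partially scrambled and encoded as fractional enrichments). They are
versioned data, overridable per scheme descriptor, and only the >10%
filter consumes them.

## Hydrogen bonds and torsions

Co-linear hydrogen-bond restraints are emitted in pairs per donor/acceptor
couple with fixed bounds: H–O 1.73–2.70 Å and N–O 2.52–3.93 Å. A couple
qualifies only when both residues are β-sheet by torsion prediction and
the complete four-peak amide cross-peak pattern (support 4) is present.
Couple candidates for the final calculation are read off the converged
bundle (`derive_hbond_couples()`): mutual nearest cross-strand amides
recurring in the selected models. Torsion restraints copy centre and
half-width from the reliable rows of a TALOS-style table, two per residue.

# The iterative protocol

`run_protocol()` is the package's fitting entry point and returns a
classed object with `print`/`summary`/`plot` methods. Full-scale defaults
mirror the reference protocol: 9 iterations (numbered 0–8), ensembles of
200 structures with the 15 lowest-energy selected, amide restraints and
torsions from iteration 0, carbon restraints from iteration 4, 4-to-4
combination of carbon restraints in iterations 4–6 followed by merging of
equivalent restraints, and rejection of restraints whose r\(^{-6}\)-pooled
effective distance is outside bounds (± the iteration's violation
tolerance) in more than half of the selected models. Numerical choices:

* *Effective distance*: \(\bar d = (\sum_o d_o^{-6})^{-1/6}\) over the
  options; never larger than the shortest option distance.
* *At least half* is implemented as
  `satisfied >= ceiling(0.5 * n_select)` — with the odd full-scale
  selection of 15 this demands 8 models.
* The violation tolerance schedule is not part of the published record;
  the default 1000, 5, 3, 1, 1, 1, 0.1, 0.1, 0.1 Å leaves the first
  iteration effectively unfiltered.
* Violation analysis re-evaluates *every* restraint each iteration:
  rejection is a per-iteration, recoverable state, so restraints rejected
  against an early ensemble return once the ensembles satisfy them.
* Ambiguity pruning keeps the smallest option prefix whose cumulative
  r\(^{-6}\) weight reaches the iteration's cutoff (default schedule
  1.0 → 0.8). Because r\(^{-6}\) weights are extremely peaked, cutoffs
  below ~0.99 effectively commit to the leading option; the desk-scale
  configuration therefore prunes only in the last iterations.
* Combination draws seed-reproducible groups without replacement; the
  union of options and the widest bounds form the combined restraint.

# The desk-scale refiner

The refiner stands in for a full structure-calculation engine so the loop
is executable end to end. It is *not* a re-implementation of such an
engine: no torsion-angle dynamics, no conformational database or
Ramachandran potential, no solvent refinement. The model is a backbone
representation (N, H, CA, CB, C′, O per residue) with a pseudo-energy of

* harmonic bond and angle terms at ideal values,
* flat-bottom dihedral terms for ω, amide planarity, Cβ chirality and the
  φ/ψ torsion restraints,
* the flat-bottom quadratic ADR term on r\(^{-6}\)-pooled effective
  distances,
* a soft CA–CA repulsion (onset 4.0 Å).

Side-chain carbons beyond Cβ are represented by Cβ with a pseudo-atom
correction subtracted from the option distance (CG 1.6, CD 2.8, CE 3.9,
CZ 4.4, CH 4.9 Å), clamped at the restraint's lower bound — without the
correction, genuine side-chain contacts are violated by the true
structure itself.

Each model is annealed independently: overdamped Langevin dynamics with a
linear cooling schedule, covalent geometry softened during the hot phase
(0.1× force constants, letting the restraint network pull the topology
together before the geometry hardens), followed by a FIRE quench. Models
start from a distance-geometry embedding of the unambiguous restraint
network: a sparse graph of covalent bonds, 1–3 distances and unambiguous
restraint midpoints is completed by shortest-path bound smoothing and
embedded with classical multidimensional scaling; restraint edges grossly
inconsistent with a first embedding (> 4 Å error) are dropped and the
graph re-embedded, which protects the metric against occasional wrongly
assigned restraints acting as shortcuts. Because a distance-only embedding
is defined up to reflection, alternate models start from the mirrored
embedding and the pseudo-energy decides which handedness survives
selection. With zero distance restraints the engine simply
geometry-regularizes an extended chain. The full-scale annealing
parameters (20000 K high temperature, two 100000-step cooling stages,
8000 refine steps) are stored as reference configuration
(`table2_reference()`); the desk-scale schedule divides the step counts by
roughly 100 and maps temperatures onto the engine's reduced units.

# The synthetic generator

`build_ideal_sheet()` constructs ideal antiparallel sheets: strands at
φ = −139°, ψ = +135°, ω = 180°, tetrahedral N–CA–C (109.5°), N–H 1.02 Å,
and adjacent strands placed by a least-squares fit onto canonical
narrow-ring hydrogen-bond targets (N⋯O 2.85 Å, collinear N–H⋯O; the
length sits in the canonical 2.7–3.0 Å range). With these parameters the
facing amide protons of hydrogen-bonded residues come out at ~3.3 Å and
sequential amide protons at ~4.3 Å, the textbook values for an ideal
antiparallel sheet. Barrel mode wraps the sheet on a cylinder whose
circumference matches the strand spacing (closing strand n against
strand 1) and then relaxes the wrapped model under ideal geometry with
tight registry hydrogen-bond restraints: the raw wrap strains covalent
geometry, and the regularized model is the physically consistent ground
truth that contacts and recovery statistics refer to. Short flexible
loops (2 residues by default) join consecutive strands; loop residues are
numbered but left unassigned, emulating flexible loops invisible to
cross-polarization-based experiments.

Chemical shifts are residue-type-typical means plus seeded Gaussian
jitter; the default dispersions (σ = 7 ppm for \(^{15}\)N, 1.2 ppm for
amide \(^1\)H, 1.5 ppm for carbons) are at the generous end of what folded
β-barrels show. This choice is deliberate: the test systems are an order
of magnitude smaller than a real membrane protein, and at realistic-centre
dispersion the small residue count leaves entire strand pairs without a
single unambiguous restraint — a small-number artifact, not a feature of
the method. Peak simulation emits both transfer directions per contact
(four peaks per fully visible amide pair across the spectrum pair),
per-residue auto-correlation peaks in the 3D spectra, r\(^{-6}\)
intensities with optional multiplicative noise, and carbon peaks gated by
the labeling scheme of the sample. Contact cutoffs: 4.6 Å for the 2 ms
proton mixing (facing and sequential contacts), 3.0/5.5/7.0 Å for
short/medium/long carbon mixing. `synthetic_study()` assembles the
complete study: the amide spectrum pair plus a 12-sample panel of
selectively labeled carbon spectra, each with a short-mixing companion
for intra-residue exclusion — the multi-scheme panel is what makes a
useful number of carbon restraints unambiguous, mirroring the role of
amino-acid-type selective labeling in the real experiment.

What passing tests on this generator do *not* show: performance under
realistic noise and incomplete assignment, spectra with baseline or
artifact peaks, spin-diffusion build-up effects, or side-chain proton
chemistry (the generator has no side chains beyond Cβ).

# Desk-scale end-to-end configuration

The end-to-end recovery analysis runs an 8-strand × 8-residue barrel with
noise-free peaks through 5 iterations of 20 models with the 3
lowest-energy selected, carbon restraints entering at iteration 2 (the
scaled equivalent of 4-of-9), violation tolerances 1000/3/1/0.5/0.1 Å,
ambiguity pruning only in the last two iterations (cutoffs 0.98, 0.95)
and no restraint combination: combination is a noise-robustness device
that in noise-free conditions only discards information and starves the
distance-geometry initialization of unambiguous edges. After the
iterations, hydrogen-bond couples are read off the converged bundle and a
final run adds the co-linear restraints. The problem sizes (20 models,
~16 k annealing steps per model) keep the complete analysis in the
minutes range on a single CPU.

# Known limitations

* **Global handedness.** Distance-class restraints on flat ideal strands
  carry almost no chirality signal about the global winding of a barrel;
  real calculations resolve handedness through sheet twist and full force
  fields, which the desk-scale engine deliberately lacks. The engine
  competes both handednesses (mirrored embeddings) and energy ranking
  favours the true one, but the margin is small and a mirror-winding
  model can enter the selected bundle for some realizations.
* **Backbone-level model.** Side-chain information enters only through
  Cβ proxies with pseudo-atom corrections; restraint networks dominated
  by long side-chain contacts are represented coarsely.
* **Intensity classes.** The intensity split into 1.0–3.5/1.0–5.5 Å
  classes degrades gracefully (everything wide) when spurious sequential
  options contaminate the strongest peaks; it never misclassifies into
  tighter bounds.
* **The annealer is a refinement engine, not a folding engine.** Its
  convergence relies on the distance-geometry initialization; with very
  sparse unambiguous networks the embedding is underdetermined and the
  ensembles reflect that.
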