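# adriter

Ambiguous distance restraints and iterative assignment for solid-state
MAS NMR structure determination, in R.

## The problem

Through-space cross peaks in MAS NMR spectra of membrane proteins are not
uniquely assignable: any pair of assigned nuclei whose chemical shifts lie
within the matching tolerances of a peak position is a candidate. The
standard treatment turns every peak into an **ambiguous distance
restraint** (ADR) — a distance class `[L, U]` attached to a set of
candidate atom pairs — and resolves the ambiguity iteratively during the
structure calculation. The restraint energy uses the r⁻⁶-pooled
effective distance over the assignment options o,

    d_eff = ( Σ_o d_o⁻⁶ )^(−1/6) ,

which is dominated by the shortest option, so a restraint is satisfiable
as soon as one candidate pair is close. After each iteration the
lowest-energy structures drive **violation analysis** (restraints outside
bounds ± tolerance in at least half of the selected models are rejected,
recoverably) and **ambiguity pruning** (the smallest option prefix whose
cumulative r⁻⁶ weight reaches a decreasing cutoff is retained).

`adriter` implements this pipeline for the amide-proton and
carbon-carbon spectra of a perdeuterated / selectively ¹³C-labeled
sample set: labeling-scheme-aware matching (assignment options are kept
only when the product of the two carbon enrichment fractions exceeds
10%), the four-fold-redundancy filter of the paired 3D amide spectra,
intensity-based distance classes (1.0–3.5 / 1.0–5.5 Å for ¹H,
1.5–8.0 Å for ¹³C), co-linear hydrogen-bond restraints (H–O 1.73–2.70,
N–O 2.52–3.93 Å) and TALOS-style torsion restraints, plus a desk-scale
simulated-annealing refiner (Rcpp) and a synthetic β-barrel generator so
the whole loop runs end to end without experimental data.

## A worked example

```r
library(adriter)

# a synthetic 2-strand antiparallel sheet: the generator's geometry
spec  <- sheet_spec(n_strands = 2, residues_per_strand = 6, seed = 1)
sheet <- build_ideal_sheet(spec)
reg   <- attr(sheet, "registry")
nar   <- reg[reg$narrow, ][1, ]                      # an H-bonded facing pair
atom_distance(sheet, 1, nar$res_i, "H", nar$res_j, "H")
#> [1] 3.348583
atom_distance(sheet, 1, 3, "H", 4, "H")              # sequential neighbours
#> [1] 4.33276
```

The facing amide protons of hydrogen-bonded residues sit at ~3.3 Å, the
sequential ones at ~4.3 Å — the two distances behind the short and wide
¹H distance classes.

```r
# restraint generation on a simulated study
spec  <- sheet_spec(8, 8, barrel = TRUE, seed = 7)
study <- synthetic_study(spec, seed = 7)
adr_stats(study$h_adrs)
#> $total          [1] 139
#> $active         [1] 139
#> $unambiguous    [1] 48
#> $mean_ambiguity [1] 2.8

# the iterative assignment loop (desk scale: 5 iterations, 20 models)
cfg <- protocol_config(n_iterations = 5, n_structures = 20, n_select = 3,
                       c_from_iteration = 2, combine_iterations = integer(0),
                       violation_tolerance = c(1000, 3, 1, 0.5, 0.1),
                       ambiguity_cutoff = c(1, 1, 1, 0.98, 0.95), seed = 17)
fit <- run_protocol(study$truth$atoms, study$h_adrs, study$c_adrs,
                    study$torsions, config = cfg,
                    anneal_cfg = anneal_config(seed = 17))
summary(fit)[, c("iteration", "restraints_used", "mean_ambiguity")]
#>   iteration restraints_used mean_ambiguity
#> 1         0             139           8.38
#> 2         1             139           8.38
#> 3         2             732           8.38
#> 4         3             732           2.63
#> 5         4             732           1.70
```

The mean number of assignment options per restraint drops from 8.4 to 1.7
as the ensembles converge. A final run then adds co-linear hydrogen-bond
restraints for couples read off the converged bundle
(`derive_hbond_couples()` + `colinear_hbond_table()`).

A thin command-line wrapper (`inst/scripts/adr`) exposes the stages as
subcommands: `simulate`, `h-match`, `c-match`, `hbonds`, `torsions`,
`protocol`, `report`.

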