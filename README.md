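# scassembly

Simulation and quantification tools for studying **head-to-head
self-assembly of SYCP1**, the transverse filament protein of the
synaptonemal complex (SC). In meiosis, SYCP1 dimers from the two
homologous chromosome axes meet at the SC midline and self-assemble
through their N-terminal tips (the αNtip, human residues 101–111);
glutamate substitution of the conserved tip leucines (human V105/L109,
mouse L102/L106) weakens this head-to-head interface, and loss of the
interface manifests as aligned but unsynapsed chromosomes. This package
provides, for researchers working on SC assembly and similar
filament-interface problems:

* a **coarse-grained steered-dissociation assay**: overdamped Brownian
  dynamics of two bead-chain dimers joined head-to-head through
  genotype-scaled attractive tip wells, pulled apart by opposing axial
  per-bead forces (`build_tetramer_model()`, `simulate_assembly()`);
* **trajectory metrics**: Kabsch superposition RMSD
  (`kabsch_superpose()`, `rmsd_series()`), per-residue RMSF (`rmsf()`),
  the interdimer marker distance (human L109 / mouse L106 centroids;
  `interdimer_distance()`), and an intact / loosened / dissociated
  classification with disruption time (`detect_dissociation()`: intact
  below 10 Å, dissociated once the distance persistently exceeds 30 Å);
* a **synthetic imaging generator**: SIM-like z-stacks of two parallel
  fluorescent axes at known separation with Gaussian PSF, focal envelope
  and Poisson–Gaussian noise (`synthesize_axis_pair_stack()`), plus
  overdispersed per-tubule apoptosis counts
  (`synthesize_tubule_counts()`);
* the matching **image quantification**: trace straightening, ten
  perpendicular profiles of thickness 3, double-Gaussian peak fitting of
  axis separation, max±2-slice projection and background-subtracted
  integrated ROI intensity (`measure_axis_separation()`,
  `measure_roi()`);
* **statistics**: Mann-Whitney U, Fisher's exact test on counts
  dichotomized at five-or-more labelled nuclei, unpaired t tests — with
  independent enumeration oracles (`mann_whitney_enum_p()`,
  `fisher_enum_p()`, `rmsd_rotation_search()`) used for validation.

The core measurement of the steered assay is the distance between the
marker residues of the two opposing dimers,
*d*(t) = ‖centroid₁(L109) − centroid₂(L109)‖: below 10 Å the interface is
intact; a sudden, persistent increase marks interface disruption, and the
first persistent crossing of the dissociation threshold is the disruption
time. Axis separation in images is measured per profile as |μ₂ − μ₁| ×
pixel size from a two-Gaussian fit I(x) = A₁G(x; μ₁, σ₁) + A₂G(x; μ₂, σ₂) + c.

## Worked example

```r
library(scassembly)

# Steered dissociation at the mid force (0.05 kJ/mol/nm per bead)
run_dissociation_assay("WT", force = 0.05, seed = 1)
#> dissociation_result: intact (thresholds 10/30 A, window 5)
run_dissociation_assay("L102E/L106E", force = 0.05, seed = 1)
#> dissociation_result: dissociated at 30.00 ns (thresholds 10/30 A, window 5)

# Synthetic unsynapsed axis pair (365 nm apart), measured back
sy <- synthesize_axis_pair_stack(axis_pair_truth(separation_nm = 365, seed = 1))
m <- measure_axis_separation(sy$stack, sy$trace)
sprintf("measured %.1f nm (n_valid = %d) -> %s",
        m$mean_separation_nm, m$n_valid, m$classification)
#> [1] "measured 364.4 nm (n_valid = 10) -> unsynapsed"

# Tubule apoptosis counts, dichotomized at >= 5, Fisher's exact test
wt  <- synthesize_tubule_counts(tubule_count_model(200, burst_fraction = 0.015), seed = 1)
mut <- synthesize_tubule_counts(tubule_count_model(200, burst_fraction = 0.16), seed = 2)
tab <- count_table_2x2(dichotomize_tunel(wt), dichotomize_tunel(mut),
                       genotypes = c("control", "mutant"))
tab
#>          tubules
#> genotype  lt_threshold ge_threshold
#>   control          198            2
#>   mutant           169           31
fisher_exact_2x2(tab)
#> Fisher's exact (two.sided, hypergeometric (minimum likelihood)):
#>   statistic = 18.0668, p = 4.3112e-08, n = 200/200
```

The wild-type interface holds under steering while the double mutant's
tip interface ruptures and the dimers drift apart; the imaging pipeline
recovers the known 365 nm axis separation to within a nanometre and
classifies the pair as unsynapsed (threshold 250 nm); and the mutant's
excess of high-apoptosis tubules is detected by Fisher's exact test.

A command-line wrapper for each stage ships in `inst/cli/scassembly.R`
(`simulate`, `analyze-traj`, `synth-images`, `synth-counts`, `pipeline`),
and `run_pipeline()` executes a whole configured study
(`inst/extdata/demo_config.yaml`) writing TSV/JSON outputs and a replayable
manifest.

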