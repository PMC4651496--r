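# epimapr

Antibody epitope mapping on small antigens from four independent lines
of computational evidence: NMR chemical shift perturbation (CSP), ¹⁵N
relaxation, docking-ensemble contact profiling, and cross-family
sequence conservation. The motivating system is the major fish allergen
beta-parvalbumin (Gad m 1 and relatives) in complex with a
cross-reactive single-chain antibody fragment (scFv), but every
operator takes plain tabular or standard-format inputs and is
system-agnostic.

## What it computes

For each residue of an antigen observed free and in complex, the
composite amide perturbation is

    CSP = |ΔδH| + 0.1 · |ΔδN|      (ppm)

Residues with CSP strictly above a threshold (default 0.028 ppm) form
the CSP-derived epitope; residues whose signals disappear on complex
formation (exchange broadening) are reported as a separate class.
Complex formation is independently diagnosed from ¹⁵N R1/R2 rates
fitted per residue from mono-exponential decays (the R2/R1 ratio tracks
rotational correlation time). From a rigid-body docking ensemble, a
residue's contact frequency is the fraction of poses in which at least
one of its heavy atoms lies within 5 Å (inclusive) of a heavy atom of
the antibody CDR region. Shrake–Rupley solvent accessibility checks
that mapped residues are exposed, and Clustal-style conservation
symbols (`*`, `:`, `.`) over a family alignment quantify why an
antibody binding those residues cross-reacts. A pipeline joins all of
this into one per-residue table plus TSV/JSON reports, and a
synthetic-data module generates every input with planted ground truth
so the whole analysis is testable end to end.

## Worked example

Generate a synthetic study (108-residue antigen, planted 29-residue
epitope of which 2 residues' signals disappear, 300 docking poses) and
run the full pipeline:

```r
library(epimapr)

cfg <- simulation_config(seed = 1, n_poses = 300)
b <- simulate_bundle(cfg, tempfile())

pcfg <- pipeline_config(
  shift_free  = b$paths$free,
  shift_bound = c(bound_40uM = b$paths$bound_40uM,
                  bound_70uM = b$paths$bound_70uM),
  decays = list(r1_free = b$paths$decay_r1_free,
                r2_free = b$paths$decay_r2_free,
                r1_complex = b$paths$decay_r1_complex,
                r2_complex = b$paths$decay_r2_complex),
  structure = b$paths$antigen, poses = b$paths$poses,
  scores = b$paths$scores, alignment = b$paths$alignment,
  cdr = 3:8)

report <- run_pipeline(pcfg)
report
#> <analysis_report>
#>   CSP: 27 significant (> 0.028 ppm), 2 disappeared [bound_70uM]
#>   regions (mapped): n_terminus=5, ab_cd_axis=9, cd_site=7, around_80=5, c_terminus=3
#>   docking epitope: 29 residues; Jaccard vs CSP = 0.931
#>   median R2/R1: complex=23.09, free=6.26
```

27 residues carry a significant CSP and 2 more disappeared, so the full
mapped set of 29 distributes 5 / 16 / 5 / 3 over N-terminus, the
CD-loop-proximal region (AB/CD axis + CD site), the region around
residue 80, and the C-terminus. The docking ensemble independently
recovers the same epitope (Jaccard 0.931 against the CSP set, which
lacks the two disappeared residues), and the complex tumbles ~3.7×
slower than the free antigen by median R2/R1.

```r
report$csp$classification$epitope
#> <epitope_set> csp_epitope (csp): 27 residues
#>   7 8 11 12 15 29 30 31 32 33 36 38 41 44 51 53 54 56 59 76 78 80 82 84 102 106 108

epitope_overlap_report(report$csp$classification$epitope)
#> # A tibble: 5 × 6
#>   name              start   end interval_size overlap jaccard
#>   <chr>             <int> <int>         <int>   <int>   <dbl>
#> 1 ab_cd_axis_28_45     28    45            18       9  0.25
#> 2 c_terminus_95_109    95   109            15       3  0.0769
#> 3 around_80_75_85      75    85            11       5  0.152
#> 4 window_30_40         30    40            11       6  0.188
#> 5 window_50_60         50    60            11       5  0.152
```

`write_report(report, "out/")` writes the TSV bundle and a versioned
JSON document; `plot_csp()`, `plot_contact_frequency()` and
`plot_relaxation()` draw the standard figures, and
`annotate_structure()` paints any per-residue score into a PDB
B-factor column for molecular viewers. A thin command-line wrapper
lives at `inst/scripts/epimap.R` (`simulate` and `pipeline`
subcommands).

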