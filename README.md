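# vuscope

Computational interpretation of *CHEK2* missense variants of uncertain
significance (VUS), for clinical-genetics and structural-bioinformatics
researchers who need each evidence line reproducible and separately
auditable. The package implements five analysis stages plus seeded
synthetic-data generators, so the whole pipeline runs offline:

* **Ensemble verdict-rate classifier** — reduces the verdicts of 15
  pathogenicity predictors to the benign rate *r* = n\_B / (n\_B + n\_P)
  (missing verdicts excluded from both counts) and compares *r* to three
  operating-mode thresholds: pathogenic when *r* ≤ 0.40 (high-coverage),
  ≤ 0.24 (intermediate) or ≤ 0.08 (low-FPR), otherwise VUS. Ties at a
  threshold go pathogenic, and classification uses the unrounded rate.
* **Conservation** — per-column residue frequencies and information
  content *I* = log₂20 − *H* from a multiple sequence alignment, with
  high/moderate/low categories for the mutated positions.
* **Structural geometry** — hydrogen bonds, salt bridges, cation–π
  interactions, inter-chain proximity, Shrake–Rupley solvent exposure and
  a volumetric substitution clash screen on static PDB coordinates.
* **Trajectory stability** — global per-frame metrics (RMSD, Rg, SASA,
  native-contact fraction, TM-score, H-bond counts), pairwise-RMSD
  (2D-RMSD) GROMOS clustering of the 1-nm neighbourhood around a
  mutation site, basal-cluster stability verdicts, dimer bound/unbound
  calls and replica aggregation ("2/3 (67%)").
* **Cohort & cosegregation** — descriptive proband statistics and a
  qualitative consistent/excluded/uninformative cosegregation tally.

## Worked example

The packaged fixture `table2.tsv` transcribes the per-predictor verdicts
of seven *CHEK2* VUS found in a breast-cancer cohort:

```r
library(vuscope)
tab <- parse_predictor_table(system.file("extdata", "table2.tsv", package = "vuscope"))
classify_all(tab)[, c("variant_id", "n_benign", "n_na", "rate_reported",
                      "high_coverage", "intermediate", "low_fpr")]
#>   variant_id n_benign n_na rate_reported high_coverage intermediate low_fpr
#> 1      Q100H        7    0          0.47           VUS          VUS     VUS
#> 2      T168I        0    0          0.00             P            P       P
#> 3      H282D        1    0          0.07             P            P       P
#> 4      H345Y        1    0          0.07             P            P       P
#> 5      A392V        1    1          0.07             P            P       P
#> 6      P471L        2    0          0.13             P            P     VUS
#> 7      R474C        0    0          0.00             P            P       P
```

Reading the output: T168I drew no benign verdicts (rate 0.00), so it is
called pathogenic in every mode. A392V has one benign verdict and one
missing predictor, giving 1/14 = 0.0714 → reported 0.07, still below the
strictest threshold. P471L's 2/15 = 0.13 clears the 0.40 and 0.24
thresholds but not 0.08, hence P/P/VUS; Q100H's 0.47 exceeds all three
and stays a VUS throughout.

The cohort stage reproduces the study's descriptive statistics from the
`table1.tsv` fixture:

```r
rec <- load_cohort(system.file("extdata", "table1.tsv", package = "vuscope"))
prevalence(rec, 396, "VUS")$percent      # 1.77  (7 of 396 patients)
describe(rec, "P_LP")$mean_age           # 60.7  (range 56-64)
cosegregation(load_pedigree(system.file("extdata", "pedigree8.json",
                                        package = "vuscope")))$verdict
#> "consistent"   (affected sister tested, carries the variant)
```

A stability analysis on a synthetic trajectory with a planted local
departure at frame 250 recovers the planted instability:

```r
ref <- gen_structure("ideal_helix", list(length = 30))
trj <- gen_trajectory(ref, "local_departure", 500, noise_sigma = 0.5,
                      params = list(site = c("A", 15), t0 = 250,
                                    displacement = 6), seed = 21)
sel <- local_selection(ref, c("A", 15), radius = 1.0)
v <- stability_verdict(cluster_frames(rmsd_matrix(trj, sel)))
v$verdict          # "unstable"
v$departure_frame  # 253 (planted: 250)
```

`run_pipeline()` (or `inst/cli/vuscope.R run --config run.yaml`) merges
all enabled stages into per-variant evidence dossiers
(`dossiers.tsv`, `dossiers/*.json`) plus a manifest of config and input
hashes; dossiers report the evidence lines independently and never
combine them into a single pathogenicity call.

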