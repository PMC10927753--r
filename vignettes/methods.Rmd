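---
title: "Methods: computational interpretation of CHEK2 missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computational interpretation of CHEK2 missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vuscope)
```

## Scope and scientific setting

Missense variants of uncertain significance (VUS) in *CHEK2* — the gene
encoding the Chk2 checkpoint kinase — are common findings in hereditary
breast cancer panels, and their interpretation typically rests on several
independent evidence lines: in-silico predictor ensembles, evolutionary
conservation, the variant's structural context in the FHA
(phosphopeptide-binding, residues ~113–175) and kinase (~220–486) domains,
conformational-stability arguments from molecular dynamics, and family
cosegregation. `vuscope` implements each of these evidence lines as an
auditable, separately testable stage, together with seeded synthetic-data
generators so the entire pipeline can be exercised without any external
download. Dossiers assembled by `run_pipeline()` report the evidence lines
side by side and deliberately never combine them into a single
pathogenicity call: evidence integration (e.g. ACMG weighting) is a
judgement the tool does not automate.

## The ensemble verdict-rate classifier

Each variant carries verdicts from 15 established pathogenicity predictors
(SIFT through CADD; `predictor_panel()`). The classifier reduces them to a
single *benign rate*

$$r = \frac{n_B}{n_B + n_P},$$

the fraction of benign verdicts among the non-missing ones, and compares
$r$ against one threshold per operating mode: 0.40 (high-coverage), 0.24
(intermediate) and 0.08 (low false-positive-rate). The variant is called
pathogenic in a mode when $r$ is at or below that mode's threshold,
otherwise it stays a VUS. Three numerical conventions matter and are fixed
by the reference table the packaged fixture transcribes:

* **Ties go pathogenic.** A variant with 1 benign verdict of 15 has
  $r = 0.0667 \le 0.08$ and is pathogenic at the low-FPR mode; comparing
  the *rounded* 0.07 would give the same answer here, but classification
  always uses the unrounded rate.
* **Missing verdicts shrink the denominator.** One NA among 15 verdicts
  with one benign gives $1/14 = 0.0714$, still below 0.08.
* **Display rounding is half-up** to two decimals (`round_half_up()`);
  R's default half-to-even rounding would print some rates differently.

Verdicts are explicit inputs rather than being derived from the predictor
scores: the same numeric score can be benign for one variant and
pathogenic for another because each predictor uses its own optimized,
variant-independent cutoff upstream of this package. Scores are therefore
carried as metadata only. The classifier has no benign output class — the
reference operating points define only the pathogenic-vs-VUS boundary, and
inventing a benign-side threshold would not be testable against anything.

## Conservation from multiple sequence alignments

`column_profile()` computes residue frequencies over the non-gap symbols
of an alignment column and the information content
$I = \log_2 20 - H$ with $H = -\sum_a f_a \log_2 f_a$, so an invariant
column scores $\log_2 20 \approx 4.32$ bits and a uniform column 0 bits.
No small-sample correction is applied by default (a Miller–Madow flag is
available); with the ~500-sequence alignments this package targets, the
bias is small compared to the categorical thresholds that consume it.
Gaps (and the ambiguity codes B/Z/X) are excluded from frequencies but
reported as a gap fraction; columns over 50% gap are flagged unreliable.
Qualitative categories mirror the two labels used in practice: *high*
requires the reference residue to be modal with frequency ≥ 0.80;
*moderate* requires rank ≤ 3 with frequency ≥ 0.05 (the pattern of a
position where another residue predominates but the reference is well
represented, as at Gln100 where Gly dominates); everything else is *low*.
These cutoffs are calibration choices — the source material gives labels,
not numbers — and all three are exposed as arguments.

## Static interaction geometry

Detectors operate on heavy-atom coordinates (crystal structures rarely
include hydrogens, so the default hydrogen-bond test is distance-only; a
donor–H–acceptor angle test switches on when hydrogens are present):

| interaction | criterion | default |
|---|---|---|
| hydrogen bond | donor–acceptor N/O distance | ≤ 3.5 Å (angle ≥ 120° with H) |
| salt bridge | min N–O distance between charged groups | ≤ 4.0 Å |
| cation–π | cation to ring centroid, off-normal angle | ≤ 6.0 Å, ≤ 60° |
| burial | side-chain SASA ratio | exposed ≥ 0.25, buried < 0.10 |

These cutoffs follow common structural-biology practice, since the work
this package operationalizes states none; every one is a function
argument. Histidine is treated as a potential cation by default
(toggleable), matching the reported His–Tyr cation/π contact. Residue
numbering always follows the source PDB's author numbering.

Solvent accessibility uses an in-package Shrake–Rupley implementation
(probe 1.4 Å, deterministic golden-spiral sphere points, 960 by default
and never fewer than 192). Relative side-chain exposure divides the
side chain's SASA in context by the SASA of the same residue isolated
with its own backbone, computed with the identical discretization. This
runtime reference makes the ratio exactly 1 for an isolated residue and
self-consistent across point counts, which a static maximum-area table is
not; glycine falls back to its Cα as the side-chain proxy.

The substitution screen is deliberately a proxy, not an energy model: it
reports the change in tabulated mean residue volume and the heavy-atom
crowding (neighbour count within 5 Å of the side-chain centroid,
threshold 30) and flags "potential clash" only when a substitution grows
into a dense environment. The report carries raw numbers so a reader can
apply different thresholds.

## Trajectory stability assessment

The trajectory stage mirrors the analysis style of relaxation-MD studies:
global per-frame metrics to establish that the fold is retained, then a
*local* clustering analysis around the mutation site to detect sustained
conformational departure.

Global metrics (`global_series()`): heavy-atom RMSD after Kabsch
superposition (reported in nm, with < 1.0 nm over all frames used as the
coarse global-stability flag), radius of gyration, Shrake–Rupley SASA,
fraction of native contacts, hydrogen-bond counts (intra-protein and
protein–water), TM-score and dihedral-bin secondary-structure fractions
(α: φ ∈ [−100, −30], ψ ∈ [−80, −5]; β: φ ∈ [−180, −40], ψ ∈ [60, 180]).
Native contacts are defined on frame 0 as heavy-atom pairs under 4.5 Å
between residues at sequence separation ≥ 4 (or on different chains),
retained while within 1.2× their reference distance; the fraction is 1 at
frame 0 by construction. The TM-score uses
$d_0 = 1.24\,(L-15)^{1/3} - 1.8$ Å on the Kabsch superposition of the
Cα trace — a lower bound on the full TM-score maximization, sufficient
for its role as a coarse fold-retention flag (> 0.5), with the self-score
equal to 1.

Local analysis: `local_selection()` takes every residue with a heavy atom
within 1 nm of the site; `rmsd_matrix()` computes the pairwise (2D) RMSD
between strided frames on that selection, each pair superposed
independently; `cluster_frames()` applies deterministic GROMOS-style
neighbour counting (cutoff 0.15 nm, ties to the lowest frame index). The
*basal cluster* is the cluster containing frame 0 even when it is not the
most populated, anchoring stability to the starting, crystal-like
conformation. `stability_verdict()` operationalizes "sustained departure"
as final-window occupancy: the trajectory is unstable when at least 50%
of the last 25% of frames lie outside the basal cluster. Point excursions
that return immediately therefore stay stable, which is the behaviour the
verdict language of the underlying studies requires; both the window and
the threshold are arguments. The stride, cluster cutoff and atom subset
(heavy atoms) are likewise configurable, since the source analyses do not
state them. Dimer association (`dimer_state()`) counts inter-chain
heavy-atom contacts under 4.5 Å in the final window and calls the dimer
unbound below a mean of 10 contacts — the state depends only on the final
window, so a drift too slow to break contact by the end stays bound.
`replica_summary()` aggregates replicas worst-case (any unstable chain
makes the replica unstable) and formats the fraction exactly as
`"k/n (p%)"` with half-up percentage rounding.

Units follow the MD literature: nm for reported RMSD/Rg/cutoffs, Å for
raw coordinates, converted only at the interface.

## Cohort statistics and cosegregation

`prevalence()` and `describe()` are deliberately plain: percentage of
matching probands among all tested patients and per-class age summaries,
all under one explicit rounding rule (half-up). Published figures derived
under different implicit conventions are *not* silently matched: the
packaged cohort's pathogenic prevalence computes to 0.76% (3/396
half-up), and the mean VUS age over all seven records to 48.6 years; the
corresponding published figures (0.75%, 45.2 over an apparent six-record
subset) can be reproduced only by changing the rule, so the package
reports computed values and leaves the discrepancy visible.

`cosegregation()` is a qualitative tally, not a likelihood or Bayes-factor
method, because the study design it mirrors performs none: *excluded* as
soon as any tested affected relative lacks the variant, *consistent* when
at least one tested affected relative besides the proband carries it (and
none excludes), *uninformative* otherwise. Exclusion dominates.
Untested individuals can never influence the verdict.

## What the synthetic generators emulate — and what they do not

All generators take an explicit integer seed and restore the session RNG
state (`withr::with_seed`); identical inputs give byte-identical outputs.
Each planted parameter is recoverable by the corresponding analysis
stage, which makes the generators the oracles for the parameter-recovery
tests.

* `gen_predictor_table()` draws i.i.d. B/NA/P verdicts; it emulates the
  *structure* of a predictor table, not correlations between predictors
  (real ensemble members are strongly correlated).
* `gen_msa()` plants per-column conservation: the consensus residue with
  probability $c_j$, otherwise a residue uniform over the other 19, so
  the consensus frequency converges to $c_j$ itself. Row 1 is the
  consensus (the target sequence). Phylogenetic correlation between rows
  is absent by design.
* `gen_structure()` builds poly-Ala helices and hairpins from exact
  backbone geometry (NeRF chain construction; helix φ = −57°, ψ = −47°),
  probe fixtures with interactions planted at exact distances and
  angles, and side-by-side helix dimers whose minimum inter-chain
  distance is tuned to the requested value within 1e−6 Å
  (separation 2.5 Å with 20-residue chains plants a 40-contact
  interface).
* `gen_trajectory()` produces statistical stand-ins, not physics: frames
  are the reference plus isotropic Gaussian noise whose `noise_sigma` is
  the per-atom RMS displacement in Å (per-coordinate s.d.
  σ/√3 — under this convention two independent frames sit
  ≈ √2·σ apart, which keeps σ ≤ 1 Å trajectories inside the 0.15 nm
  clustering cutoff, as a stable trajectory should be). Local departures
  rigidly displace the residues within `radius` (default 10 Å) of the
  site *centroid* from frame `t0` on; because the analyzer's 1-nm window
  reaches from all site atoms, the window strictly contains unmoved
  anchor residues and the planted displacement survives pairwise
  superposition. Dissociation translates one chain at constant velocity.

Passing tests on these inputs demonstrate that the analyzers recover
planted signals under controlled noise; they do not demonstrate anything
about force fields, solvent, or the microsecond dynamics of real
proteins, which are outside this package's scope.

## Numerical choices and degenerate inputs

* Superposition is closed-form Kabsch via 3×3 SVD with the determinant
  sign correction; fewer than three atoms or a collinear selection is a
  degenerate-selection error.
* An all-NA verdict row, an all-gap alignment column, a single-chain
  dimer query, a TM-score on ≤ 15 residues and a single-frame RMSF are
  explicit typed errors, not NaNs.
* Alternate locations in PDB files resolve to the highest-occupancy
  conformer (ties: first in file). Waters and heteroatoms are kept but
  tagged, and excluded from protein-only analyses.
* GROMOS clustering is fully deterministic given the matrix; ties in
  neighbour counts break to the lowest frame index.

## Problem sizes used by the test suite

The suite exercises 1000-frame trajectories of a 30-residue helix for
departure-recovery and false-positive checks (20 seeds each), 500-sequence
alignments for conservation recovery, 50-residue random fixtures for the
brute-force geometry oracles, and the full $2^{15}$ verdict-pattern
enumeration for the classifier. These sizes keep the complete run inside
a few minutes on a single core while leaving each statistical check at
least three standard errors of resolution.

## Known limitations

* The classifier consumes predictor verdicts; it cannot run the
  predictors, so upstream verdict quality bounds its output.
* The substitution screen is volumetric; it has no rotamers, no
  electrostatics and no ΔΔG.
* The trajectory stage analyzes trajectories; it does not generate
  physical ones, and the synthetic generators' noise model is
  frame-independent (no autocorrelation).
* Cosegregation is qualitative and proband-anchored; penetrance and
  likelihood modelling are out of scope.
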