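---
title: "Ratiometric secretome profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric secretome profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the statistic

Conditioned-media proteomics is confounded by leakage: damaged cells release
cytoplasmic protein into the medium, so detecting a protein in the media does
not show it is secreted. The ratiometric approach quantifies each protein in
*both* the conditioned media (M) and the cell lysate (L) and uses the M/L
abundance ratio as the discriminating statistic. A protein that is actively
exported accumulates in the media relative to its intracellular pool
(M/L above 1, often far above), whereas a leaked cytoplasmic protein appears
in the media only in proportion to the leaked fraction of cells (M/L well
below 1, and roughly constant across proteins). Treatment with brefeldin A
(BFA), which blocks Arf1-dependent ER-to-Golgi transport, provides a causal
check: conventionally secreted cargo is depleted from the media and
accumulates in the lysate, while cargo exported by ER/Golgi-independent
("unconventional") routes is unaffected. `secretr` implements this pipeline
from the PSM (peptide-spectrum match) tables of TMT 6-plex experiments
through to per-protein secretome calls, plus a ground-truth generator that
makes every stage testable.

# Quantification model

Each MS experiment (one for media, one for lysate) carries six reporter
channels: three control replicates and three BFA replicates. Quantification
proceeds PSM by PSM:

1. **Quality filters** (`filter_psms()`): PSMs with no TMT label, precursor
   purity strictly below 0.5, summed reporter intensity at or below the
   run's 5th percentile (nearest-rank convention, computed after the first
   two filters), or mapping to contaminant accessions are removed.
2. **Peptide-ion deduplication** (`deduplicate_peptide_ions()`): among
   redundant PSMs of one peptide ion (same run, sequence, charge and
   modification state) only the highest-summed-intensity PSM is kept; exact
   ties break to the smallest spectrum id.
3. **Protein grouping and FDR** (`infer_protein_groups()`, `fdr_filter()`):
   accessions with identical peptide sets merge; shared peptides are
   razor-assigned to the group with the most distinct peptides. Groups are
   ranked by their best (smallest) peptide posterior error probability and
   filtered at 1% protein-level FDR by decoy counting (no +1 correction by
   default; `plus_one = TRUE` switches the conservative estimator on),
   followed sequentially by a 1% PSM-level decoy filter among PSMs mapping
   to the surviving prefix of the ranking.
4. **Virtual-reference ratios** (`psm_log2_ratios()`): within each PSM, each
   channel is expressed as a log2 ratio to the geometric mean of the PSM's
   positive channels. This makes ratios invariant to peptide ionization
   efficiency and to any per-spectrum scaling.
5. **Rollup** (`rollup_protein_ratios()`): the protein-by-channel ratio is
   the median of its PSM ratios after a Tukey fence (values outside
   quartiles +/- 1.5 IQR dropped, applied only with at least four values).
6. **Absolute reconstruction** (`reconstruct_absolute()`): the per-protein
   reference intensity is the sum of all its reporter intensities divided by
   the channel count, so a flat-ratio protein's absolute intensity equals
   its mean per-channel signal; channel absolutes are
   `reference * 2^ratio`, which preserves every cross-channel ratio.

Per-replicate M/L is the ratio of paired media and lysate channel absolutes;
the per-condition summary is the geometric mean over replicates, consistent
with the downstream log2 statistics. We deliberately choose the geometric
mean over a ratio of means: the replicate summary then commutes with the
log2 transform used by the moderated test, and a single outlier replicate
cannot dominate.

Two properties of this reconstruction are worth knowing. First, cross-channel
ratios within one experiment are exact: with noiseless input the pipeline
returns them to floating-point accuracy (this is a test). Second, the
*between*-experiment M/L ratio inherits a mild bias for proteins whose
channels are strongly spread by treatment: the reference is an arithmetic
mean over channels while the ratio structure is geometric, so strongly
BFA-shifted proteins carry an arithmetic/geometric-mean mismatch of up to
roughly +0.2 to +0.3 log2 units in their M/L. This is intrinsic to the
summed-reference design, affects control and treated summaries in the same
direction, and does not change any sign-based or rank-based conclusion; the
synthetic benchmarks below quantify it.

# Moderated differential testing

BFA-vs-control changes are tested per protein on three responses: log2
lysate intensity, log2 media intensity, and per-replicate log2 M/L
(`bfa_contrasts()`). The test is the empirical-Bayes moderated t
(`fit_moderated_test()`): per-protein two-group equal-variance fits, a
scaled-F prior for the residual variances whose parameters
(`d0`, `s0^2`) are estimated by matching the mean and spread of
`log(s_g^2)` (trigamma inversion by monotone Newton iteration, tolerance
1e-8), posterior variances `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and t
statistics on `d0 + d_g` degrees of freedom with Benjamini-Hochberg
adjustment across proteins. The implementation is authored here and is
cross-checked in the test suite against the independent limma
implementation, to which it agrees to 1e-10 on shared inputs; the `d0 = 0`
limit reproduces the ordinary two-sample t exactly. We use the plain
equal-variance two-group model with no intensity trend and no robustified
prior: the study design this package addresses has three replicates per
condition and a single factor, where the simplest moderated test is also
the most transparent one. Proteins detected in only one condition are
excluded from a contrast rather than imputed; no imputation scheme is part
of the model.

# Classification rules

With `alpha = 0.05` on the M/L contrast, a protein is **BFA-sensitive**
when its adjusted p-value is below alpha *and* its M/L log2 fold change is
negative; a significant positive shift counts as resistant but is flagged
separately, since a blocked secretory route cannot raise M/L. Labels are
assigned in a fixed precedence (`assign_labels()`), and every both-detected
protein receives exactly one:

* `conventional_secreted`: signal peptide, control M/L > 1, BFA-sensitive;
* `unconventional_candidate`: no signal peptide, no TM domain,
  control M/L > 1, BFA-resistant;
* `post_golgi_tm`: TM domain, control M/L > 1, BFA-resistant;
* `intracellular`: control M/L at or below 1 and nothing above applies;
* `indeterminate`: conflicting evidence (for example a signal-peptide
  protein with high M/L that resists BFA) is surfaced rather than binned.

The candidate screen (`rank_unconventional_candidates()`) ranks
signal-peptide-lacking, both-detected proteins by control M/L and returns
the top 10; TM-bearing members stay in the list but are excluded from the
cytosolic subset, and a BFA-sensitive member is retained with a flag --
these mirror how individual borderline proteins are best handled: visibly,
not silently. All thresholds (M/L > 1 cuts, alpha, top-10) are arguments.

# The synthetic-data generator

`sim_config()` / `simulate_experiment()` define the ground-truth conditions
under which the pipeline is validated. Five trafficking classes are
simulated; per protein with baseline synthesis `A`, export fraction `f`,
leakage `lambda` and BFA block `b`:

```
lysate_ctrl = A(1-f)          media_ctrl = A f + lambda * lysate_ctrl
lysate_bfa  = A(1-f) + A f b  media_bfa  = A f (1-b) + lambda * lysate_bfa   (blocked cargo)
```

BFA-resistant cargo (unconventional class, shed membrane proteins) and
non-exported classes are unchanged by BFA. Intracellular proteins therefore
have true M/L exactly `lambda` -- the leakage background the ratiometric
method is designed to reject.

Default conditions, chosen once as a realistic hepatocyte-like secretome
screen and then frozen:

* 2000 proteins: 12% conventional secreted, 70.75% intracellular, 15%
  membrane, 2% ER/lysosome-lumenal residents (signal-peptide bearing but
  retained, matching the observation that lysate-only proteins are rarely
  SP-positive), and 5 planted unconventional candidates (0.25%), so that
  the top-10 recovery question is well-posed.
* Baseline abundance log-normal (`meanlog 11`, `sdlog 1.2`), spanning about
  three orders of magnitude as deep TMT experiments do.
* Export fractions: conventional cargo uniform on (0.38, 0.98) -- from
  weakly exported SP+ proteins with M/L near 1 up to near-complete export
  with M/L around 50; unconventional cargo uniform on (0.72, 0.80),
  placing candidates at M/L 2.7-4.1, well separated from both the leakage
  background and the shed-membrane band, consistent with candidates being
  efficient but not extreme exporters; 38% of membrane proteins are shed
  (ectodomain released by sheddases from a post-Golgi pool, BFA-resistant)
  with shed fractions on (0.30, 0.63), i.e. M/L roughly 0.5-1.8.
* `leakage_fraction = 0.1` (intracellular M/L of 0.1, in the range observed
  for cytoplasmic markers), `bfa_block = 0.9` (BFA strongly but not
  completely blocks anterograde transport).
* Measurement layer: on average 7 observable peptides per protein, 2
  redundant PSMs per peptide ion, a per-peptide log-normal ionization
  factor (`sdlog 0.9`) shared across channels and runs, multiplicative
  reporter noise at CV 0.2 per channel, precursor purity Beta(8, 2), and
  5% / 2% / 2% decoy / unlabelled / contaminant spectra. Genuine-PSM
  posterior error probabilities follow Beta(1, 300) -- post-rescoring PEPs
  of correct identifications are small -- while decoys are uniform.
* Planted unconventional candidates are drawn from the upper half of the
  abundance distribution (`candidate_abundance_quantile_min = 0.5`):
  candidate discovery in a ratiometric screen is conditional on robust
  quantification in both fractions, so recovery of the planted truth is
  only measurable when the planted proteins are quantifiable; set the
  quantile to 0 for an unrestricted draw.

Three deliberate design choices in the sampling model:

* **Shared peptide inventory.** A protein's peptide count, ionization
  factors and PSM multiplicities are drawn once and shared by the media and
  lysate runs (equal sampling depth); only detection is gated per run.
  Because the absolute-intensity reference is a sum of reporter ions,
  independent per-run peptide sampling would inject order-0.5 log2 noise
  into every M/L ratio through the reference alone -- contradicting the
  premise that summed reporter intensity tracks abundance across the two
  experiments. With the shared inventory, M/L error is dominated by
  reporter noise and by genuinely asymmetric peptide filtering.
* **Detection gated on the control state.** A protein enters a run when its
  control-condition abundance clears `detection_floor` (default 500,
  arbitrary units). Using the control abundance rather than the across-
  condition mean keeps the run composition anchored to the untreated
  steady state; otherwise BFA-driven lysate accumulation would make
  media-only detection of efficiently exported cargo nearly impossible,
  which is not what such experiments show. In practice the binding
  detection limit is usually the lower-5% intensity filter, not the floor.
* **Ionization spread.** The per-peptide ionization factor spans roughly an
  order of magnitude (`sdlog 0.9`). Peptide ionization efficiency genuinely
  varies over orders of magnitude, and this spread is what makes the
  lower-5% intensity filter trim a borderline protein's weakest peptides
  instead of deleting all of its PSMs at once.

What the generator does **not** emulate: chromatography, isotope-impurity
cross-talk between channels, missed cleavages, real peptide masses or
sequences (peptides are abstract identifiers), biological replicate
variation (replicates differ only through measurement noise), co-isolation
interference beyond the purity score, and batch effects between the two
experiments. Passing the simulation benchmarks therefore demonstrates the
correctness and calibration of the pipeline's statistics under its stated
model -- not performance on real instrument data, where normalisation and
interference corrections upstream of this pipeline matter.

# Numerical choices and degenerate inputs

* Percentile for the intensity filter: nearest-rank (inclusive); removal
  uses "at or below the cutoff". Deterministic and exactly testable.
* Purity boundary: strict less-than, so a PSM at exactly 0.50 survives.
* Outlier rule in rollup: Tukey 1.5 IQR fence with a minimum of four
  values; with three or fewer the plain median is used. The fence is a
  deterministic stand-in for the unspecified outlier removal of upstream
  tools.
* FDR estimator: decoys / max(1, targets), optionally +1-corrected; the
  largest qualifying cut is taken, so an isolated early decoy does not
  truncate the list.
* Ties: dedup ties break by spectrum id; razor ties by group id; candidate
  ranking ties by accession. Every stage is re-run stable, and the full
  pipeline is byte-identical across reruns of one seed (tested).
* Degenerate inputs: all-decoy input yields an empty result with a warning;
  a PSM with fewer than two positive channels is excluded from
  quantification and counted; zero residual variance yields t = 0 / p = 1
  for zero fold change; proteins with fewer than two finite values per
  group are excluded from a contrast and counted.
* Problem sizes used in the checks: 2000-protein experiments (20 seeds) for
  trend, recovery and classification benchmarks; 500-protein experiments
  for the quantification-fidelity checks; 100 simulations for FDR
  calibration and 100-200 global-null fits (2000 proteins, n = 3 per group)
  for test calibration.

# Known limitations

* The M/L reference-reconstruction bias described above (+0.2-0.3 log2 for
  strongly treatment-shifted proteins) is inherited from the summed-
  reference design; rank- and sign-based conclusions are unaffected.
* No between-channel normalisation is applied by default, because none is
  part of the described workflow; unequal protein loading between the media
  and lysate experiments therefore shifts all M/L ratios by a common
  factor, and the M/L > 1 thresholds should be read with that in mind.
* Proteins with similar intra- and extracellular pools (M/L near 1) are not
  separable by this statistic, and proteins absent from one fraction never
  receive a ratio; both sets are reported with explicit detection status
  rather than imputed.
* The moderated test assumes equal variances between the two conditions and
  log-normal measurement error; with three replicates per group there is
  little power to check either per protein, which is precisely why variance
  moderation is used.
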