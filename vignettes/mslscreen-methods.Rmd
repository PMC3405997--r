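---
title: "Methods: dual-luciferase screen statistics and MRE occupancy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-luciferase screen statistics and MRE occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslscreen)
library(dplyr)
```

# Scope

`mslscreen` implements the computational side of a cell-based genome-wide
RNAi screen for regulators of MSL (Male-Specific Lethal) complex targeting
in *Drosophila*, plus the chromatin-occupancy analyses used to follow up
candidate factors. It covers five stages:

1. **Synthetic data** — simulators for screening plates and a toy genome,
   so every downstream stage is testable without the original raw data.
2. **Plate screen** — Firefly/Renilla ratio normalisation, plate QC by
   control dynamic range, duplicate-concordant hit calling, and a Renilla
   viability filter.
3. **Candidate triage** — ribosomal-gene removal, exact k-mer dsRNA
   off-target prediction, ambiguous-amplicon removal, multi-reporter
   validation, and functional classification into classes 1–6.
4. **ChIP enrichment** — qPCR-style normalisation (input, control locus,
   histone H3) and binned log2(IP/input) coverage tracks.
5. **Motif occupancy** — PWM scanning for MREs (MSL recognition elements),
   five-way site classes, peak–MRE occupancy fractions, and sites × bins
   enrichment matrices for heatmaps and average profiles.

Read alignment and peak calling are deliberately out of scope: the package
consumes aligned read positions and peak intervals (BED), as produced by
standard aligners and peak callers.

# The screening statistic

Each well holds one dsRNA amplicon; the readout is a pair of luciferase
activities. The MSL-dependent Firefly reporter responds to the perturbation
of interest, while a constitutive Renilla reporter tracks transfection
efficiency and cell number, so the per-well statistic is the ratio
$r = F/R$. Per plate and replicate:

* the **plate centre** is the median ratio over *sample* wells,
* the **plate scale** is the sample standard deviation of those ratios,
* the **dynamic range** is the mean negative-control ratio divided by the
  mean positive-control ratio; a plate passes QC at $\ge 5$-fold.

An amplicon is a **hit** when its deviation
$d = (r - \mathrm{median}) / \mathrm{SD}$ is strictly greater than 2 in
magnitude on *both* replicate plates, with matching sign, and the well
passes the viability filter: wells whose Renilla value is more than 3-fold
below the plate's sample-well Renilla median on either replicate are
excluded, since reporter loss there reflects cell death or failed
transfection rather than specific regulation.

Design choices where the procedure was genuinely open:

* **Sample wells only** enter the median/SD. Controls are by design extreme
  (10-fold Firefly suppression in the positive control) and would inflate
  the plate scale, costing sensitivity. Both statistics are invariant to
  rescaling all Firefly values on a plate, which the tests verify.
* **Ordinary (n−1) standard deviation**, not MAD, is the default scale —
  the procedure is defined in terms of the standard deviation — but
  `robust_sd = TRUE` switches to the normal-consistent MAD for long-tailed
  plates. With MAD, a plate whose scale collapses to zero while wells
  deviate raises a named `degenerate_plate_sd` error rather than dividing
  by zero.
* **Matching sign across replicates** is required by default
  (`require_matching_sign`): a gene cannot plausibly be both activator and
  repressor of the same reporter. The sign-agnostic variant is available
  because the choice is not forced by the statistic itself.
* **Strict inequality** at the threshold ("more than two standard
  deviations").
* The **Renilla reference** for the viability filter is the median of
  sample-well Renilla values on that plate, the natural plate-level centre
  for a well-level quantity.
* Wells with non-positive Renilla are flagged (`renilla_nonpositive`),
  excluded from all plate statistics, and can never be hits; they are
  never silently dropped.

# The plate simulator

`simulate_screen()` draws both reporters from a multiplicative log-normal
model: luminescence is positive and right-skewed, and most technical
effects (transfection efficiency, reagent batches) act multiplicatively.
For well $w$ on plate $p$, replicate $t$:

$$F_{w} = R_0\,\beta\,e_w\,u_w\,s^{F}_{pt}\,\varepsilon^F_{w},\qquad
  R_{w} = R_0\,u_w\,s^{R}_{pt}\,\varepsilon^R_{w},$$

with baseline Renilla $R_0$ (default $10^4$ RLU), baseline ratio $\beta$
(default 3, arbitrary units — the published design does not state the RLU
scale, so the default is documented rather than fitted), amplicon effect
$e_w$ (spiked hits; 0.1 for positive controls), a shared lethality factor
$u_w$, per-plate per-reporter scale factors $s_{pt}$ (log-SD
`plate_scale_sd`, default 0.1 — applied independently to the two reporters
so the baseline ratio genuinely drifts between plates), and i.i.d.
log-normal noise with coefficient of variation `noise_cv` (default 0.15, a
typical well-to-well CV for 384-well luminescence assays).

**Lethality** scales *both* reporters by a single factor drawn uniformly
in (0.01, 1/3): cell death removes cells, and with them both luciferases,
which is exactly the failure mode the Renilla filter exists to catch. The
ratio of a lethal well is therefore unremarkable while its Renilla falls
more than 3-fold below the plate centre. Lethal wells are lethal in both
replicates (the reagent, not the measurement, kills the cells) and are
sampled among non-spiked sample wells so ground truth stays interpretable.

**Controls** occupy fixed wells (first positions of the first row,
positive; last positions of the last row, negative): the published design
does not state positions, and a deterministic layout makes fixtures and
round-trips exact.

# The toy genome simulator

`simulate_genome()` builds a miniature genome with an X chromosome and an
autosome; plants non-overlapping 21-bp MREs uniformly at random; designates
a random subset of X MREs as chromatin entry sites (CES, the MRE padded
±100 bp); plants peaks over MREs with class-dependent probabilities
(`p_peak_given_ces`, default 0.985, matching the observed fraction of CES
with a binding site; background defaults 0.35/0.32 for X/autosome,
matching the observed genome-wide occupancy fractions); and emits IP reads
whose density is elevated `peak_read_enrichment`-fold (default 8) inside
peaks over a uniform background, plus uniform input reads.

Motif scores are drawn independently of CES status — deliberately so,
because the motif sequence alone does not predict which MREs are utilised
in vivo, and analyses downstream must not be able to cheat by reading the
score.

What the simulator does *not* emulate: sequencing error, fragment-length
effects, mappability, chromatin accessibility structure, or realistic
sequence composition. Passing tests therefore demonstrate correctness of
the statistics and bookkeeping under the declared generative model, not
robustness to every artefact of real ChIP-seq data.

# Candidate triage

Off-target prediction follows the exact-overlap convention for arrayed
dsRNA libraries: a gene is a predicted off-target when its transcript
shares at least one exact 17-mer with the dsRNA or its reverse complement
(k-mer set intersection; no mismatches). The off-target set is monotone
non-increasing in k, which the tests check. The published cascade removed
genes with "a large number" of off-targets without stating the cutoff;
`max_off_targets` (default 1 — any predicted off-target disqualifies the
amplicon) makes the threshold explicit and configurable.

Filter precedence is fixed (`ambiguous_amplicon` > `ribosomal` >
`off_target`) so each removed candidate carries one reproducible primary
reason. Validation requires ≥2 distinct hit amplicons per gene and a hit
with consistent direction in all three reporter configurations; the
additional construct is required to be a formal hit in some reporter (not
merely concordant), the stricter and better-defined reading. Classification
maps direction × annotation to classes 1–6; RNA-metabolism genes go to
class 5 regardless of direction (the category is defined by function, not
direction), core MSL subunits are set aside, and a gene annotated both as
general-transcription and DNA-binding resolves toward the DNA-binding
class with a warning.

# ChIP enrichment and occupancy

* **qPCR enrichment** is (IP/input) at the target divided by (IP/input) at
  a non-transcribed control locus; H4K16ac is further divided by the H3
  fold enrichment to express acetylation per nucleosome.
* **Tracks**: reads are counted by 5′ position into half-open bins
  `[ib, (i+1)b)` (default b = 200 bp, the resolution used for the
  heatmaps); the final partial bin is kept. Per bin the value is
  `log2(((ip+p)/N_ip) / ((in+p)/N_in))` with pseudocount p = 1 added
  *before* library scaling, which keeps every bin finite; p = 0 recovers
  exact library-size invariance at the cost of infinities in empty bins.
  Read extension/shifting (fragment-model estimation) is intentionally not
  performed; this is a documented limitation, not an omission.
* **Occupancy** uses the BED convention throughout (0-based, half-open)
  and counts an MRE as occupied when it overlaps a peak by ≥1 bp;
  `max_gap` optionally relaxes this to proximity. Percentages are
  reported on the 0–100 scale rounded to one decimal.
* **Site classes**: "best" classes are the top-n non-CES MREs by PWM
  log-odds with ties broken by ascending coordinate (determinism); random
  classes are seeded uniform draws without replacement; both exclude
  CES-overlapping MREs only (not all bound MREs — a flag-level choice the
  data formats leave open, resolved toward the simpler set definition).
* **Matrices**: 50 bins of 200 bp across ±5 kb around the MRE midpoint
  `floor((start+end)/2)`; each cell is the length-weighted mean of the
  step-function track over the output bin, so output bins need not align
  with the track grid. Bins extending past a chromosome end — or sites on
  chromosomes absent from the track — are missing (`NA`), never zero, and
  are excluded from column averages. Profiles are not strand-flipped: MREs
  are treated as unoriented, matching the symmetric ±5 kb presentation.
* **PWM scanning** reports every window on either strand with log2-odds
  score ≥ threshold against a uniform background (configurable);
  N-containing windows are skipped. A toy GA-rich PWM (`mre_pwm()`) is
  provided for simulation; real analyses should supply the published
  motif via `read_pwm()`.

# Verification strategy and problem sizes

Every statistic has an independent brute-force oracle in the test suite:
hit calls are re-derived from first principles on small plates, off-target
sets by all-substring comparison, occupancy by exhaustive pairwise overlap,
matrix summaries by explicit column loops, and motif scans by scoring every
window. Property-style tests cover plate-scale invariance, viability-filter
order independence, k-monotonicity, IP/input antisymmetry, read-count
conservation, class-set disjointness, and seed determinism (byte-identical
emitted files).

Simulation-based checks run at desk scale, chosen to keep the suite fast
while leaving comfortable statistical margins: 10 plate-pairs × 384 wells
with 15 spiked effects over 20 seeds for recovery; 15 seeds of 10 null
plate-pairs against the analytic two-replicate tail bound
$(2\Phi(-2))^2$; 50 toy genomes for the CES-coverage expectation
(0.985 × 137 ≈ 135); and 20 genomes for the class-level enrichment
ordering (CES ≫ background). `scripts/acceptance.R` recomputes the
headline quantities from scratch at the same scales.

# Known limitations

* The plate model has no spatial (edge/row) effects and hence no B-score or
  loess correction — matching the published per-plate analysis, but real
  plates may need one.
* Off-target prediction is exact-match only; near-matches with one
  mismatch are not considered.
* Tracks treat reads as single 5′ positions; no duplicate marking or
  fragment-size modelling.
* The published screen's full candidate tables are not redistributed here;
  the triage stage operates on user-supplied hit tables and annotations.
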