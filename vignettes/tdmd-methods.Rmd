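---
title: "Methods: screening and quantifying target-directed miRNA degradation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and quantifying target-directed miRNA degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdmdtools)
```

## The problem

Most miRNA:target encounters silence the target. In target-directed miRNA
degradation (TDMD) the logic inverts: a target carrying, besides the seed
match, extensive complementarity to the miRNA's 3' region triggers
degradation of the miRNA itself, typically accompanied by 3' tailing
(non-templated adenylation/uridylation) and trimming of the miRNA. The
canonical endogenous example is the Serpine1 transcript in mouse
fibroblasts, which directs degradation of miR-30b-5p and miR-30c-5p during
serum-stimulated cell-cycle re-entry. `tdmdtools` implements the
computational workflow around that biology: screening candidate TDMD
targets, characterising duplex anatomy, profiling isomiRs, quantifying
stoichiometry, and measuring downstream miRNA activity.

## Duplex anatomy

A miRNA:MRE duplex is decomposed into a seed helix and a 3' supplementary
helix separated by a central loop. Conventions:

* sequences 5'→3' on both strands, duplex antiparallel; the seed helix is
  anchored at the site's 3' end, pairing miRNA positions 2–8 (2–7 for the
  weaker classes). Target position 1 sits opposite miRNA position 1 and is
  never paired; the A1 rule asks for an adenosine there regardless of the
  miRNA's first base.
* seed classes follow the canonical hierarchy 8mer > 7mer-m8 > 7mer-A1 >
  6mer, and a site reports only the highest matching class.
* the supplementary helix is the placement maximising *contiguous*
  Watson–Crick pairs between the remaining target 5' segment and the miRNA
  3' region. Ties go to the longer helix, then the smaller target-strand
  bulge, then the placement closest to the seed. G:U wobbles are excluded
  by default (`allow_wobble = FALSE`): strict pairing is the auditable
  rule, and the package reports 10 contiguous pairs for miR-30c-5p against
  the Serpine1 element where figure annotations that admit a wobble count
  11. Both counts are available; the default is the strict one.

The brute-force check — enumerating every seed-anchored two-helix
decomposition — lives in the test suite as an independent oracle and is run
against the aligner on 1,000 random pairs.

One caution discovered while testing: the intuitive claim "breaking a
paired 3' base can only shorten the supplementary helix" is false. The
substituted base can pair in a shifted register and the globally optimal
helix can lengthen by a base or two. The suite therefore asserts the
placement-local form (the run through the original placement must shrink)
and re-checks the mutant against the oracle.

### TDMD eligibility

A duplex is eligible when it has a high-affinity seed (8mer or 7mer-m8),
at least `min_3p = 8` nt of contiguous supplementary pairing, and a
target-strand central bulge inside `bulge_range`. Two presets ship:

* `default`, bulge 1–7 nt — reconstitution experiments show degradation
  persists, modestly reduced, with a bulge widened to seven nucleotides,
  while four 3'-end mismatches abolish it;
* `strict`, bulge 3–4 nt — the narrower "greater than 2, smaller than 5"
  window used when describing ideal candidates.

A perfectly complementary site (bulge 0) is deliberately *not* eligible
under either preset: perfect complements route to slicing/sponging rather
than the bulged TDMD geometry, which is also why the 4-repeat sensor is a
reporter of activity, not a decay trigger.

## The candidate screen

3'-complementarity (3C) scores are consumed from TargetScan-style tables,
never recomputed. Classes: LOW (−0.03, −0.01], MID (−0.05, −0.03], HIGH
≤ −0.05; boundaries are assigned to the more-negative class (the sources
do not state inclusivity; a fixed choice keeps the partition exhaustive).
Expression context: a gene counts as expressed at ≥ 1 RPKM in at least one
condition; a miRNA at > 10 CPM (strict). Candidates are ranked by class,
then by the maximum share the target takes of the miRNA's 3C pool
(RPKM of the target over the summed RPKM of all pool members, per
condition), then by the maximum log2 fold-change against the reference
condition. The fold-change pseudocount is 0.1 RPKM, bounding fold-changes
for transcripts absent at the reference; the reference is the first
column (the quiescent 0 h state) and is configurable, since "maximum
change" could also be read against the row minimum.

```{r screen}
sim <- gen_serum_timecourse(serum_scenario(), seed = 1)
ranked <- tdmd_screen(sim$targets, sim$gene_expr, sim$mirna_expr,
                      class_floor = "HIGH")
head(ranked, 3)
```

## isomiR profiling

Reads are assigned to references by exact prefix over a trim window, then
classified as CANONICAL, TRIM (3' shortening ≤ `max_trim`), TEMPLATED_3P
(extension matching the downstream genomic sequence), NT_A / NT_U /
NT_MIXED (non-templated tails after stripping the longest templated
prefix), or OTHER. Windows default to `max_trim = max_tail = 4` nt — the
customary workflow defaults, flagged as assumptions since the original
tool's exact windows are not restated in the sources this package follows.
Stripping the templated prefix first makes 3'NT calls conservative: a
genome that happens to continue in A can never inflate the adenylation
signal. 5' isomiRs are out of scope and fall into OTHER.

Within a miRNA family, trim-window prefixes nest (the canonical
miR-30c-5p read begins with miR-30b-5p's prefix), so prefix hits are
disambiguated by explainability: a candidate reference keeps a read only
if the read classifies as something other than OTHER under it; reads
explainable under several references are set aside as ambiguous.

Normalisation is reads-per-million against the library size, with an
optional externally supplied per-condition amplification factor (for
global RNA amplification after serum stimulation; the package applies the
factor, it does not estimate it).

## Stoichiometry

Standard curves are ordinary least squares of Cq on log10(copies) — the
titration figure gives no fitting detail, and OLS in log space is the
standard choice — with efficiency `10^(-1/slope) - 1`. Copies per cell
invert the curve and divide by cell equivalents per reaction;
extrapolation outside the calibrated range is flagged, not refused. The
target-per-miRNA (TPM) ratio divides the two copy numbers; a pooled
denominator (summing a family subset) is supported because the published
"TPM ≈ 1 in growing cells" is only consistent with a pooled or
higher-expressed-member denominator. Half-life arithmetic assumes pure
exponential loss with negligible synthesis: `t½ = -elapsed / log2FC`,
so the two serum log2 fold-changes (−0.88, −1.13 at 4 h) average to a
half-life of ~4 h.

## Activity statistics

Target-set shifts are median log2 fold-change differences (set minus
non-targets) with raw two-sided Wilcoxon rank-sum p-values — no multiple
testing correction, matching how such panels are reported; apply
`p.adjust` across sets if needed. Per-miRNA summaries require at least 50
expressed targets. Differential miRNA expression uses Welch's t-test on
log2(CPM + 1). The serum DEG filter demands |log2 FC| > 1 in *both*
mutant clones at a shared time point with concordant sign — concordance is
this package's choice (the source is silent), because opposite-signed
calls in the two clones are contradictory evidence, not replication.
Cluster enrichment is a per-cluster 2×2 Pearson chi-square without
continuity correction.

The flow-cytometry sensor estimator log-transforms both channels, sorts
each population by the co-reporter (dNGFR), splits it into 100
equal-count bins, and compares per-bin mean log sensor (dGFP) levels at
matched bin rank; the fold is oriented control/sensor so repression gives
folds above 1 (the bracketed published formula is ambiguous in
orientation). The summary is the arithmetic mean over bins rather than a
pooled-cell ratio — binning is what controls for co-reporter level, and
averaging bins weights each expression stratum equally. The estimator is
invariant to monotone rescaling of dNGFR and multiplicative rescaling of
dGFP applied to both populations.

## Synthetic data: what it emulates, and what it does not

Every generator is seed-reproducible bit for bit and returns its planted
truth. The serum scenario plants one transcript induced with a maximum
log2 fold-change of 6.92 peaking above 1000 RPKM at 2 h over a log-normal
background, dominating (> 90%) the HIGH 3C pool of its two miRNAs; the
defaults are the study conditions, not tuning knobs. Flow events are
bivariate log-normal with multiplicative noise of 0.3 natural-log units.
Read simulation uses synthetic downstream contexts chosen to start with
G/C so that templated extensions are distinguishable from A/U tails — a
property real loci do not guarantee, which is one of several ways the
synthetic data are cleaner than real libraries (no sequencing error, no
cross-mapping, no 5' heterogeneity, no composition bias). Passing tests
on these fixtures therefore demonstrates correctness of the arithmetic
and classification logic, not robustness to real-data artefacts.

### Kinetics model

The simulator integrates

$$\frac{dM}{dt} = \sigma - \Big(\delta_0 + \delta_T\,\frac{T(t)}{T(t)+K}\Big) M$$

with fixed-step fourth-order Runge–Kutta (`deSolve::ode`, `method =
"rk4"`, `dt ≤ 0.1 h`). The saturable (Michaelis–Menten in target
abundance) TDMD term is a modelling choice of this package — no kinetic
law is given in the sources — chosen because a single form then covers
both the steady-state effect at TPM ≈ 1 and the acute effect at TPM > 10;
setting `K` far below the target range recovers the mass-action-saturated
limit. The `serum` preset uses a basal half-life of 14 h, steady state
100 cpc, and a target pulse from 88 cpc to > 4000 cpc peaking at 2 h;
`deltaT` is calibrated once (by root-finding at preset construction) so
the miRNA halves over the first 4 h of the pulse, synthesis included,
because the published "~4 h half-life" is the net observed halving time
derived from the 4-h log2 fold-changes. The `steady` preset instead sets
target-directed decay equal to basal decay at 170 cpc, so removing the
TDMD term doubles the steady-state level.

```{r kinetics}
p <- tdmd_params("serum")
tr <- simulate_tdmd_kinetics(p, dt = 0.05, t_end = 12)
log2(tr$M[tr$time == 4] / p$M0)
```

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere (CRISPR cuts, scanned
  sites); a cut is the coordinate of the bond, so excised plus retained
  lengths always reconstruct the input.
* Site scanning resolves overlaps on the 8-nt seed window, keeping the
  higher class (5'-most on ties), so adjacent perfect repeats are all
  reported.
* A duplex with no supplementary pairing reports `NA` bulges (the loop is
  undefined without a second helix) and fails eligibility on the pairing
  criterion.
* Zero-sum 3C pools, empty read groups, zero-expected contingency cells
  and out-of-range Cq values are flagged (warning/`NA`) rather than
  silently dropped; empty FASTA/FASTQ files parse to empty tables.
* Guides matching a sequence more than once are a hard error in deletion
  arithmetic: the deletion screen presumes unique sites.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: 1,000
random duplexes against the brute-force oracle, 10⁴–10⁵ simulated reads,
200,000 flow events per population, 1,000 null resamplings for the
type-I-error checks, and a few hundred genes per synthetic time course.
Genome-scale figures that depend on the full deposited sequencing data
and complete prediction downloads (tens of thousands of pairs, thousands
of DEGs) are outside what these fixtures reproduce; the property-based
checks above stand in for them.

## Known limitations

* The duplex model scores contiguous Watson–Crick runs, not folding free
  energy; wobble handling is a flag, not a thermodynamic model.
* TargetScan 3C scores are inputs; the package neither recomputes them
  nor checks their provenance.
* The isomiR classifier handles 3' events only, and mixed trim-plus-tail
  reads fall into OTHER rather than a combined class.
* Amplification-correction factors and time-course cluster labels are
  consumed, not estimated.
* The kinetics model is deterministic and single-compartment: no AGO
  loading, no bursting, no cell division dilution.
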