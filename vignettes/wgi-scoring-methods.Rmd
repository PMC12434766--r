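---
title: "Copy-number based genomic instability scoring from shallow WGS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number based genomic instability scoring from shallow WGS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgiscore)
```

## The problem

Homologous recombination deficiency (HRD) predicts benefit from PARP
inhibitors in ovarian cancer, but allelic scar markers (LOH, TAI, LST)
need deep sequencing that is often unaffordable and unreliable on degraded
FFPE material. An alternative is to read genomic instability directly from
the copy-number profile of shallow whole-genome sequencing (sWGS, 1–2X):
an HRD genome accumulates many large intra-chromosomal copy-number breaks,
which survive binning at very coarse resolution. `wgiscore` implements
this approach end to end: read counting into fixed windows, GC
normalisation, segmentation with a noise- and tumour-fraction-adaptive
event cutoff, large-scale genomic alteration (LGA) counting, the
whole-genome instability (wGI) score, a simplified tumour-fraction
estimator, in-silico dilution, BRCA1/2 variant-status filtering, and the
combined HRD call with its QC gates and concordance statistics.

## The measurement model

Reads are counted into fixed windows of 500 kb confined to chromosome
arms. The large window is deliberate: FFPE degradation produces short-range
artefact waves that average out at 500 kb but dominate 50 kb bins. For a
clonal tumour of fraction $t$ and ploidy $\psi$ in a diploid background,
a segment at integer copy number $n$ has expected log2 ratio

$$E(n; t, \psi) = \log_2\frac{t\,n + 2(1-t)}{t\,\psi + 2(1-t)},$$

so neutral segments sit at 0 and a single-copy gain moves the ratio by
about $\log_2(1 + t/2)$ — the fundamental reason low tumour fraction
erodes sensitivity.

GC correction groups usable bins into GC deciles and rescales each count
by the ratio of the genome-wide median to its decile median. A decile
correction was chosen over LOESS because it is deterministic, has no
tuning parameter that interacts with segment structure, and is exactly
invertible in tests. Bins with mappability below 0.75, missing GC, or
zero counts carry no ratio. Ratios are centred on the median corrected
count, so the genome median is 0 by construction.

## Noise index

DNA quality is summarised by the noise index: for every segment, the
median absolute deviation (MAD, unscaled) of its bins' ratios about the
segment median; the index is the median of these per-segment MADs, and
their standard deviation is reported alongside. Because deviations are
taken within segments, real copy-number structure does not inflate it.
For Gaussian ratio noise the index is $0.6745\,\sigma$; the packaged
calibration check uses $\sigma = 0.148 \Rightarrow 0.100$. An index above
0.10 flags the sample as at risk (orthogonal assays tend to fail such
samples) without failing it outright. The index is computed on the
first-pass segmentation, before any merging, so later smoothing cannot
hide noise. A `aggregate = "bin"` switch pools deviations across all bins
instead of taking the median across segments; the segment-median form is
the default because it is robust to a few outlier segments.

## Segmentation

Per arm, the bin ratio sequence is partitioned by exact penalized optimal
partitioning: minimise total within-segment sum of squares plus
$\lambda\hat\sigma^2$ per changepoint, minimum segment size 3 bins, with
$\hat\sigma$ estimated from median absolute successive differences
(robust to true level shifts). The search is a dynamic program, so the
result provably attains the optimum over *all* partitions — the package's
tests verify this against an exhaustive enumeration on short arms. A
greedy recursive binary splitter was considered and rejected: it applies
the same acceptance rule (split only if the cost falls by more than
$\lambda\hat\sigma^2$) but cannot guarantee optimality, which would have
made the oracle-equivalence property of the tests unprovable. $\lambda =
10$ (roughly $2\log n$ for arm-scale $n$) keeps pure-noise splits rare
while a 0.6-ratio step over five or more bins is always found. Ties
resolve to fewer changepoints; the algorithm is fully deterministic.

## The minimal CNA cutoff and merging

Which boundaries count as events depends on the sample. Two effects set
the scale: noise (random fluctuation must not be called an event) and
tumour fraction (a real single-copy event is only $\log_2(1+t/2)$ deep).
The cutoff is

$$\mathrm{cutoff} = \max\!\big(k_{\mathrm{noise}} \cdot \mathrm{noise\ index},\;
k_{\mathrm{tf}} \cdot \log_2(1 + t/2)\big)$$

with $k_{\mathrm{noise}} = 2.5$ and $k_{\mathrm{tf}} = 0.5$: two and a
half times the within-segment MAD, or half the single-copy signal,
whichever is larger. When the cutoff reaches the full single-copy signal
the sample is flagged "single-copy events may be unresolvable". The
functional form is this package's own calibration decision; it is
validated by parameter-recovery and oracle-agreement simulations rather
than by comparison with any external implementation.

Merging then iterates per arm to a fixpoint: segments shorter than 3 Mb
(the same scale as the LGA gap tolerance) are absorbed into the
neighbour with the closer mean (ties left, shortest first); adjacent
pairs closer than the cutoff are merged smallest-difference-first, which
makes the fixpoint independent of scan order. After merging, every
surviving intra-arm boundary is an event at the cutoff scale.

Because the cutoff needs a tumour fraction and the tumour fraction needs
segments, the driver `run_wgi()` is two-pass: a provisional merge under a
noise-only cutoff feeds a provisional TF estimate, which fixes the final
cutoff; the reported TF is re-estimated on the final merged profile.

## LGA calling and the wGI score

An LGA is an intra-arm break between adjacent segments that are each
strictly longer than 10 Mb, separated by strictly less than 3 Mb, with a
mean-ratio contrast at or above the cutoff. Both strictness choices
follow the assay definition word for word ("more than 10 Mb", "less than
3 Mb"). Bins never straddle the centromere, so cross-centromere breaks
are structurally impossible rather than filtered.

The wGI score is the LGA count minus a baseline of 20, with 0 as the
positivity cutoff; a score of exactly 0 is called positive (the
borderline-positive convention used for reporting), and a strict
comparator is available in the configuration. The baseline is
configurable; 20 matches the positivity threshold the LGA-counting
literature converged on for ovarian cancer.

## Tumour fraction by grid search

The estimator does a grid search over $t \in \{0.05,\dots,1.00\}$ (step
0.01) and $\psi \in \{1.6,\dots,4.0\}$ (step 0.1), assigning each segment
the integer copy number in 0–8 whose expected ratio is nearest its mean,
and scoring the length-weighted squared residual. Three safeguards handle
the classic purity–ploidy degeneracy, in which a genome-doubled
reinterpretation (all states doubled at halved fraction, or shifted at
raised ploidy) reproduces the same segment means exactly:

* assigning copy 0 to a segment longer than 3 Mb incurs a large penalty —
  multi-megabase homozygous deletions are not biologically viable;
* a weak prior `state_penalty * (n - psi)^2` (default 0.001) disfavours
  the scaled branches, whose denser level lattices would otherwise
  out-fit the parsimonious solution on noise alone;
* among candidates within 5% of the minimal cost, the ploidy nearest 2 is
  preferred, then the cost-minimising $t$ in that class (exact ties to
  the smaller $t$).

A fit in which every segment is assigned the neutral state carries no
information about $t$; it is reported at the grid floor with
`floor_flag = TRUE` rather than as a confident estimate. The estimator is
validated purely by parameter recovery on simulations (|error| ≤ 0.05
across $t$ from 0.2 to 0.8); it is a deliberately simplified clonal fit,
not a reimplementation of an HMM-based tool, and samples dominated by
subclonal events are outside its model.

## In-silico dilution

Dilution emulates mixing tumour reads with white-blood-cell reads at bin
resolution: with $\alpha = \mathrm{target}/\mathrm{tumor}$ TF, each mixed
count is $\mathrm{Bin}(c^{tum}_i, \alpha) + \mathrm{Bin}(c^{nrm}_i,
1-\alpha)$, which matches read-level subsampling in distribution at bin
resolution, conserves expected depth, and is deterministic per seed.
`dilution_series()` reruns the whole pipeline at each level and reports
the stability floor — the lowest tumour fraction down to which the wGI
status matches the undiluted call.

Two frozen reference designs (`instability_reference_spec()`) probe this:
a clearly unstable genome (48 breaks, score +28, ordinary FFPE
dispersion) and a borderline genome (exactly 20 breaks, score 0, heavy
dispersion, six of its breaks at weak 4-to-5 contrast). In simulation the
robust design keeps its positive status down to 20% tumour fraction,
while the borderline design holds only to 30% and flips at 20% — the
behaviour that motivates a 30% tumour-fraction floor for reporting:
below it a borderline result may no longer be trustworthy, so reports
carry a reliability warning (not a no-call). This pattern is also a
structural property of the cutoff formula: for clonal integer-copy
events, the tumour-fraction term of the cutoff shrinks faster with $t$
than any single-copy contrast, and count mixing with a clean normal
scales artefact noise down with the signal, so events detectable with a
comfortable margin undiluted remain detectable down to roughly 20%;
only genuinely borderline genomes sit close enough to the boundary to
flip earlier.

## BRCA status, HRD call and statistics

Variant records arrive pre-annotated (VAF, population frequency, clinical
classification); classification itself is upstream of this package. Two
exclusion filters act independently by default: VAF < 5%, or population
frequency > 0.1%. The sentence defining these filters is grammatically
ambiguous between an OR and an AND of the two conditions; the disjunctive
reading is the clinically standard one (each filter is an independent
reason to distrust a call) and the conjunctive reading is available via
`exclusion = "both"`. A sample is BRCA-positive if any retained BRCA1/2
variant is deleterious or suspected deleterious.

The HRD call is a truth table: any failed QC gate (targeted: mean depth
> 40X and ≥ 90% of positions at 40X; sWGS: mean depth > 1X and ≥ 40% at
1X, all comparisons exactly as worded) gives `no_call`; otherwise the
sample is HRD-positive when either BRCA status or wGI status is positive.
`no_call` samples are excluded from prevalence denominators. Agreement
between assays is reported as PPA/NPA/OPA with one-decimal, half-up
rounding; marginals with empty denominators are reported absent, never 0.

## The synthetic-data generator

`simulate_profile()` draws negative-binomial counts around
$\mu_i = D\, g(\mathrm{gc}_i)\, (t n_i + 2(1-t))/(t\psi + 2(1-t))$, with
$D$ = 7500 reads per 500 kb bin (about 1.5X at 100 bp reads, the assay's
stated sWGS depth), variance inflation 1.5 by default (FFPE libraries are
overdispersed relative to Poisson; the borderline reference design uses
36 to emulate heavily degraded DNA), and a smooth unimodal GC-bias curve
$g$ peaked at GC 0.45 with amplitude 0.3. The GC track is a deterministic
smooth function of genomic position: GC belongs to the bin, not the
sample, and sharing it between tumour and normal profiles is what makes
in-silico mixing coherent. `random_truth_spec()` draws clonal genomes
whose segment lengths avoid the 10 Mb decision boundary (so breakpoint
jitter of a bin cannot flip an LGA's qualification) and whose copy states
follow a return-to-diploid walk over {1, 2, 3}, keeping the genome median
diploid.

What the generator does *not* emulate: subclonal copy states, real
mappability structure and blacklisted regions, chimeric/duplicate read
artefacts, and FFPE deamination variants. Passing tests therefore show
the algorithmic chain is correct under its stated model — they do not by
themselves validate performance on clinical FFPE libraries.

Problem sizes used throughout the packaged tests and the acceptance
script: 6-chromosome genomes of 110 Mb (1320 bins) for oracle-agreement
and recovery studies, 12-chromosome genomes (2640 bins) for dilution
studies, 100 replicates for oracle agreement, 70 for TF recovery, 10
seeds per dilution arm — chosen so the full suite exercises every claim
at meaningful replication while remaining quick to run on a laptop.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; trailing partial bins
  shorter than half a window are dropped, longer ones kept truncated.
* Arms with fewer than 6 usable bins are returned as a single flagged
  segment; profiles with fewer than 50 usable bins are an error.
* A GC decile with zero median count marks its bins unusable with a
  warning rather than producing infinite ratios.
* Merging ties (equidistant neighbours) absorb to the left; segmentation
  ties resolve to fewer changepoints; all randomness in the simulator
  flows from a single per-spec seed and never touches global RNG state.
* Sex chromosomes are excluded from scoring by default (copy-number
  baseline on X/Y is ambiguous without matched sex information);
  `autosomes_only = FALSE` keeps them.

## A worked example

```{r example, eval = FALSE}
layout <- toy_genome(6, 55e6)
spec <- random_truth_spec(layout, tumor_fraction = 0.6, seed = 42)
sim <- simulate_profile(spec)
frag <- run_wgi(sim$profile, layout)
frag
#> wgi_fragment 'sim_seed42': 19 LGAs, score -1 (negative), TF 0.60,
#> noise 0.033, cutoff 0.189
sim$truth$true_lga_count
#> [1] 19
```

## Known limitations

The tumour-fraction estimator assumes one clonal population; heavily
subclonal genomes or very high ploidies near the grid edge will fit
poorly (the `fit_cost` and `floor_flag` fields expose this). The wGI
baseline of 20 is a configuration default, not a clinically re-validated
threshold for any particular cohort. The QC surrogate derived from bin
counts (`run_wgi()` without explicit depth statistics) approximates
coverage at bin resolution and should be replaced by true per-base depth
statistics when BAMs are available. Concordance statistics treat the
reference assay as ground truth, as percent-agreement measures do by
construction.
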