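---
title: "Models and methods behind k36land"
author: "k36land authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind k36land}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models, the synthetic-data generator
and the numerical choices in `k36land`, in the spirit of how a pipeline
package documents what its numbers mean and where its defaults come from.

## The measurement problem

ChIP-seq of histone H3K36 methylation states across methyltransferase (HMT)
depletions asks an absolute question — did the amount of a mark at a locus go
up or down? — with a relative instrument. Library depth is arbitrary, and an
RNAi that removes half of a genome-wide mark also halves the immunoprecipitated
material, so within-library normalization hides exactly the effect of
interest. The remedy is an exogenous spike-in added at a fixed proportion of
cell numbers before chromatin preparation: spike-genome reads track the
per-cell IP yield, so dividing by them calibrates all libraries onto a common
absolute scale.

`k36land` implements this calibration and everything downstream of it:
domain-level maps of the three K36 methylation states, window-level
differential analysis between depletion conditions, a gene-centric clustering
of methylation signatures, and two biophysically motivated models — a
saturating dual-mark model of chromatin-reader retention and the Hill
binding-curve model used for nucleosome titrations.

## Spike-in calibration

Two modes are provided, mirroring the two standard practices:

* **Total-read mode** (`spikeScaleTotalReads`): `factor_j = 10^6 /
  spike_reads_j`. Simple, robust, and exact when the spike-in share of each
  library faithfully reflects IP efficiency.
* **Trimmed-M mode** (`spikeScaleTMM`): TMM factors computed on spike-genome
  windows restricted to the top 25% by mean count (the "high ChIP signal"
  filter), with conventional trims (30% of log-ratios, 5% of abundances).
  Because the factors are computed with equal nominal library sizes, the
  M-values are direct between-library bin log-ratios, and the inverted
  factors are renormalized to geometric mean 1. The computation is delegated
  to edgeR's `calcNormFactors`, the reference implementation of TMM.

Input normalization defaults to floored subtraction
(`max(chip − input, 0)`), matching tools that subtract a scaled input track;
a pseudocounted ratio mode (ψ = 0.5) is exposed because subtract-versus-ratio
is a genuine dialect difference between pipelines. Flooring has a
quantifiable side effect discussed under *Numerical choices*.

## Broad domains

K36 methylation forms broad domains, not point peaks. `callBroadDomains`
takes maximal runs of bins at or above a signal cutoff `c`, merges runs
separated by at most `g` bp and discards merged runs shorter than `l` bp;
the domain score is its mean signal. Defaults are `c = 3`, `l = 1000` for
the K36 marks (with 0.8 and 2.0 the matching cutoffs for K27me3 / K9me2
style domains) and `g = 100`. The merge gap is not documented by the
commonly used caller, so it is exposed as a parameter; the caller is tested
bin-for-bin against an exhaustive scan oracle. Feature annotation uses the
midpoint rule with promoter `[TSS−1000, TSS+100)` and TTS `[TTS−100,
TTS+1000)` windows and precedence promoter > TTS > exon > intron >
intergenic; a whole-overlap mode is available.

## Differential binding

Counts in 250-bp tiling windows are filtered against the matched input
(mean scaled ChIP ≥ 3 × mean scaled input) and tested in edgeR's
negative-binomial quasi-likelihood framework with a robust fit. Spike
calibration enters as the effective library size (proportional to the
inverse scale factor), so log-fold changes are absolute. The original
design sketch for this package proposed a hand-rolled moderated log-ratio
test on the grounds that NB quasi-likelihood machinery should not be
re-implemented; since edgeR is available as a dependency, the package uses
the real thing instead — the same framework the analysis this package
re-implements was built on. With a single replicate per condition the QL
dispersion is not estimable and the test falls back to a pooled common
dispersion with a warning.

Tested windows with p < 0.1 seed clusters; neighbours within 500 bp join
until a 3-kb span cap. Two choices here matter for error control and were
validated by null simulation:

* the Simes combination for a region runs over **all** tested windows inside
  the region span, not only the seed windows (combining only selected
  windows biases the combined p downward);
* Benjamini–Hochberg runs over the full tested universe — windows outside
  every region enter as singleton clusters — so that seeding does not shrink
  the multiple-testing denominator. With BH restricted to seeded clusters,
  null simulations showed 5.3% cluster-level false discovery at a nominal
  5%; with the full universe they are at or below nominal.

Reported regions additionally satisfy at least a 50% loss or gain relative
to control (fold ≤ 0.5 or ≥ 1.5). Z-score maps standardize the per-window
statistic `d = log2((x+ψ)/(y+ψ))` (5-kb window means, ψ = 0.5) over windows
with nonzero control coverage; note that when a large fraction of the genome
is genuinely depleted, standardization centres the map on the *mixture*, so
unaffected windows sit slightly above zero — `d` itself is the absolute
readout.

## Gene-centric landscape

Gene-body means of the calibrated, input-normalized tracks across
(mark × condition) are clustered with k-means (k = 12, 20 restarts, fixed
seed, clusters renumbered by descending control-me3 centroid). The original
analysis merged clusters into superclusters manually; `assignSuperclusters`
replaces this with explicit rules so results are reproducible: a cluster is
SC-I when me3 is its dominant control mark (highest standardized centroid)
*and* the (me3, Set2) pair is its strongest canonical depletion; likewise
SC-II for (me2, NSD) and SC-III for (me1, Ash1). Clusters whose control
centroids sit below the 20th percentile of gene signals for every mark
become SC-IV and are excluded downstream. SC-II genes split into IIA/IIB
purely by overlap with H3K9me2/heterochromatin domains. Unmappable clusters
fall back to the nearest supercluster centroid with a warning.

Metagene profiles use 500 scaled body bins flanked by 1 kb of unscaled
50-bp bins, genes ≥ 1500 bp only. Body resampling integrates the per-bp step
function exactly, so it is mean-preserving per gene to floating-point
precision — this is asserted in the test suite at 1e-9. The per-gene effect
statistic is the proportional change `Δp = (S_RNAi − S_ctrl)/S_ctrl`,
summarized per cluster as a median with a bootstrap confidence interval.

## The reader-retention model

The biological observation is that reader loss tracks the *combined* loss of
me2 and me3: me2 gain can compensate for me3 loss. The package formalizes
this as a saturating readout

$$R(g) = b + A\,\frac{u^m}{K^m + u^m},\qquad u = w_2\,\mathrm{me2}(g) + \mathrm{me3}(g),$$

with `w3` fixed to 1 for identifiability and `w2` initialized from the
measured nucleosome affinity ratio Kd(me3)/Kd(me2) = 0.60/0.32 ≈ 1.88. The
Hill form is chosen because it nests both proportional binding (m = 1) and a
hard threshold (large m), so the data decide where on that continuum the
reader sits. Fitting is bounded Levenberg–Marquardt over all
(gene, condition) observations with a random 20% of genes held out for an
out-of-sample R². A fitted `w2 > 0` is the model-level signature of me2
compensation. No quantitative retention model was fitted in the work this
package re-implements; the functional form and identifiability choices are
this package's own, and its outputs are labelled accordingly.

## Binding curves

`dilutionSeries(16e-6, 2, 16)` reproduces the measured design
(2:1 series from 0.488 nM to 16 µM). Simulated responses are
`F(c)(1 + ε)`, ε ~ N(0, cv), and `fitHill` pools all replicate points into
one bounded fit (Kd ∈ [c_min/10, c_max·10], h ∈ [0.5, 4], A free in sign so
monotone-decreasing signals fit symmetrically), with initialization at the
half-range concentration and up to five jittered restarts. A response whose
per-concentration means span less than three times the pooled replicate
noise raises a "no binding detected" error rather than returning an
unstable fit. Presets carry the measured affinities: Kd = 0.32 µM (K36me2),
0.60 µM (K36me3), 4.00 µM (unmodified).

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions every recovery test runs under.

**Architecture.** Three chromosomes totalling 5 Mb, 15% pericentric
heterochromatin (PCH) at the centromere-proximal end of each. 1725 genes in
six planted groups: C1 (n = 280) and C3 (245) are me3-dominant euchromatic
genes (supercluster I); C6 (230) me2-dominant euchromatic (IIA); C7 (130)
me2-dominant inside PCH (IIB); C9 (240) me1-dominant (III); SC0 (600)
unmethylated baseline genes. Non-genic K36me2 blocks in PCH and intergenic
K36me1 enhancer domains (1.4 kb) top the strong-domain footprints up to
target genome fractions of exactly 20% (me2), ~20% (me3, genic only) and
12% (me1). Group bp budgets were sized so each effect-carrying cluster holds
≥ 200 genes while the footprints hit those fractions; this lands at ~1700
genes rather than the ~2000 sketched in the original plan. Strong domains
carry enrichment excess 7 over the input baseline; secondary marks (me2 on
SC-I genes, me3 on SC-II genes) carry sub-threshold excess 0.3 — clearly
below the calling cutoff under count noise, yet quantifiable at gene level.
K36me3 excess is redistributed within genes at a 2:1 exon:intron ratio with
the gene-body mean preserved.

**Count model.** Expected per-bp coverage is `λ(x) = 1 + excess(x) ·
effect(group, condition, feature)`. Every library is sequenced to the same
expected target depth D (default 2 × 10⁶), while expected spike reads scale
*inversely* with the library's enrichment integral — this is what a
cell-number spike-in measures: a more efficient IP yields a smaller spike
share. Consequently spike-scaled coverage equals a common `γ·λ(x)` for all
libraries and planted multiplicative effects are recovered exactly in
expectation; the configured 5% spike share holds for unenriched (input)
libraries. Counts are negative binomial (gamma-Poisson) with dispersion 0.1
per 50-bp bin — no noise model was reported for the real libraries, so this
and the log-normal depth jitter (σ = 0.2) applied per library are generator
choices made once. Effects multiply the enrichment *excess*, not the
background, so the planted proportional change of input-normalized signal
equals `effect − 1` exactly.

**Planted effects** encode the measured biology: under Set2 RNAi, C1 genes
lose 50% me3, double me2 and lose 20% reader; C3 genes lose 70% me3, gain
50% me2 and lose 55% reader; under NSD RNAi, C6 genes collapse both marks
(me2 × 0.3 — a stand-in for "eliminated", which was not quantified — and
me3 × 0.4) with 60% reader loss; Ash1 RNAi halves me1 on C9 genes and
enhancers; the double knockdown suppresses the C1 me2 gain; the triple
knockdown depletes everything.

**What the generator does and does not emulate.** It reproduces the
statistical structure the pipeline relies on — compartmentalized genome,
group-wise multiplicative effects, spike-in bookkeeping, overdispersed
counts, depth jitter — but not read-level realism: no sequence content, no
fragment-length or GC effects, no nucleosome positioning, no
mappability gaps. Passing recovery tests therefore demonstrates that the
*computations* are correct and calibrated, not that the pipeline is robust
to every artefact of real libraries. Two idealizations are deliberate:
all planted breakpoints lie on the 50-bp simulation lattice (the generator's
fidelity contract is bin resolution; off-lattice breakpoints would make
boundary bins mix two planted levels and misstate the planted piecewise
profile), and planted elements are separated by at least 500 bp (one gene
analysis window) so neighbouring elements never share a window — with
abutting genes, a strong neighbour's signal bleeds into a gene's boundary
window and contaminates its proportional change by several points in a
genome-realization-dependent way.

## Numerical choices

* **Resolutions.** Simulation and domain calling run at 50-bp bins;
  differential windows are 250 bp; gene-body quantification uses tracks
  resized to 500-bp windows; Z-maps use 5-kb windows and chromosome maps
  10 kb (2 kb for differential maps). The 500-bp gene window matters
  because floored input subtraction is applied bin-wise: at fine bins a
  noticeable share of weak-signal bins floors to zero and the truncated
  noise biases gene means upward; averaging into 500-bp windows before
  subtraction keeps that bias below a percent while leaving gene bodies
  (≥ 1.5 kb for profiles) well resolved.
* **Pseudocount** ψ = 0.5 scaled units wherever a log-ratio is taken.
* **Seeds.** A single master seed fans out to stage and library seeds by a
  stable polynomial string hash (`stageSeed`), so every stage is
  independently reproducible and a manifest of seeds suffices to replay an
  experiment byte-for-byte.
* **Ties and degeneracies.** Per-gene peak windows break argmax ties
  leftmost; domains tied at the strongest-decile score threshold are all
  retained; identical condition/control tracks yield all-zero Z with a
  warning; genes without exon records are treated as single-exon (with a
  message); intronless genes are excluded from exon/intron bias; genes with
  zero control signal are excluded from proportional changes and counted.
* **Problem sizes.** Recovery tests and the acceptance computation run the
  default 5-Mb/1725-gene preset with two replicates per ChIP cell; the
  calibration (null) simulations use a 1-Mb preset over 20 seeds; the
  domain-caller property test uses one hundred 10-kb toy tracks. These sizes
  give medians over ≥ 200 genes per cluster and stable false-discovery
  estimates while keeping the whole suite comfortably fast on one CPU.

## Known limitations

* The differential module fixes the typical two-group,
  replicate-with-batch design; arbitrary design matrices are out of scope.
* Broad-domain calling has no summit resolution and is not meant for narrow
  peaks.
* The reader model is a phenomenological readout, not a kinetic exchange
  model; MST curves are abstracted to generic concentration–response pairs
  with no thermophoresis physics.
* bigWig output is not produced; bedGraph/BED/TSV/JSON are the exchange
  formats.
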