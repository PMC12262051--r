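# k36land

Quantitative analysis of context-dependent histone H3K36 methylation
landscapes from spike-in calibrated ChIP signal.

H3K36 mono-, di- and tri-methylation (K36me1/2/3) are placed by three
methyltransferases (Ash1, NSD, Set2) whose contributions are locus-specific:
depleting one enzyme removes a mark at some gene classes, leaves it intact at
others, and can even increase the neighbouring methylation state. Because the
depletions shift *global* ChIP signal, none of this is measurable without an
exogenous spike-in to put libraries on a common absolute scale. `k36land`
implements the full analysis chain for this kind of experiment, for
computational epigenomicists who want each stage as a reusable, tested
building block:

* **Spike-in calibration** — per-library scale factors, either
  `factor = 10^6 / (spike-in mapped reads)` (total-read mode) or trimmed mean
  of M-values (TMM; log-ratio trim 30%, abundance trim 5%) on high-signal
  spike-genome windows, renormalized to geometric mean 1.
* **Input normalization** — floored subtraction
  `max(chip − input, 0)` (default) or pseudocounted ratio.
* **Broad-domain calling** — maximal runs of bins with signal ≥ c, gap-merged
  (≤ g bp) and length-filtered (≥ l bp); defaults c = 3, l = 1000 for the K36
  marks. Genome fractions, strongest-decile filtering, midpoint feature
  annotation (promoter > TTS > exon > intron > intergenic) and chromosome-map
  binning attach here.
* **Differential binding** — 250-bp window counts, input filtering,
  negative-binomial quasi-likelihood tests (edgeR, robust fit) with
  spike-derived effective library sizes, merging into regions of ≤ 3 kb with
  Simes-combined p-values and Benjamini–Hochberg cluster-level FDR at 0.05;
  Z-score maps `z = standardize(log2((x+ψ)/(y+ψ)))` on 5-kb windows.
* **Gene-centric landscape** — gene-body signal matrices, k-means clustering
  (k = 12) with rule-based merging into superclusters (SC-I Set2/me3, SC-II
  NSD/me2 split into euchromatic IIA / heterochromatic IIB, SC-III Ash1/me1,
  SC-IV low-signal), metagene profiles (500 scaled body bins, unscaled 1-kb
  flanks, genes ≥ 1500 bp), exon/intron bias and the per-gene proportional
  change `Δp = (S_RNAi − S_control) / S_control`.
* **Reader retention model** — a saturating dual-mark readout
  `R = b + A·uᵐ/(Kᵐ + uᵐ)` with `u = w₂·me2 + me3`, formalizing the
  hypothesis that chromatin readers (JASPer PWWP, MSL3 chromodomain) are
  retained while the combined K36me2 + K36me3 density stays above a critical
  level; `w₂ > 0` is the signature of me2 compensation.
* **Binding curves** — simulation and bounded nonlinear least-squares fitting
  of the specific-binding-with-Hill-slope model
  `F(c) = F0 + A·cʰ/(Kdʰ + cʰ)` for MST-style dilution series
  (16 steps, 2:1, 0.5 nM – 16 µM).

Everything runs on a **synthetic-data module** that plants the effect
structure the analysis is designed to recover: a ~5-Mb genome with
euchromatin and pericentric heterochromatin, ~1700 genes in labelled cluster
groups, per-mark domain footprints at target genome fractions (~20% me2/me3,
~12% me1), a 5% cell-number spike-in, negative-binomial count noise and
multiplicative depletion effects taken from the measured biology (e.g.
cluster-1 genes under Set2 depletion: me3 −50%, me2 +100%, reader −20%).
Every pipeline stage is therefore testable end to end without downloads.

## Worked example

Fit a simulated nucleosome-binding curve from the K36me2 preset
(Kd = 0.32 µM) and call K36me2 broad domains on a simulated control library:

```r
library(k36land)

conc  <- dilutionSeries(16e-6, 2, 16)        # 0.488 nM ... 16 uM
curve <- simulateMstCurve(mstPreset("K36me2"), conc, noiseCv = 0.05,
                          replicates = 6, seed = 101)
fitHill(curve, seed = 1)
#> HillFit (specific binding with Hill slope)
#>   Kd = 3.15e-07 M (se 9.5e-09), h = 0.97, A = 0.9967, F0 = -0.002407
#>   RSS = 0.04407 over 96 points

preset <- buildGenomeModel(seed = 1)
preset
#> GenomePreset: 3 chromosomes, 5e+06 bp, 1725 genes
#>   gene groups: C1=280 C3=245 C6=230 C7=130 C9=240 SC0=600
#>   planted domain fractions: K36me1 0.120 K36me2 0.200 K36me3 0.200

eff  <- defaultEffectTable()
chip <- simulateLibraryCounts(preset, eff, "GST", "K36me2", seed = 11)
inp  <- simulateLibraryCounts(preset, eff, "GST", "input",  seed = 12)
fChip <- 1e6 / spikeReads(chip)              # spike-in scale factors
fInp  <- 1e6 / spikeReads(inp)
norm <- inputNormalize(scaleTrack(asCoverageTrack(chip), fChip),
                       scaleTrack(asCoverageTrack(inp),  fInp))
domains <- callBroadDomains(norm, cutoff = 3, minLen = 1000,
                            mark = "K36me2", condition = "GST")
domains
#> DomainSet (K36me2, GST): 440 domains, 1.03e+06 bp total
#>   params: cutoff=3 minLen=1000 maxGap=100
genomeFraction(domains, preset)
#> [1] 0.207
```

The fitted Kd (0.315 µM) recovers the preset affinity within noise, and the
called domain footprint (20.7% of the genome) recovers the planted 20%
K36me2 fraction. `runPipeline(pipelineConfig(seed = 7))` chains all stages —
simulation, normalization, domain calling, differential analysis, gene
clustering and the reader-model fit — into one deterministic result bundle.

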