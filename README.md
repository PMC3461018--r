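# wavecall

Wavelet-based detection of enriched regions in ChIP-Seq data, for
epigenomics analysts who need one caller that handles both punctate
binding-site peaks (TFBS, H3K4me3) and broad, diffuse histone-modification
domains (H3K36me3, H3K27me3) without assuming a parametric background
model.

## The method

Aligned, deduplicated reads are shifted by half the fragment length to
represent fragment centers and binned into non-overlapping windows
(default 200 bp). Each chromosome's count vector *x(t)* is decomposed with
the continuous wavelet transform

  W(s, t') = Σ_t x(t) · (1/√s) ψ*((t − t')/s),

computed by FFT over a dyadic scale grid s_j = s₀·2^(j·dj), with either
the Morlet wavelet ψ(η) = π^(−1/4) e^(iω₀η) e^(−η²/2) (punctate and
moderately broad features) or the Mexican hat (very broad domains). The
wavelet power |W(s,t')|² localizes enrichment energy in position and
scale.

Significance is learned from the data itself, in three nonparametric
stages:

1. **Monte Carlo power thresholds.** N random track segments (default
   N = 5000, length 2¹² windows) are transformed and the power at each
   segment midpoint sampled; the per-scale threshold is the empirical
   upper p_thres-quantile (default 0.2; 0.4 for broad marks). Windows
   whose power exceeds the threshold at some scale in the calling band —
   with a positive coefficient, so troughs are excluded — are significant.
2. **Gap merging.** Runs of significant windows separated by at most *g*
   non-significant windows become one putative peak (g = 0 for sharp
   peaks, up to 10 for H3K27me3-like domains), with no upper limit on a
   merged peak's internal gaps.
3. **Peak significance.** Without a control, each peak's read count r is
   compared with the empirical null F(R) built by dropping P = 10⁶
   length-matched intervals at random genomic positions:
   p = (1 + #{R ≥ r}) / (P + 1). With a matched control, counts scaled to
   reads-per-million are compared by a two-sided exact binomial test with
   H₀: p = ½. Benjamini–Hochberg correction yields q-values; a
   control-swap pass merges regions significant in either direction into
   one non-redundant differential list.

A synthetic-data module simulates multi-chromosome genomes with Poisson
background and spiked enrichment intervals (punctate, intermediate, or
diffuse archetypes) plus matched test/control pairs, providing ground
truth for calibration and benchmarking.

## Worked example

```r
library(wavecall)
library(GenomicRanges)

genome <- GenomeInfoDb::Seqinfo(c("chr1", "chr2"), c(6e6, 4e6))
spikes <- tileSpikes(genome, 20, c(1000, 1000), fold = 20, seed = 4)
sim    <- simulateReads(simSpec(genome, backgroundRate = 0.5,
                                spikes = spikes), seed = 5)
length(sim$reads)
#> [1] 25715

peaks <- callPeaks(sim$reads, genome, seed = 6)
length(peaks)
#> [1] 4881

sig <- peaks[peaks$qValue < 0.05]
sig[1:3]
#> GRanges object with 3 ranges and 6 metadata columns:
#>       seqnames          ranges strand |  nWindows  maxPower  boundary readCount
#>   [1]     chr1   292401-293400      * |         5   31.7415     FALSE        39
#>   [2]     chr1   504401-505400      * |         5   29.4755     FALSE        39
#>   [3]     chr1 1146601-1147600      * |         5   82.7795     FALSE        56
#>            pValue    qValue
#>   [1] 1.46000e-04 0.0375066
#>   [2] 1.46000e-04 0.0375066
#>   [3] 8.99999e-06 0.0130160

unlist(scoreAgainstTruth(sig, spikes))
#>    recall precision   nCalled
#>      0.95      1.00     19.00
```

The 4881 putative peaks are everything the permissive wavelet stage
emits; the q < 0.05 filter retains 19 calls, all overlapping true spikes,
recovering 19 of the 20 (the one missed spike drew an unusually low read
count). `writePeaks()` exports BED6+ with readCount, p, q and maximum
power; `diffPeaks()` runs the two-sample workflow and returns merged DMRs
with direction labels.

A command-line front end with `simulate`, `callpeaks`, `diffpeaks` and
`gapscan` subcommands is installed at
`system.file("scripts", "wavecall.R", package = "wavecall")`.

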