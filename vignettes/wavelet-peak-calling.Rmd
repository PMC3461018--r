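---
title: "Wavelet-based peak calling: model, parameters, and design notes"
author: "wavecall maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based peak calling: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ChIP-Seq enrichment comes in radically different shapes: transcription
factor binding sites and H3K4me3 produce sharp, kilobase-scale peaks;
H3K36me3 covers gene bodies in 2–10 kb stretches; H3K27me3 silences
regions tens to hundreds of kilobases wide at low signal-to-noise.
Fixed-bandwidth callers are tuned to one of these regimes. `wavecall`
instead scans all feature widths simultaneously through the continuous
wavelet transform (CWT) of the windowed read-count track, and makes every
significance decision nonparametrically, from the data being analysed.

## The model

**Preprocessing.** Reads are deduplicated (one read per chrom/start/end/
strand), shifted by `shift` bp from their 5' end to the fragment center
(default 95 bp — half of a ~190 bp mononucleosomal fragment; override for
libraries with other fragment sizes), and counted in non-overlapping
windows of `windowSize` bp (default 200). Peak calling runs on raw
counts; reads-per-million scaling (`normalizePerMillion()`) is used only
for cross-sample reporting, because every threshold in the pipeline is
learned from the same track, making calling exactly invariant to global
rescaling (a property the test suite asserts).

**Transform.** Per chromosome, the count vector is zero-padded to the
next power of two and convolved (via FFT) with scaled, unit-energy
wavelets on the dyadic grid $s_j = s_0 2^{j\,\delta j}$ with $s_0 = 2$
windows, $\delta j = 0.25$, up to $\min(1024, L/4)$ windows where $L$ is
the Monte Carlo segment length. Two mother wavelets are provided: the
analytic Morlet ($\omega_0 = 6$ by default; admissibility requires
$\omega_0 \ge 5$) and the Mexican hat (second derivative of a Gaussian).
Larger scale means a wider wavelet; the Fourier period of scale $s$ is
$4\pi s/(\omega_0 + \sqrt{2+\omega_0^2}) \approx 1.03\,s$ for Morlet and
$2\pi s/\sqrt{2.5} \approx 3.97\,s$ for the Mexican hat. Positions within
the e-folding distance $\sqrt{2}s$ of a chromosome end are inside the
cone of influence; peaks touching it are flagged (`boundary`), not
dropped, so telomeric enrichment is retained with a caveat rather than
silently lost.

**Monte Carlo thresholds.** `N` contiguous segments of `sampleLength`
windows (defaults 5000 and $2^{12}$) are drawn with replacement,
chromosome chosen proportionally to its eligible start windows. Each
segment's power-spectrum column at the segment *midpoint* — the point
most distant from the pad edges — yields, per scale, an empirical
distribution whose upper `pThres`-quantile (the $\lceil(1-p)N\rceil$-th
order statistic) is the significance cutoff. By construction the
fraction of sampled powers above the cutoff equals `pThres` up to ties
and $1/N$. Thresholds are pooled across chromosomes by default so that
short chromosomes remain estimable; pass `chromosomes=` to
`mcThresholds()` for per-chromosome cutoffs.

**Window significance and the calling band.** A window is significant
when its power exceeds the cutoff at the scale of maximal excess within
the *calling band*, with a positive real coefficient there (the
transform responds to depleted troughs as strongly as to enriched peaks;
the sign separates them). The band is the one deliberately
shape-specific parameter: Morlet defaults to scales 4–10 windows
(0.8–2 kb features at 200 bp windows), the Mexican hat to 8–64 windows
(~10–50 kb domains). The full grid is always computed and exposed; only
calling is banded. We chose banded defaults after simulation showed that
letting the largest scales trigger calls merges marginal background
fluctuations into putative peaks tens of kilobases long, whose lengths
then contaminate the randomized null (below) and mask true peaks, while
the smallest scales flood the peak list with single-window shot noise.
For intermediate marks (H3K36me3-like), widen the band (e.g.
`scaleBand = c(4, 48)`) and raise `g`.

**Gap merging.** Maximal runs of significant windows with inter-run gaps
of at most `g` non-significant windows merge into one putative peak that
always starts and ends on a significant window. There is no cap on the
non-significant windows inside a merged peak — unlike island callers
that bound them for closed-form statistics — because broad marks are
genuinely discontinuous. Recommended values: `g = 0` for TF peaks, 2 for
H3K4me3, 5 for H3K36me3, 10 for H3K27me3; `gapSaturation()` reports the
read-coverage of the top-N peaks as a function of `g`, which saturates
at a mark-dependent rate and guides the choice on real data.

**One-sample significance.** `P` (default $10^6$) intervals with lengths
resampled from the putative-peak length multiset are placed uniformly on
the genome (chromosome weighted by its valid starts for that length) and
their shifted-center read counts tallied into the frequency table
$F(R)$. A peak with $r$ reads gets
$p = (1 + \#\{R \ge r\})/(P+1)$: the +1 pseudocount is the standard
permutation-test correction that keeps $p$ strictly positive (a raw tail
sum can be 0, which breaks both BH and log-scale reporting) and differs
from the plain tail ratio by at most $1/P$. The null is built from the
same sample's raw reads, so no background distribution is assumed.

**Two-sample significance.** For each putative peak the test and control
counts are scaled to reads per million and rounded; under the null that
a read is equally likely from either library, the test count is
Binomial$(t, 1/2)$ with $t$ the normalized total. The default two-sided
p-value is the minimum-likelihood sum, which for this symmetric binomial
is both tails beyond the observed count and its mirror; the printed
upper-tail ("at least T successes") variant is available with
`alternative = "greater"`. Rounding is needed because an integer trial
count is; the alternative `normalize = FALSE` mode tests raw counts
against success probability $\mathrm{lib}_T/(\mathrm{lib}_T +
\mathrm{lib}_C)$, which is statistically cleaner at low counts but no
longer matches the per-million framing. Benjamini–Hochberg correction is
applied genome-wide per run (via `stats::p.adjust`), never per
chromosome. `diffPeaks()` repeats the analysis with peaks called on the
control (using the same threshold seed, so swapping the input files
reverses every direction label exactly), filters both passes at
`alpha`, and unions intervals overlapping by at least 1 bp into the
final non-redundant differential list annotated with direction(s) and
minimum q.

## Parameter summary

| parameter | default | units | meaning |
|---|---|---|---|
| `windowSize` | 200 | bp | count-window width |
| `shift` | 95 | bp | 5'-end to fragment-center shift |
| `wavelet` | morlet | — | morlet (punctate) / mexican_hat (broad) |
| `omega0` | 6 | — | Morlet non-dimensional frequency |
| `pThres` | 0.2 | probability | per-scale power-threshold tail (0.4 broad) |
| `g` | 0 | windows | gap bridged between significant runs |
| `nSamples` | 5000 | segments | Monte Carlo sample count |
| `sampleLength` | 4096 | windows | Monte Carlo segment length (power of 2) |
| `P` | 1e6 | intervals | randomized-null size |
| `scaleBand` | by wavelet | windows | scales allowed to trigger calls |
| `alpha` | 0.05 | FDR | cutoff for the merged DMR list |

## The synthetic generator

`simSpec()`/`simulateReads()` emulate the features the method must
handle: a multi-chromosome genome, homogeneous Poisson background
(`backgroundRate` reads per window), and non-overlapping spiked
intervals whose center rate is multiplied by `fold`, either uniformly
(`block`) or with a Gaussian taper (sd = width/4). Fragment centers
become stranded 36 bp reads whose 5' ends sit half a fragment from the
center, so the standard shift recovers centers exactly.
`simulatePair()` adds test-only spikes over a shared spike set with
independent noise, producing ground-truth differential regions. The
package's recovery tests use three archetypes chosen to mirror the
mark classes: punctate (20 × 1 kb spikes at fold 20 over 0.5
reads/window on 10 Mb — about 2 sites/Mb, between typical TF and
promoter densities), and diffuse (8 × 20–50 kb blocks at fold 3).

What the generator does *not* emulate: mappability and GC structure,
PCR-duplicate excess, copy-number variation, chromatin-state
autocorrelation of the background, and read-sequence errors. Passing the
synthetic recovery tests therefore demonstrates the statistical engine
under a neutral background, not robustness to those real-data artifacts
— for real data the control-based two-sample mode absorbs most of them.

## Numerical choices and degenerate inputs

Zero-padding (not reflection) to the next power of two, with the cone of
influence flagged; power-of-two signals are transformed circularly with
no padding. The per-scale threshold uses a deterministic order statistic,
so identical seeds give bit-identical thresholds, peaks and q-values (an
asserted invariant). Normalized binomial p-values are clamped to
$[10^{-300}, 1]$ against underflow at extreme imbalances. Empty read
files yield zero peaks and a clean exit; constant tracks yield zero
significant windows (a zero-mean wavelet nulls them); reads on unknown
chromosomes are skipped with a message, while malformed BED lines abort
with their line number. Read shifting clamps to chromosome bounds and
never drops a read. In `estimateThresholds()` the "fixed point" of each
segment is its midpoint, minimizing pad contamination. The batched
threshold stage computes only the midpoint column of each segment's
transform (one FFT per segment plus per-scale dot products), which is
algebraically identical to the full transform's midpoint column; a unit
test checks the identity.

## Known limitations

* **Null self-contamination bounds power.** Because randomized intervals
  may land on enriched regions, the null's count tail includes the
  signal's own footprint; the more of the genome is enriched, the more
  conservative the one-sample p-values. At shallow depth (~50 reads per
  true peak) peaks whose Poisson draw falls below ~40 reads become
  statistically inseparable from that contaminated tail at FDR 0.05,
  which caps recall in the weakest regime. This is inherent to a
  distribution-free self-null; a matched control (two-sample mode)
  restores power.
* The permissive thresholding stage (`pThres` of all windows per scale)
  necessarily emits thousands of background putative peaks; they are
  controlled by the FDR stage but enlarge the multiple-testing burden.
* Scales below ~4 windows cannot be meaningfully compared against
  time-domain convolution because the sampled wavelet aliases there; the
  frequency-domain transform is the definition used throughout.
* Single-end logic only: fragment length is a parameter, not inferred.

## Problem sizes in the test suite

The suite runs the full pipeline on 2.5–10 Mb two-chromosome genomes
with Monte Carlo sizes scaled to the task: unit tests use N = 300,
L = 512, P = 2·10⁴; the end-to-end recovery and calibration checks use
the analysis defaults (N = 5000, L = 4096, P = 10⁶) or N = 1000,
P = 10⁵ for the 20-replicate calibration, sizes at which every
documented property is already stable.
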