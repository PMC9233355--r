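---
title: "Pool genetic maps: estimating recombination rates from pooled allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool genetic maps: estimating recombination rates from pooled allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombPool)
```

## The problem

Recombination-rate (RR) estimation normally requires genotyping many
individuals of a segregating population, because each meiosis contributes
only a handful of crossovers. Genotyping costs scale linearly with the
number of individuals, which makes dense RR screens — across environments,
genetic backgrounds, or many populations of a crossing program — expensive.

Pooling sidesteps this: a single library prepared from a pool of
individuals yields genome-wide **allele frequencies** (from array
intensities or sequencing allele depths) at every polymorphic locus, at the
cost of one sample, but destroys haplotype information. `recombPool`
implements an estimator that recovers a genetic map and windowed RR from
nothing but those pooled allele frequencies and the loci's physical
positions.

## The model

In an F2 (or RIL) population descended from two fully homozygous inbred
parents, every locus has an expected allele frequency of 0.5. Finite
population size makes the realized frequency drift away from 0.5, and
because linked loci drift together, the frequency profile along a
chromosome is a smooth random walk whose *increments* between neighbouring
loci reflect the recombination between them: for pooled dosages of an F2 of
$n$ individuals,

$$\operatorname{Var}(AF_2 - AF_1) = \frac{r_{12}}{2n},$$

with $r_{12}$ the recombination fraction of the pair (the per-locus
variance is $1/8n$ and the dosage correlation of linked loci is $1-2r$).
A frequency jump between close neighbours therefore signals local
recombination. The estimator scales the jump by the physical distance:

$$K_{M_1M_2} = \frac{|\Delta AF_{M_1M_2}|}{\log_{10} \Delta \mathrm{Dist}_{M_1M_2}},$$

and accumulates $K$ along each chromosome into the **raw pool genetic map
(PGM)**. The absolute value is forced by the statistic itself: only the
magnitude of the frequency difference is informative, and a non-negative
increment is what makes the cumulative map monotone. For this to work the
allele frequencies must be *consistently polarized* along the genome (the
parent-2 allele in simulations, the ALT allele from a VCF); folding to
minor-allele frequencies would corrupt differences across the 0.5 boundary
and is deliberately not offered.

Since $E|\Delta AF| \propto \sqrt{r/n}$, the raw PGM is a heavily
compressed, depth- and size-dependent image of the true map: its total
length grows with the number of assayed loci (more pairs, each contributing
a positive increment) and shrinks with population size (less drift). The
**calibration model** absorbs both effects. With the observed correction
factor $adj_{start} = ML_{ref}/ML_{PGM}$ (reference over raw map length)
collected over a simulation grid of genotyping depths ($\Sigma SNPs$) and
population sizes ($\Sigma Genotypes$), the model

$$adj_{start} = \alpha\, e^{\beta \log_2 \Sigma SNPs}\, e^{\gamma \log_2 \Sigma Genotypes} + \frac{\theta}{\sqrt{\Sigma SNPs}}$$

is fit by Levenberg–Marquardt least squares and selected against a
no-intercept linear baseline ($adj_{start} = a\,\Sigma SNPs + b\,\Sigma
Genotypes$) by AIC and log-likelihood; the non-linear form wins on every
grid we have fit, consistent with the $\sqrt{n}$ and
$\approx \Sigma SNPs^{-0.5}$ scaling the drift model predicts. Multiplying
every $K$ by the predicted $adj_{start}$ yields the **nPGM** in
centiMorgans (K′ = K · adj_start). The package ships the published F2
calibration, `defaultAdjustmentModel()` with
$(\alpha, \beta, \gamma, \theta) = (7958.92, -0.5401, 0.3491, 691.0495)$;
because that surface was calibrated on a specific reference genome and
marker system, absolute lengths for other genomes should be recalibrated
(`calibrateAdjustment()`) or linearly rescaled against a known map length —
windowed RR *correlations* are invariant to the scalar and unaffected
either way.

The **HGM baseline** (individual genotypes) estimates, per physically
adjacent marker pair, the maximum-likelihood F2 recombination fraction by
EM over the nine joint dosage classes — the double-heterozygote class mixes
parental and recombinant gamete pairs and is resolved in the E-step — with
a symmetric genotyping-error probability (default 1e-4) mixed into the
emission probabilities, then maps $\hat r$ through Haldane's function
$d = -50\ln(1-2\hat r)$ cM and accumulates. Two-point chaining over the
fixed physical order replaces multipoint estimation: marker order is given
by the assembly here, so multipoint re-ordering machinery would add nothing.

**Windowed RR** divides each adjacent interval's genetic length by its
physical length (cM/Mb) and summarizes intervals in sliding windows
(default 50 Mb, slide half a window, at least 2 contributing pairs), each
interval assigned to windows by its bp midpoint — the unambiguous choice
for intervals straddling window edges; assignment by left marker is
available as a flag. Windows are reported with 0-based half-open
coordinates so the TSV doubles as BED. The **GRE** (general recombination
effect) summarizes per-parent influence on genome-wide RR across a crossing
design by a sum-to-zero main-effects least-squares fit — a deliberately
simple stand-in for the G-BLUP used in the literature, and labelled as such
in its output.

## Aggregating windows: median vs mean

The individual-genotyping maps use the median interval RR per window. For
pool-derived maps we aggregate with the *mean* (and the comparison
functions default accordingly in the examples): pooled allele frequencies
live on a lattice of resolution $1/2n$, so adjacent-pair $|\Delta AF|$ takes
few discrete values and the within-window *median* of $K$ collapses onto
that lattice, quantizing the window track and destroying resolution (at
depth 10,000 and $n = 2000$ the Pearson correlation with the true windowed
RR is ~0.71 with medians and ~0.97 with means). The mean is also what the
pool-map RR summary in the source method uses.

## The simulators, and what they do not emulate

`makeSyntheticMap()` builds the reference map: equally spaced markers, with
either a uniform genetic profile or the default `barley_like` profile that
concentrates ≥ 70% of the genetic length in the outer chromosome thirds
(pericentromeric suppression typical of large cereal genomes). Defaults —
7 chromosomes, 600 Mb and 150 cM each, 1500 markers per chromosome — are
chosen at the scale of a barley-like genome and a mid-density consensus
map.

`simulateGametes()` implements Haldane (no-interference) meiosis exactly:
per chromosome, a Poisson number of crossovers in the genetic length
(Morgans), uniform crossover positions on the cM axis, Bernoulli(0.5)
starting parent, markers between the same crossovers sharing origin. F2
individuals are sums of two independent gametes; RILs iterate selfing
(`Inf` runs to fixation, capped at 50 rounds, residual heterozygotes
resolved by a fair coin per locus). The simulator never generates missing
data; missingness handling is exercised through the filter surface.
`simulateReadCounts()` reduces pooled sequencing to a binomial read-count
model: per-locus depth fixed or Poisson, alt count Binomial with
$p' = AF(1-e) + (1-AF)e$ and default per-read error $e = 0.001$.

What passing tests on these simulators show — and what they do not: the
meiosis model validates every statistical property the estimator relies on
(drift magnitudes, Haldane recombinant fractions, map recovery), but real
data add marker-order errors, structural variation, segregation distortion,
uneven marker density, and, for sequencing, alignment and variant-calling
artefacts. None of these are emulated. In particular, the read-count model
deliberately omits the read-level pipeline (read simulation, alignment,
calling), with a concrete consequence: the depth-dependent recovery pattern
reported for full read-level pool sequencing (correlations rising steeply
from 10 to 50–100 reads per locus) does *not* emerge from binomial count
noise alone. At pool sizes of 50–100, the per-pair drift signal
$\sqrt{r/2n}$ sits an order of magnitude below read-sampling noise at all
three depths; a rectified statistic like $|\Delta AF|$ responds to
sub-noise signal only quadratically, and the component the two tracks do
share (marker-density structure) scales with the noise mean and cancels in
correlations. Reproducing that pattern evidently requires the read-level
mechanisms (notably variant-calling dropout reshaping the marker set at low
depth), which are out of scope here; the corresponding check in the test
suite documents this as an expected failure of the simplified model, not of
the estimator.

## Numerical choices and degenerate inputs

* Marker filters, in order: missing physical positions; *all* copies of a
  duplicated (chrom, bp) position; monomorphic loci (AF exactly 0 or 1);
  optional MAF floor; missing fraction strictly greater than 0.10. An
  emptied track raises an error naming the dominating filter.
* `computeK()` guards the logarithm with a 2 bp minimum pair distance
  (log10 of 1 bp is 0); closer pairs become counted zero-length increments.
  The coarser rule sometimes advisable for very dense tracks — dropping
  loci closer than ~10 kb — is available as `thinMarkers()` and the CLI's
  `--min-dist`, off by default.
* Recombination fractions are clamped below 0.4999 to keep Haldane
  distances finite; EM runs to 1e-9 on $\hat r$; pairs with fewer than 10
  jointly non-missing individuals are skipped and chained as zero-length
  with a warning.
* The non-linear fit starts at $\alpha = \mathrm{median}(adj_{start})$,
  $\beta = -0.5$, $\gamma = 0.35$, $\theta = 0$ — the surface is multi-modal
  in principle and these starts sit in the regime the model is built for.
  Convergence is parameter change below 1e-10; because the underlying LM
  implementation caps iterations per call, the fit restarts from its last
  estimate until that criterion holds and refuses fits that never reach it.
  Log-likelihood and AIC use the Gaussian MLE-σ convention (k = 5
  non-linear, k = 3 linear).
* $adj_{start}$ is a single genome-wide scalar per sample (map lengths
  summed over chromosomes), never per-chromosome.
* An F2-calibrated model refuses RIL samples: fully inbred lines accumulate
  roughly twice the visible recombination (Haldane–Waddington
  $R = 2r/(1+2r)$), so applying an F2 calibration silently would
  misestimate lengths by ~2×. The doubling heuristic is available behind an
  explicit `rilExpansion = TRUE` / `--ril-expansion` opt-in; recalibration
  on RIL simulations is the recommended route when absolute lengths matter.
* Windows tile each chromosome from its start in steps of
  `slideFrac × windowMb`; when the complete tiling stops short of the
  chromosome end one trailing window is added and flagged `partial`.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations are sized for a desk-scale
end-to-end run while keeping Monte-Carlo error well inside the asserted
bands: drift checks use 210 loci spread over 7 chromosomes × 20 replicates
(pool sizes 50 and 10,000); the Haldane-map check 1,200 markers ×
10 replicates at population size 500; the calibration grid 3 depths ×
3 sizes × 5 replicates on a 2,400-marker map; the window-correlation check
a 10,000-marker subsample at population size 2,000. Loci for the drift law
are spread genome-wide because linked loci share drift — the Monte-Carlo
standard error is taken over independent replicates, not over correlated
loci.

## Known limitations

* The estimator recovers *relative* recombination structure well; absolute
  map lengths inherit the calibration's domain. Outside it (other genomes,
  marker systems, RIL pools, sequencing-derived frequencies), rescale
  against a known map length or recalibrate.
* Because $E[K] \propto \sqrt{r}$, the pool map compresses high-RR regions
  relative to low-RR regions within a chromosome; window correlations are
  robust to this monotone distortion but per-interval absolute rates in
  extreme-RR regions are biased toward the genome mean.
* Very skewed inter-marker distance distributions degrade the estimate
  (the log-distance denominator varies while the drift signal does not);
  thinning closely spaced loci can help.
* The GRE here is a fixed-effects approximation, not G-BLUP; use it for
  ranking, not for variance-component interpretation.

## A minimal run

```{r example, eval = FALSE}
map <- makeSyntheticMap()                       # barley-like reference map
sub <- subsampleMarkers(map, 10000, seed = 1)   # genotyping depth
pop <- simulateF2(sub, 2000, seed = 2)          # pooled population
af  <- poolAlleleFreq(pop)

k    <- computeK(filterMarkers(af))
adj  <- predictAdjStart(defaultAdjustmentModel(), nSnps = 10000, nGenotypes = 2000)
npgm <- buildPGM(applyAdjustment(k, adj), useAdjusted = TRUE)

compareRR(windowRR(sub, stat = "mean"), windowRR(npgm, stat = "mean"))
```
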