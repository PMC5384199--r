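---
title: "Theta-band network analysis of an observational fear conditioning session"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-band network analysis of an observational fear conditioning session}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ofcnet)
```

This vignette documents the methods implemented in `ofcnet`, the modeling
assumptions behind the synthetic-data generator, and the reasoning behind
the non-obvious design decisions.

## Session protocol and epoching

An observational fear conditioning (OFC) session is 300 s of habituation
followed by 240 s of conditioning in which the demonstrator receives a
2-s foot shock every 12 s. Foot shocks produce large electrical
artifacts, so analysis windows exclude a 1-s guard on both sides of every
shock: each 12-s cycle contributes one window of
$12 - 2 - 2\times1 = 8$ s, and the default session yields exactly twenty
such windows. Habituation is tiled into 10-s windows (30 of them).

```{r}
p <- session_protocol()
head(as.data.frame(conditioning_epochs(p)), 3)
```

Epochs are half-open intervals $[start, end)$ in seconds;
`epoch_samples()` floors both ends when discretizing, so adjacent tiles
never share a sample. Conditioning quarters are formed from consecutive
shock cycles (5 cycles each by default); if the cycle count is not
divisible by four, the remainder goes to the last quarter with a warning.

## Filtering: why hand-built second-order sections

The theta band here is 3–8 Hz. At a 1600 Hz sampling rate this is a very
narrow normalized band, and a Butterworth band-pass of prototype order 4
has 8 poles crowded near $z = 1$. Representing that filter as a single
polynomial transfer function is numerically ill-conditioned — the
expanded-coefficient form produced gains of 1.5 in the passband and
unbounded output at the band edge in our checks. The filter is therefore
designed pole-by-pole: analog low-pass prototype, low-pass→band-pass
transform, bilinear mapping, and conjugate pairing into cascaded biquads
(second-order sections). Each biquad is applied forward and backward
(zero phase) in a small compiled kernel; zero-phase filtering matters
because lag structure feeds the cross-correlation stage. Gains are
−3 dB at the band edges and unity at the geometric center. The test
suite cross-checks the cascade against an independent implementation
section by section.

## Connectivity

For one subject and phase, every analysis window is sliced from the
**raw** recording, band-filtered per epoch, and the zero-lag Pearson
correlation is computed for every unordered channel pair; per-epoch
coefficients are averaged (arithmetic mean by default, Fisher-z mean
optionally) into a symmetric region × region matrix with unit diagonal.

Slicing before filtering is a deliberate choice. Filtering the
continuous recording first would let shock artifacts leak into the
guard-trimmed windows through the filter's impulse response; filtering
each window separately guarantees — to machine precision, bit-exact in
the tests — that samples outside the windows cannot influence any matrix
entry. The cost is discarding the guard samples as filter warm-up, which
the 1-s guard (1600 samples, far longer than the biquad transients)
absorbs.

Session dynamics are summarized by the Euclidean dissimilarity between
matrices, computed over the strict upper triangle so each region pair
counts once:

$$d(M_1, M_2) = \sqrt{\sum_{i<j} (M_1[i,j] - M_2[i,j])^2}.$$

The trajectory of dissimilarities from the habituation matrix to each
conditioning-quarter matrix, with an ordinary least-squares trend,
distinguishes a *sustained* network change (elevated values, trend not
returning to zero) from a transient response. The trend's predictor is
the quarter index starting at 0, so the reported intercept is the trend
evaluated at the first quarter — the natural "elevation" quantity.

## Spectra and band powers

Welch spectra use 2-s Hann segments with 50% overlap (0.5 Hz
resolution), averaged over all segments of all epochs of a phase, scaled
as one-sided power density (so the integral recovers the variance). Band
powers are computed after min–max normalization
$(x - \min x)/(\max x - \min x)$ of the per-channel spectrum across the
1–55 Hz bins of one phase; each band is the mean of its normalized bins.
Band edges are delta 1–3, theta 3–8, alpha 8–13, beta 14–30, gamma
30–55 Hz, as half-open intervals; the 13–14 Hz gap is part of the
definition and intentionally preserved. Because normalization is per
channel and per phase, band powers are relative spectral shapes, not
absolute powers — cross-phase comparisons compare shapes.

## Behavior

Freezing is the absence of movement lasting **strictly longer than 1 s**:
a maximal immobility run of exactly 1.0 s does not count (an inclusive
reading is available via `strict = FALSE`). Bouts spanning a bin
boundary are split across bins for per-bin percentages. Outlier
exclusion removes animals whose totals deviate from the group mean by
more than 2 sample standard deviations, computed in a single pass with
the candidate included; a consequence worth knowing is that a single
extreme value among $n$ cannot exceed $(n-1)/\sqrt{n}$ SDs, so exclusion
at $k = 2$ is only possible for $n \ge 6$.

## Statistics

- `pearson()` and `spearman()` return the coefficient with a two-sided
  p-value. Spearman uses midranks under ties; for $n \le 8$ the p-value
  is computed by exhaustive enumeration of all $n!$ permutations (exact),
  otherwise by the t approximation.
- `steiger_z()` compares two dependent correlations sharing one variable
  (e.g. freezing vs. burden in two regions). The default is Steiger's
  $Z_1^*$ with the pooled estimate $\bar r = (r_{12}+r_{13})/2$ in the
  covariance term; Williams' $T_2$ is available as an alternative. The
  pooled-$\bar r$ variant was chosen because it holds its nominal size
  well at the cohort sizes involved — the acceptance suite verifies a
  type-I error within [0.04, 0.06] at $\alpha = 0.05$ under a
  trivariate-normal null with $n = 30$.

## Plaque quantification

Plaques are segmented by Otsu's threshold computed from the intensities
**inside the region mask only** (a global threshold would be biased by
background outside the region), with an optional minimum
connected-component size. Burden is the plaque area as a percentage of
the region area. Otsu on in-region pixels makes the segmentation
invariant to affine intensity rescaling, which the tests assert.

## The synthetic generator and its calibration

Each channel carries unit-variance $1/f$ ("pink") background noise,
synthesized in the frequency domain. During a coupling window, a coupled
channel instead carries

$$x_k = g\,s + \sigma\,n_k,$$

where $s$ is a shared band-limited (theta-carrier) Gaussian source and
$n_k$ independent band-limited noise, both standardized to unit
variance. The zero-lag in-band correlation of an equally mixed pair is
then exactly

$$\rho = \frac{g^2}{g^2 + \sigma^2},$$

giving $\rho \in \{1.0, 0.5, 0.2\}$ for $\sigma \in \{0, 1, 2\}$ at
$g = 1$. This closed form is the generator's calibration: it exercises
the generator, the filter, the epoching and the correlation stage as one
chain, with no tunable constants. The acceptance suite verifies it over
100 seeds.

Cohort specifications build on this: the transgenic-like default couples
AI_L–BLA_R with a habituation gain of 0.3 and per-quarter conditioning
gains (0.5, 0.65, 0.8, 0.9) — an elevated coupling that keeps rising, a
sustained network change by construction. The wild-type-like default
uses equal gains (0.3) in both phases. Per-subject amyloid burden is
drawn uniformly, other regions get attenuated noisy copies of the AI
burden, and the fraction of the conditioning session spent freezing is a
noisy increasing function of AI burden — a monotone link recoverable by
rank correlation. Shock windows receive large deterministic artifacts
(Hann-windowed bursts) strictly inside $[onset, onset + 2\,\mathrm{s})$,
which the guard-trimmed analysis must ignore.

Limits worth stating: the generator makes no claim of physiological
realism beyond spectral shape (pink background, band-limited coupling);
volume conduction, non-stationarity within windows, and cross-frequency
structure are out of scope. Generator defaults are the study conditions
used by the validation suites and were fixed before those suites were
run.

## Problem sizes and runtime

The validation suites run on one CPU: 100-seed coupling calibration
(two-channel, conditioning-only sessions), 100-seed end-to-end cohort
recovery (eight-channel, full 540-s sessions at 1600 Hz), 10,000-rep
test-size calibration, and exhaustive permutation checks up to $n = 6$.
A full eight-channel subject takes a few seconds to generate and analyze;
the compiled biquad kernel is what makes the 100-seed suites feasible.

## Serialization

Recordings round-trip through a samples CSV plus JSON sidecar
(sampling rate, labels, protocol); configurations round-trip through
YAML and carry an MD5 content hash into every result bundle, so any
output directory can be traced to the exact configuration that produced
it.
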