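---
title: "Modeling team neurodynamic information: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling team neurodynamic information: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyn)
```

## The measurement problem

EEG band power fluctuates second to second, but during demanding team tasks
it also shows *persistence*: stretches of tens of seconds in which a
member's power in a given channel and frequency band stays in its high (or
low) range. `neurodyn` measures that persistence as information. The raw
microvolt scale is discarded deliberately: what carries the signal here is
the *organization* of the power levels over time, not their amplitude, and
an information measure over a small symbol alphabet is comparable across
channels, frequencies, headsets and people in a way that raw power is not.

## From voltage to symbols

**Welch PSD on a per-second cadence.** Each epoch (1 s by default) of each
channel is tapered and transformed; density is integrated over 1-Hz bands
(`band power = density × 1 Hz`), giving a `time × channel × bin` tensor.
With the default single 1-s segment, Welch's method degenerates to a
modified periodogram — the appropriate limit when the output cadence equals
the segment length; a 2-s segment stepped 1 s is available when variance
reduction matters more than temporal locality. The taper is Hann by default
(standard leakage control; configurable to Hamming or rectangular). Note
that a Hann taper spreads roughly a third of a pure tone's power into the
two adjacent 1-Hz bins — exact single-bin concentration holds only for the
rectangular taper with tones periodic in the window — which is immaterial
for the symbolization stage, since tertile ranks are computed within each
bin, not across bins. Epochs containing masked samples yield masked PSD
rows that propagate to masked symbols, preserving time alignment rather
than silently shortening the record.

**Equal-occupancy tertiles.** For each (member, channel, bin), the
whole-performance distribution of band power defines two cut points;
bottom/middle/top thirds map to symbols −1 / 1 / 3. Two design points:

* *Cuts are global, never per window.* Windows inherit the
  performance-level cuts; recomputing cuts per window would erase exactly
  the low-frequency persistence the measure is meant to detect.
* *Rank-based assignment with time-stable tie-breaking.* The construction
  requires the three symbols to occupy equal thirds for entropies to be
  comparable; quantile thresholds break down under repeated values, so we
  assign by rank with ties broken by time index, making the counts differ
  pairwise by at most one, *exactly*, for any input. A sequence of all-equal
  values cannot be split into three levels and raises a degenerate-input
  error naming the stream. An exact-tertile reading was chosen over
  mean-±-band cuts because only equal occupancy makes the whole-performance
  numeric mean identically 1.0 and the maximum-entropy bound attainable.

**Team composition.** Member symbols combine lexicographically in declared
member order: `label = 1 + Σ rank(sᵢ)·3^(k−1−i)` with rank −1→0, 1→1, 3→2.
Any fixed bijection onto `1..3^k` would serve; this one is stored on the
stream (`$encoding`) so downstream consumers never have to assume it.
Decoding recovers each member stream exactly, and an epoch masked in any
member is masked in the composite (intersection semantics).

## Information over sliding windows

The plug-in entropy of the window histogram, base 2, gives
`NI = log2(S) − H` — the distance of the observed distribution from maximal
disorder. Defaults follow the canonical analysis: 60-s windows stepped 1 s.
Windows are *trailing* (anchored at their final second), so `NI(t)` is a
causal summary of `(t−60, t]` — the natural convention if traces are ever
to drive near-real-time feedback; centered alignment is available. A window
below the occupancy floor (50% unmasked by default) emits `NA` rather than
an estimate from too few symbols.

**Estimator bias and the randomized baseline.** The plug-in estimator
underestimates entropy, hence overestimates NI, by about
`(S−1)/(2N ln 2)` bits — ~0.10 bits for S = 9 in a 60-s window. We use the
*uncorrected* estimator on purpose: the method's own control is a
randomized baseline (mean NI of uniformly permuted copies of the stream,
6 by default), and subtracting it cancels the bias in expectation while
also inheriting any occupancy imbalance of the actual stream. The
subtraction floors at zero, NI being defined as a positive quantity. The
composite team stream itself is shuffled (the stream being modeled is the
unit of randomization); shuffling members before composition is available
as an option via per-member baselines.

The first-order bias expression is asymptotic in `N/S`. The exact
expectation is available in closed form through
`E[H] = −S·E[(n/N)·log2(n/N)]` with `n ~ Binomial(N, 1/S)`, and the test
suite validates the estimator against this identity over
S ∈ {3, 9, 27} × N ∈ {30, 60, 120}. At small `N/S` (say S = 27, N ≤ 60) the
first-order term understates the true bias by up to ~0.1 bits, so checks
phrased against `(S−1)/(2N ln 2)` fail there not because the estimator is
wrong but because the approximation is; the binomial identity is the
authoritative reference.

**Shared information.** For dyads,
`MI = H(X) + H(Y) − H(X,Y)` per window, with all three entropies computed
over the same unmasked epochs. Since the team capacity is the sum of member
capacities (`log2 9 = 2·log2 3`), the decomposition
`NI_team = NI_X + NI_Y + MI` is an algebraic identity and holds per window
to machine precision — it is tested to 1e−10 on random dyads. Triads are
handled pairwise only; a three-way interaction information is deliberately
out of scope. Member NI is computed on the member streams directly;
marginalizing the team stream gives the same values because decoding is
exact.

**Drill-down aggregation.** `aggregate_ni()` averages traces per time index
across a stratum — whole scalp, one sensor across bins, a scalp region
(default scheme: frontal Fp1/Fp2/F7/F3/Fz/F4/F8, central T3/C3/Cz/C4/T4,
parietal P7/P3/Pz/P4/P8, occipital O1/O2), or one bin across sensors.
Averaging many background streams dilutes a localized episode, which is
precisely why drilling from scalp to sensor to bin concentrates NI; the
pipeline test asserts that ordering on a planted hotspot.

## Power values and their correlation with NI

EEG-PV is the same symbol stream read numerically and moving-averaged over
the NI window: values above 1 mean net activation, below 1 net
deactivation, and a complete stream averages exactly 1.0 by construction.
NI/PV correlation is Pearson (rank correlation available), either one
coefficient over the whole performance or a windowed series. Regional maps
*aggregate then correlate* — the stratum's mean NI trace against its mean
PV trace — rather than averaging stream-level coefficients, because the
scientific question is whether the region's common signal co-varies, and
stream-level r's are noisy and not variance-weighted. Windows in which
either trace is constant have undefined r and are masked, never
zero-filled: zeros would bias maps toward neutrality.

## Peaks: frequency, magnitude, duration

Peaks are local maxima (plateau-aware: a flat top yields its middle sample)
with topographic prominence — height above the higher of the two flanking
minima, computed within the peak's base interval — at or above the
threshold, 0.1 bits by default. Duration is the width where the trace
exceeds `height − prominence/2`, linearly interpolated between samples
(full-prominence width available). Maxima at trace or mask-segment
boundaries have no defined width and are excluded. Baseline-corrected
traces are the intended peak-detection input; raw traces work but their
bias floor inflates prominence. Incidence counts each analyzed second once
even under overlapping peak intervals (union semantics), and reports both
the fraction and the percent explicitly, because a quantity of this kind is
too easily mislabeled between the two conventions.

## The synthetic generator: what it does and does not emulate

`simulate_symbols()` draws baseline symbols i.i.d. uniform over thirds (or
first-order Markov with configurable persistence) and plants non-overlapping
epochs in which a held symbol is emitted with probability `hold_prob`.
Defaults — 0.8 hold probability, 90-s epochs, 60-s windows, 0.1-bit
prominence — describe an episode regime in which organized stretches are
long relative to the window and clearly separated from background, the
regime where incidence estimation is meaningful at all. Member coupling
shares epoch *timing* across members with independent emissions, mimicking
weakly correlated member episodes without imposing synchrony.
`simulate_raw_eeg()` drives band-limited oscillators through three
amplitude levels following the symbol process, plus white noise at a
configurable SNR, to exercise the Welch → symbolize path end to end.

What passing tests on this generator demonstrate: the estimator chain is
correct (oracle equivalence), unbiased after correction (permutation null),
monotone in persistence, and able to recover planted episodes at stated
recall/precision. What they do not demonstrate: performance on real EEG,
which has 1/f spectra, artifacts, volume conduction, non-stationary
occupancy and episode shapes far less clean than a held symbol; none of
these are modeled, by design.

When matching detected peaks to planted epochs, a trailing 60-s window
anchored at `t` reflects symbols in `(t−60, t]`, so an epoch `[a, b]`
influences anchors in `[a, b+59]`; recovery tests match peak intervals
against that influence span rather than the raw epoch span.

## Numerical and validation choices

* Entropy uses `log2(n) − Σc·log2(c)/n` over counts, avoiding `0·log 0`.
* Sliding histograms update incrementally; equivalence with per-window
  recomputation is tested to 1e−12, masks included.
* All randomness flows from explicit seeds; baselines and simulations are
  bit-reproducible, and the pipeline writes its seed and config into a run
  manifest.
* Validation problem sizes: streams of 300–3600 s, oracle fixtures of
  70–200 s, 20-seed recovery ensembles, 150–200 Monte-Carlo windows per
  bias cell — sizes at which Monte-Carlo bands in the tests are meaningful
  while the full suite stays fast.
* Maximum-information capacities print as 4.75 (triad), 3.17 (dyad) and
  1.58 bits (individual) at two decimals; `log2 3 = 1.5849625` is sometimes
  quoted as 1.59 through double rounding.

## Known limitations

* EDF/BDF ingestion is not built in; inputs are delimited numeric tables
  (channels × samples, or long-format PSD/symbol tables).
* The entropy engine is for discrete symbol streams only; no
  continuous-amplitude estimators.
* No transfer entropy, directed information or lagged member coupling.
* Statistical inference (group comparisons, multiplicity control across
  hundreds of streams) is out of scope beyond plain correlation reporting.
* Welch segment length, overlap and taper are explicit configuration; no
  claim is made that any particular setting matches historical analyses
  that did not document theirs.
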