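---
title: "Quantifying genome-embedded ribonucleotides from alkaline-gel densitometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genome-embedded ribonucleotides from alkaline-gel densitometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgelquant)
```

## The measurement

Ribonucleoside monophosphates (rNMPs) embedded in genomic DNA are the most
common non-canonical nucleotides in replicating cells.  Hot alkali cleaves
the DNA backbone at every embedded rNMP, so denaturing (alkaline) gel
electrophoresis of alkali-treated total DNA converts the *density* of
rNMPs into a *size distribution* of single-stranded fragments: the more
rNMPs per genome, the shorter the fragments.  A stained gel lane is scanned
into a one-dimensional densitometry profile — intensity (proportional to
DNA mass, not molecule count) versus migration distance — and the task of
this package is to invert that profile into the number of rNMPs per
genome.

`rnmp_fit()` performs the whole inversion for one lane; the steps below
are also exposed individually.

## Model and procedure

**Mobility calibration.**  Electrophoretic distance is log-linear in
fragment size over the resolving range of the gel.  The model is fitted by
ordinary least squares of distance on log size, `lm(d ~ log(sz))`, using
the detected peaks of a ladder lane (`fit_ladder()`), and inverted
analytically: `sz = exp((d - a)/b)`.  The regression direction matters
under noise — distance is the measured quantity — so the fit is done
exactly that way and never reversed.  The default band list is the 1 kb
Plus ladder; a size-range filter is available because bands outside the
resolving range curve away from log-linearity.

**Densitometry conditioning.**  The raw lane is background-subtracted
(constant, linear-envelope, or empty-lane estimate), then smoothed with a
penalized cubic spline with 15 interior knots, and resampled into
intervals of width $\Delta d = 1$ mm.  Each interval carries its
integrated intensity $I_{sz}$ (AU·mm) and the characteristic size $sz$ of
its midpoint.

**Counts and normalization.**  Staining intensity measures mass, so the
molar fragment count of an interval is $n_{sz} = I_{sz}/sz$.  Counts are
made loading-independent by rescaling to a fixed amount of DNA:
$n_{sz}(\mathrm{per\,1Gb}) = n_{sz} \times 10^9 / \sum sz\, n_{sz}$, the
sum running over all included intervals.  After this step
$\sum sz\, n_{sz}(\mathrm{per\,1Gb}) = 10^9$ exactly — a mass-conservation
invariant the tests assert — and every downstream quantity is invariant
under rescaling the lane intensities.

**Totals and truncation correction.**  The preliminary rNMP count per
genome is $N = \sum n_{sz}(\mathrm{per\,1Gb}) \times G / 10^9$ with
$G = 24$ Mb for haploid yeast.  Fragments smaller than the minimum
detectable size $sz_{min} = \exp((d_{max}-a)/b)$ migrate beyond the
signal-to-noise cutoff and are censored.  Under uniform break placement
the censored fraction follows from the exponential spacing distribution,
giving
$N_{corr} = N \times (2 - \exp\{-sz_{min} \sum n_{sz}(\mathrm{per\,1Gb})/10^9\})$.
The correction factor is bounded by 2; for clustered (non-uniform) breaks
it undercorrects, so the estimate is conservative — a property the test
suite checks by simulation.

**Control subtraction.**  Alkaline heat treatment breaks DNA at some rate
even without rNMPs.  That background is measured in a matched control lane
quantified the same way and subtracted: $N_{net} = \max(0, N_{corr} -
N_{corr}^{ctrl})$.  Subtraction of corrected totals is the default; the
alternative order (difference the preliminary totals, then apply the
sample's correction factor) is available, since the order is a genuine
modelling choice and the two differ when the lanes' cutoffs differ.

**Densities and comparisons.**  Totals are reported per Gb of DNA
($N \times 10^9/G$), rounded to the nearest 1000 only for display.
`bin_distribution()` sums per-Gb counts into half-open 50-nt bins and
normalizes to 1; `restrict_common_support()` truncates a set of
distributions to bins above the largest $sz_{min}$ among them before
renormalizing, so gels with different cutoffs are compared on common
support.  `lane_fraction_profile()` normalizes a profile to its within-lane
sum for strand-specific hybridization comparisons.

**Polymerase contributions.**  Given the rNMP totals of an
RNase-H2-null strain with wild-type polymerases ($N_{base}$) and of the
matching strains carrying an rNTP-permissive steric-gate variant of Pol
α, δ or ε, the share of genome synthesis of each polymerase is
$$100 \times \frac{\Delta N_x / F_x}{\sum_j \Delta N_j / F_j}, \qquad
\Delta N_x = N_x - N_{base},$$
where $F_x$ is the variant's in vitro rNMP incorporation frequency
(1/40 for α-L868M, 1/300 for δ-L612M, 1/100 for ε-M644G).  Dividing by
$F$ converts excess rNMP load into nucleotides synthesized; note that the
*least* permissive variant (δ-L612M) therefore receives the largest
weight per observed rNMP.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `delta_d` | 1 | mm | resampling interval width; halving it changes totals by well under 1% on smooth lanes |
| `n_knots` | 15 | — | interior knots of the smoothing spline |
| `window` | 3 | mm | detrending bandwidth of the cutoff rule |
| `ratio_threshold` | 1.5 | — | lane/empty fluctuation ratio defining `d_max` |
| `d_max` | automatic | mm | manual cutoff override (supervised use) |
| `genome_size` | 24e6 | nt | haploid genome length |
| `bin_width` | 50 | nt | size-distribution bin width |

## Design choices where the procedure was open

**Knot placement.**  "Optimally placed" free knots (as in interactive
spline tools) are not deterministic.  The package instead fixes 15
interior knots at quantiles of a blended measure — two thirds cumulative
absolute intensity gradient, one third uniform — so flexibility
concentrates where the lane changes fast while long low-signal stretches
always keep coverage (an unconstrained cubic tail next to a tall band
oscillates badly).  Generalized cross-validation chooses the roughness
penalty.  This is reproducible, and
accuracy is judged by integral fidelity (asserted to 3% on noisy
renders), not by knot positions.  Uniform placement is available.

**Cutoff automation.**  In practice `d_max` is chosen under supervision.
The automatic surrogate compares the fluctuation magnitude of the raw
lane with that of an empty lane: both are detrended with a running
median, and `d_max` is the first distance beyond which the standard
deviation of *all remaining* lane samples falls below `ratio_threshold`
times that of the empty lane.  A cumulative tail statistic is used rather
than a single rolling window because a windowed SD deep in the noise
region has high variance, and one spurious window would otherwise defer
the cutoff to the lane end, flooding the estimate with noise counts at
tiny fragment sizes.  When the ratio never crosses the threshold the
cutoff is placed at the lane end and a warning recorded.  The tail
statistic still contains the decaying signal's own fluctuations, so the
automatic `d_max` sits slightly above the last visible signal; the
truncation correction absorbs most of the difference, leaving the total
mildly conservative.

**Interval intensities** are integrals (AU·mm), not point samples; with
fixed `delta_d` the two differ by a constant that cancels in the per-Gb
normalization.  Negative values are clipped to zero after background
subtraction and after smoothing, because mass cannot be negative.

**Bin edges** are half-open `[k*50, (k+1)*50)`, and a bin is reported
only when its lower edge clears `sz_min` — the conservative reading of
restricting comparisons to sizes above the cutoff.

**Subtraction order** defaults to correct-then-subtract, because the
background breakage of the control lane is itself size-censored by the
same gel physics and should receive its own truncation correction.

## The synthetic-gel generator

Simulation is the only way to validate the inversion, because the
ground-truth break count of a real gel is unknowable.
`simulate_fragments()` places break points on a 24 Mb single-stranded
genome — uniformly, or clustered into hotspots for robustness checks —
together with molecule ends, and returns fragment sizes that partition
the genome exactly.  Molecule ends are placed uniformly at random,
emulating the random shearing of extraction;
the number of starting molecules is a free parameter because the true
degree of shearing in a preparation is not known.  `render_lane()` is the
forward model the pipeline inverts: band centers at $a + b\ln(sz)$,
Gaussian band broadening, staining mass proportional to fragment size, a
compression zone near the well for fragments beyond the resolving range,
a polynomial background, and detector noise with an additive and a
signal-proportional-variance component.  The signal-dependent component
matters: real scanned gels show fluctuations that grow with signal, and
the automatic cutoff rule is meaningful only under that structure.

Default study conditions used in the tests: DNA sheared to about 50 kb
(480 molecules per genome), 500 rNMP-independent background breaks in
sample and control alike, band SD 0.5 mm, constant background at 1% of
the peak signal, and peak signal-to-noise 25.  End-to-end parameter
recovery is exercised at 2,000, 8,403 and 20,136 breaks per genome and
asserted to ±10%; truncation-correction conservativeness is averaged
over 20 seeds of clustered breakage (90% of breaks in 1% of the genome).

The generator does **not** emulate two-dimensional gel artifacts
(smiling, lane warping), stain saturation, partial alkaline cleavage, or
sequence context of incorporation.  Passing tests therefore demonstrate
the correctness and stability of the *inversion* under the stated noise
model, not the accuracy of any wet-lab protocol; absolute totals from
real gels remain conditional on densitometry quality and on the
supervised cutoff.

## Degenerate inputs and numerical tolerances

Profiles must be strictly increasing in distance with finite intensities;
duplicate distances are rejected at parse time with the line number.
Ladder fits require at least two distinct sizes, error on zero-variance
profiles, and report unmatched expected bands rather than dropping them.
Zero-mass lanes cannot be normalized and raise errors, as do requests to
bin an empty table.  An unreachable cutoff threshold excludes nothing
(lane-end `d_max`); identical lane and empty profiles exclude
everything.  All randomness flows from explicit integer seeds through a
restored-on-exit RNG state, so every simulation is reproducible and no
global state leaks.

## Known limitations

* The estimate near the cutoff depends on the truncation model; when a
  large share of fragments lies below `sz_min` (heavy clustering, very
  high break loads) the correction is deliberately conservative.
* Fragments larger than the resolving range are piled into the
  compression zone and counted at the apparent compression-zone size;
  control-lane subtraction cancels most of this when sample and control
  share the shearing and background-break structure.
* Uncertainty is reported only as across-replicate SEM in the batch
  summary; no per-lane error model is propagated.
* Densitometry extraction from gel images (lane finding, 2-D
  segmentation) is upstream of this package.
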