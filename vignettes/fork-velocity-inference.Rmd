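---
title: "Inferring replication fork velocity from gene-dosage profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring replication fork velocity from gene-dosage profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replifork)
```

## The steady-state dosage model

In an exponentially growing bacterial population, loci near the replication
origin are present in more copies than loci near the terminus, because at any
instant a fraction of cells has already replicated them. `replifork` turns
this *gene dosage* (marker frequency) gradient into a position-resolved
estimate of replication fork velocity.

Let the population grow with mass doubling time $T$ (so cell number
$N(t) \propto 2^{t/T}$), and let $v(x)$ be the fork velocity at replichore
distance $x$ from *oriC*. If the population is in steady state, the shape of
the dosage profile is time-invariant: the total copy number of every locus
grows at the same exponential rate as the population, and the expected
per-cell dosage of a locus depends only on the time a fork needs to reach
it,

$$ t(x) = \int_0^x \frac{\mathrm{d}s}{v(s)}, \qquad
   g(x) \;=\; \log_2 f(x) \;=\; g(0) - \frac{t(x)}{T}. $$

The log2 dosage therefore declines *linearly* with $x$ wherever $v$ is
constant, with slope

$$ a \;=\; \frac{1}{v\,T} \quad (\text{per Mbp}), $$

and the inference is: fit a piecewise-linear function to the log2 track,
then invert each segment's slope, $v = 1/(aT)$. A segment where replication
is impeded (e.g. by head-on transcription of an rRNA operon) shows up as a
locally steeper slope; a comparison of two segments' speeds reduces to a
slope ratio, $100\,(1 - a_\mathrm{ref}/a_\mathrm{test})\,\%$, in which both
the arbitrary intercept and $T$ cancel.

The same closed form underlies the synthetic generator
(`expected_async_profile()`), which is also available as an explicit
single-cell simulation (`mode = "cell_sampling"`): cells carry initiation
events at $(\varphi + j)T$ minutes in the past, $j = 0, 1, 2, \dots$, with
$\varphi$ drawn from the exponential-phase density
$2\ln 2 \cdot 2^{-\varphi}$ on $[0,1)$, and a locus's copy number relative
to *oriC* is $2^{-m}$ with $m$ the number of initiations whose fork has not
yet passed it. The population mean of $2^{-m}$ recovers $2^{-t(x)/T}$
exactly, which the test suite verifies by Monte Carlo; the agreement is what
licenses using the cheap closed form everywhere else. Division bookkeeping
(the D period) is deliberately omitted: the steady-state *ratio* profile is
independent of it.

## Coordinates and rearranged chromosomes

All arithmetic is 0-based bp with half-open intervals; degrees
(360° = genome length, *oriC* at 0°) are provided for display and exchange
(`bp_to_degrees()`, `degrees_to_bp()`). The right replichore is the
clockwise arc *oriC* → *terC*; replichore distance is the fork's path
length, and origin-centered plots use $+$/$-$ signed distance for the
right/left arm.

Engineered chromosomes are described by an ordered rearrangement list.
An inversion $[s, e)$ maps $x \mapsto s + e - 1 - x$ inside the interval
(an involution); a deletion shifts downstream coordinates and makes deleted
positions an error. `bsub_genome_map()` ships the geometries used in the
worked analyses: wild type, the strain with the *oriC*-proximal quarter of
the chromosome inverted (head-on transcription, "HT"), the strain with
*oriC* relocated to 94° (unequal replichores, "UR"), the mirror-image
left-replichore inversion, and the local rrnIHG-cluster inversion. For the
left-replichore variant no exact endpoints are published, so the package
declares the symmetric convention $[266°, 360°)$ — the *oriC*-proximal half
of the left arm.

## Fitting segments and locating slope breaks

`fit_segments()` maps probes to replichore coordinates and fits each
boundary-delimited segment. The default is *independent* per-segment OLS —
matching the convention in which each published segment carries its own
standard error — with slopes reported as positive declines per Mbp. A
*continuous* mode (a linear spline in hinge basis, forcing segments to meet
at the boundaries) is provided because the underlying model is a connected
piecewise-linear function; on continuous truth the two agree, and the test
suite exercises both. Segments need at least 10 probes; a zero-extent
segment is an error, and a flat profile legitimately fits slope 0 (velocity
is then undefined — `velocity_from_slope()` refuses non-positive slopes).
The slope SE propagates to the velocity by the delta method,
$\mathrm{se}_v = v\,\mathrm{se}_a/a$.

`detect_changepoints()` automates what was historically read off the plot by
eye: it minimizes, by optimal-partitioning dynamic programming, the total
RSS of independent straight-line fits plus a penalty per segment, with at
least 50 probes per segment and a BIC-flavored default penalty
$4\hat\sigma^2\log n$ ($\hat\sigma$ from the robust first-difference MAD;
two parameters per segment). Ties break toward fewer segments. Two
numerical facts are worth knowing. First, on noiseless tracks the search
recovers breakpoints exactly. Second, breakpoint *localization* under noise
is information-limited: misplacing a slope-only break by $\delta$ costs
RSS of order $\Delta a^2 \delta^3 / (3h)$ ($h$ = probe spacing), so the
typical error scales as $(3h\sigma^2/\Delta a^2)^{1/3}$ — roughly 50 kb for
a 0.24-per-Mbp slope contrast at 0.05 noise and 1 kb spacing. Sharper
contrasts (the ~3-fold slope jump at a stalled rRNA segment) localize
proportionally better. The tests assert accuracy at this computed scale,
not beyond it.

`stall_segments()` operationalizes "strongly impeded": a segment is flagged
when its slope exceeds `fold_threshold` (default 2) times the median slope
of the other segments on its replichore.

## Synchronized-release profiles

After a synchronized release in which a fraction $f$ of cells initiates,
the dosage ratio against a pre-initiation reference is a two-plateau step
per arm: $1 + f$ behind the fork front, 1 beyond it. The package estimates

* $f$ from medians: plateau over an *oriC*-proximal region, baseline over a
  distal region (defaults: first/last 10% of the arm's probes, configurable
  because interior stalls can distort the shape), then
  $\hat f = 2^{\text{plateau} - \text{baseline}} - 1$, clipped to $[0,1]$.
  The estimate is invariant to the track's intercept.
* the fork front as the *transition midpoint*: the first position, moving
  away from *oriC*, where the smoothed track crosses
  $(\text{plateau}+\text{baseline})/2$, linearly interpolated between the
  flanking probes. The halfway level is defined in log2 space (consistent
  with the plotted tracks); a linear-space option exists and differs
  negligibly at small $f$. The first-crossing rule resolves noise wiggles;
  smoothing uses the same 200-probe rolling mean as the plotted data, and
  on noiseless ramps the midpoint bias is below half the window's bp span.

Time-varying fork speeds (e.g. rifampicin added 4 minutes after release)
are modeled by a `velocity_schedule()` — contiguous time phases, each with
its own velocity field — and `predicted_fork_position()` integrates the
schedule for direct comparison with the estimated front.

## Fluctuation tests, growth and fitness

`simulate_fluctuation_assay()` is a discrete-generation Luria–Delbrück
sampler: mutations arise as Poisson events proportional to the cells added
per generation and found clones of final size $2^{g-k}$. Generations are
spaced at exact fractional positions ($N_k = \min(N_0 2^k, N_t)$) so the
zero-mutant probability is exactly $e^{-\mu(N_t - N_0)}$ — the quantity the
P0 method inverts. `p0_mutation_rate()` implements that method and nothing
more (the maximum-likelihood estimators are out of scope): $\hat P_0$ =
fraction of zero-mutant cultures, $m = -\ln \hat P_0$, rate $= m/N_t$, with
a Wilson binomial interval on $P_0$ transformed through $-\ln(\cdot)/N_t$.
The $N_t$ denominator follows the method's convention; $N_t - N_0$ is an
option and the difference is negligible when $N_t \gg N_0$. All-zero
assays return rate 0 with a one-sided upper bound; no-zero assays are a
hard error (the method needs $P_0 > 0$). Because no significance procedure
is published for rate contrasts, `rate_ratio()` uses a percentile bootstrap
on the zero counts, with boundary resamples pulled half a culture inward.

Growth rates come from OLS of $\ln(\mathrm{OD}_{600})$ on time
(`doubling_time_from_od()`, $T = \ln 2/\text{slope}$, delta-method SE).
The multiplicative fitness null combines two perturbations by multiplying
growth-rate ratios, `multiplicative_expected_doubling()`:
$T_{AB} = T_A T_B / T_\mathrm{control}$. Competitions are summarized by the
standard ratio of realized Malthusian parameters,
$W = \ln(A_f/A_0)/\ln(B_f/B_0)$, optionally divided by a neutral-marker
control fitness; `simulate_competition()` generates count tables with
mean-one lognormal count noise of chosen CV.

## What the generator does and does not emulate

The synthetic profiles reproduce the features the estimators rely on:
piecewise-constant velocity fields (including the published per-segment
slope structure via `ht_velocity_profile()`), steady-state log2 linearity,
partial-initiation plateaus, moving fronts under velocity schedules,
Gaussian probe noise (default sd 0.05 log2 units, aCGH-like), jackpot-
skewed mutant counts, and lognormal count noise. They do *not* emulate
probe-specific hybridization biases, spatially correlated noise, the
baseline elevation caused by an incompletely replicated reference sample,
prophage-related copy-number blips, or smooth (non-piecewise) velocity
variation. Passing the recovery tests therefore shows the estimators are
correct and well-calibrated under the declared noise model — not that real
arrays are free of artifacts the model excludes.

Default study conditions used throughout the tests and the reproduction
script: 1 kb probe spacing (2000 probes on a 2 Mbp arm), probe noise 0.02
(asynchronous slope recovery) or 0.1 with a 200-probe window (synchronized
profiles), 10–20 seeds per Monte-Carlo average, 50-culture fluctuation
assays with $N_t = 2\times10^8$, and 10-doubling competitions with 2% count
noise — sizes chosen to mirror the scale of the original experiments while
keeping every check fast enough to run routinely.

## Known limitations

* Velocity is assumed piecewise-constant between supplied or detected
  boundaries; genuinely gradual velocity changes are approximated by steps.
* The steady-state model excludes the synchronized protocol by design; the
  two analyses meet only through the velocity schedule.
* Changepoint localization is bounded by the information limit described
  above; boundaries known from annotation (rRNA positions) should be passed
  to `fit_segments()` directly rather than re-estimated.
* The P0 method discards the information in non-zero counts; its precision
  degrades when $P_0$ is near 0 or 1, which the interval makes visible.
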