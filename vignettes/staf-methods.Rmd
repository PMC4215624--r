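---
title: "Estimating spatio-temporal action fields with m-sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spatio-temporal action fields with m-sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stafkit)
```

## The problem and the model

A fly tracking a visual figure steers using (at least) two parallel
streams of information: the first-order *elementary motion* (EM) of the
luminance texture inside the figure, detectable by correlation-type
motion detectors, and the *figure motion* (FM) of the window itself,
defined by higher-order spatio-temporal disparities and present even
when the interior contains no coherent motion at all. The gain and
dynamics of both streams change with where the figure sits in the
visual field, so neither is summarized by a single impulse response.

The central representation in this package is the **spatio-temporal
action field (STAF)**: a grid $G(t, \gamma)$ of temporal kernel values
indexed by lag $t$ and figure azimuth $\gamma$, with $\gamma = 0$ at
front center and positive to the animal's right. Over a narrow range of
positions the steering behavior is treated as quasi-linear, and the
steering effort $y(t)$ (difference in wingbeat amplitudes,
$\Delta WBA$) produced by per-frame position steps
$\Delta_{FM}(\tau)$ of the figure and $\Delta_{EM}(\tau)$ of its
interior texture is modelled as the discrete superposition

$$
y(t) \;=\; \sum_{\tau \le t}
  \Big[ G_{FM}(t-\tau, \gamma(\tau))\,\Delta_{FM}(\tau)
      + G_{EM}(t-\tau, \gamma(\tau))\,\Delta_{EM}(\tau) \Big]
  \;+\; \sum_{\theta = 0}^{\gamma(0)} G_{FM}(t, \theta)\,\Delta_F(\theta),
$$

where the trailing sum is the *initial-position term*: the FM stream
responds to figure position, so a trial that starts with the figure
away from front center behaves as if the figure had stepped there
pixel by pixel at $t = 0$. The term vanishes for trajectories starting
at front center, and for a figure parked at azimuth $\gamma$ the model
predicts an asymptotic effort equal to the azimuthal cumulative sum of
the FM asymptote from $0$ to $\gamma$. The two kernels have
qualitatively different shapes: $G_{EM}$ is an impulse response (fast
rise, decay to zero), $G_{FM}$ an *incremental step response* that can
hold a nonzero value for many seconds.

## The m-sequence protocol

Kernels are estimated by reverse correlation against maximal-length
shift-register sequences (m-sequences): $\pm 1$ drives of period
$p = 2^n - 1$ whose circular autocorrelation is $p$ at lag zero and
exactly $-1$ elsewhere. `m_sequence()` implements a Fibonacci LFSR
(taps given as polynomial exponents, output from the last stage, bit
1 mapped to $+1$), and validates primitivity empirically: if the
register does not return to its seed after exactly $p$ steps the
polynomial is rejected by name. The built-in table
(`primitive_taps()`) carries all 18 degree-7 primitive polynomials and
a few per degree otherwise, so distinct-sequence pairs never require a
search. Sequence order trades spatial against temporal resolution: the
drive must stay short enough that the figure remains roughly localized
within one period. For order 7 the within-period standard deviation of
the cumulative one-pixel-step trajectory about its mean is a little
over 3 pixels (about 12 degrees) for every built-in polynomial, and
each period ends with the figure displaced exactly one pixel (the
sequence sum is $\pm 1$).

One protocol run (`build_compound_protocol()`) steps the figure window
by one m-sequence, $m_{FM}$, and the interior texture by a second,
*distinct* sequence, $m_{EM}$, on a 96-pixel, 3.75-degrees-per-pixel
panoramic ring. Each start azimuth is run as a *pair*: once with
$(m_{FM}, +m_{EM})$ and once with $(m_{FM}, -m_{EM})$. Two rendering
hygiene measures are applied by `render_frames()`: on every
syndirectional step both boundary columns of the window are redrawn at
random (otherwise syndirectional steps would drive coherent motion
across more pixel boundaries than antidirectional ones, leaking figure
motion into the EM estimate), and the random background is replaced at
the start of every third period to limit chance figure-ground
correlations.

## Estimation and the dc error

With the sign-flipped pair $y_1, y_2$ in hand
(`estimate_em_kernel()`, `estimate_fm_kernel()`):

* **EM kernel.** $u_{EM} = \tfrac12\,[\,m_{EM} \star y_1 - m_{EM}
  \star y_2\,] / (p+1)$. The FM-driven response — including its slowly
  accumulating position component — is identical in the two runs and
  cancels in the difference, as does the finite $m_{FM} \times m_{EM}$
  cross-correlation. What remains is $g_{EM}(k) - \sum_j g_{EM}(j)/(p+1)$,
  i.e. the kernel up to the usual small m-sequence dc offset;
  `em_dc_correct = TRUE` inverts even that exactly
  ($g = u + \sum_k u(k)$).

* **FM kernel.** Because $g_{FM}$ does not die out within a period, the
  traces are first differentiated, so the quantity being estimated
  ($dg_{FM}/dt$) does have compact support. The differentiated traces
  are cross-correlated with $m_{FM}$ — *summing* the pair, so the EM
  components cancel — and integrated back. Integration turns the
  m-sequence dc error into a ramp that nearly cancels the kernel by lag
  $p-1$; with the $(p+1)$ normalization the cumulative sum obeys
  exactly $c(k) = g(k) - (k+1)A/(p+1)$, where $A$ is the kernel
  asymptote. Since the step response has saturated well before the 2–5 s
  window (default `dc_window`), $A$ is recovered in closed form from the
  window mean, $A = \overline{c}_W / (1 - (\bar k + 1)/(p+1))$, and
  added back along the ramp. The *literal* reading — add the window
  mean, divided by the period, to $u_{FM}$ before integrating — is kept
  as `dc_method = "literal"`; it under-corrects, because the window
  mean of $c$ itself still carries the error slope, and the package
  defaults to the self-consistent closed form (validated by parameter
  recovery in the test suite).

One implementation detail matters here: the derivative is taken on the
*continuous* record before period-folding, not circularly within the
folded period. Each period leaves the figure one pixel displaced, so
the FM position response drifts by one asymptote-unit per period; a
circular within-period difference would convert that drift into a
spurious impulse at the wrap sample (about 10% of peak in noiseless
recovery), while the plain first difference of the record is exactly
periodic in steady state. Handed a single isolated period, the
estimator falls back to the circular difference.

Kernels are estimated per run, attributed to the circular mean figure
azimuth over the analyzed frames, repeat-averaged per position, and
concatenated along azimuth (`assemble_staf()`), then smoothed with a
circular four-pixel boxcar applied to every time slice (unit-sum, so
azimuthal means are preserved). `staf_fit()` orchestrates the whole
protocol and returns a classed object with `predict`, `coef`,
`summary` and `plot` methods; a sliding-window mode segments one long
continuous paired record into single-period windows instead, rotating
the reference sequences by each window's phase offset.

## The synthetic plant

No animal data ships with the package; every stage is validated
against `plant_model()`, a quasi-linear two-stream simulator built
from `make_ground_truth_stafs()`. Its fixture parameters mimic the
qualitative shapes reported for tethered flight and are *choices, not
measurements*:

| parameter | default | meaning |
|---|---|---|
| EM time course | alpha function, 40 ms delay, 100 ms constant | impulse-like, zero asymptote |
| EM envelope | frontal Gaussian, 60 deg half-width, peak 1 | strongest at front center |
| FM time course | smoothstep, 200 ms delay, saturates at 2 s | persistent incremental step response |
| FM envelope | difference of Gaussians, 50/130 deg, zero azimuthal sum | positive center, inverted surround |
| noise | additive white Gaussian, SD 0.5 | see below |

The FM smoothstep reaches its asymptote *exactly* at 2 s, and the EM
alpha function is numerically zero well before 5 s, so kernel
increments have support shorter than one 127-frame period at the
default 25 Hz frame rate (the update rate is a configuration choice;
25 Hz makes one period 5.08 s, compatible with the 2–5 s dc window).
Consequently the response is in exact steady state from the second
period onward, which is why the default protocol simulates two periods
and discards the first: noiseless estimation then inverts simulation
to float tolerance, a property the tests assert directly.

The noise level is set so that single-run FM kernels are visibly noisy
(long-lag error around half the peak, since integration accumulates
noise as a random walk) while 20-repeat averages are clean (about 10%);
that ratio is what exercises the repeat-averaging logic. The plant can
also apply a slow sinusoidal baseline drift and a static output
nonlinearity, both off by default.

What the plant does *not* emulate: closed-loop behavior, trial-to-trial
gain fluctuations, temporally correlated (1/f) noise, saccadic steering
events, and any genuine nonlinearity of motion detection. Passing the
recovery tests therefore demonstrates that the estimator inverts the
model it assumes — not that real behavior satisfies that model;
on animal data the same pipeline would inherit the quasi-linearity and
superposition assumptions discussed above.

## Numerical choices and degenerate inputs

* Cross-correlation divisor $(p+1)$, so a plant echoing its input with
  unit gain yields a unit-peak kernel; `normalization = "p"` is
  available.
* Azimuth stored in $(-180, 180]$; all lookups interpolate linearly
  with circular wrap; kernel lags beyond the stored time axis hold the
  terminal value (zero for EM, the asymptote for FM), and negative lags
  are zero.
* Forward simulation groups steps by the (pixel-grid) azimuth at which
  they occur and runs one FFT convolution per distinct azimuth, which
  is exact and keeps the full protocol around a few seconds.
* The initial-position term walks one-pixel increments along the
  shorter arc from front center, signed like the start azimuth.
* Degenerate inputs fail loudly: identical figure/texture sequences,
  non-primitive polynomials (named in the error), zero register seeds,
  mismatched trace lengths, dc windows outside the period, constant
  traces handed to `r_squared()`, traces with missing samples. Step
  magnitudes beyond the one-pixel calibration step *warn* rather than
  fail, since this is a validity caveat of the quasi-linear domain, not
  an arithmetic error.
* All randomness (texture draws, plant noise, protocol simulation) is
  scoped: seeded calls restore the caller's RNG state, and a `staf_fit`
  under a fixed seed is bit-reproducible.

## Statistical comparison of STAF populations

`paired_t_map()` computes per-pixel paired two-tailed t statistics
across individuals (df $= n-1$, no pooling across pixels), and
`bh_fdr()` applies the Benjamini–Hochberg step-up rule, appropriate
here because neighboring STAF pixels are strongly positively
correlated. STAF populations are very low-dimensional —
`staf_population_svd()` exposes this; members are not mean-centered by
default, so the leading fraction describes the fields themselves
(a `center = TRUE` option gives the PCA-style alternative; the two
differ and the default is the one matching "fraction of population
variance captured by one component" for near-proportional members).
The package applies standard BH over all pixels and reports
dimensionality separately rather than folding it into an adjusted test
count, for which no principled formula is available.

## Problem sizes used in the shipped analyses

The default study conditions — and the ones the acceptance script and
test suite run — are: order-7 sequences (127 frames per period) at
25 Hz, start azimuths every 4 pixels (15 degrees, 24 positions), paired
sign-flip runs, 2 periods per run with the first discarded, 20 repeats
per position, noise SD 0.5, four-pixel boxcar. This is a complete
in-silico replica of the protocol at a scale a laptop fits in seconds;
the estimator itself is indifferent to denser azimuth grids or more
repeats.

## Known limitations

* The FM dc correction presumes the step response has truly saturated
  inside the dc window; kernels with slower dynamics than ~2 s would
  bias the asymptote estimate.
* A kernel estimated over one period attributes to the mean azimuth a
  response that actually mixes positions across the excursion, weighted
  by step occurrence; where the spatial envelope is steep this
  linearization error reaches a few percent of peak (the end-to-end
  recovery test bounds it at 15%).
* The initial-position term treats FM position increments as
  path-independent, as the model equation is written.
* Frequency-domain views (`staf_transfer_function()`) are descriptive
  only; the kernels are valid near the calibration step size and update
  rate and do not extrapolate to arbitrary speeds.
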