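---
title: "Dynamic neural resource modelling of visual working memory: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic neural resource modelling of visual working memory: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`dynres` implements a dynamic neural resource account of continuous-report
visual working memory. A reported orientation is modelled as the
maximum-likelihood decode of Poisson spiking in an idealized population of
orientation-tuned neurons, whose *gain* (expected activity) at the moment of
decoding is set by deterministic sensory and memory dynamics, while the
*value* it encodes has been perturbed by diffusion and, on some trials,
replaced by a non-target (a swap). Orientation is 180°-periodic; all
internal circular mathematics uses doubled angles on $[-\pi, \pi)$.

### Population code

Neuron $i$ of $n$ (default 100, with evenly spaced preferred values
$\varphi_i$) responds to a feature $\theta$ at gain $\gamma$ with mean rate

$$f_i(\theta,\gamma) = \frac{\gamma}{n}
  \exp\{\kappa(\cos(\theta-\varphi_i)-1)\},$$

spike counts are independently Poisson, and the decode is the likelihood
maximizer, which for an even population equals the direction of the
spike-weighted resultant vector. The expected total spike count is
$\gamma\,e^{-\kappa}I_0(\kappa)$; a zero-spike trial carries a flat
likelihood and is resolved as a uniform guess. Decode precision at high
gain attains the Cramér–Rao bound $1/I(\theta)$, which the acceptance suite
verifies against numerically differentiated tuning curves. Results are
insensitive to $n$ for $n \gtrsim 50$; $n$ is exposed in `pop_config()`.

### Signal dynamics

The sensory population low-pass filters the stimulus: amplitude rises as
$1 - e^{-t/\tau_{rise}}$ during the exposure and decays as
$e^{-(t-t_{offset})/\tau_{decay}}$ afterwards (a backward mask shortens the
fitted decay; the mask-terminated variant zeroes it). Working memory
accumulates this input under divisive normalization,

$$\dot\gamma_{wm}(t) = \gamma_s(t)\,
  \bigl(\check\gamma_{wm}/M(t) - \gamma_{wm}(t)\bigr)/\tau_{wm},$$

where $M(t)$ is the number of items still competing for the resource: all
$N$ until the cued item is identified at
$t^*_{cue} = t_{cue} + b\log_2 N$ (Hick's law), one afterwards. The cue
therefore lifts the normalization ceiling and lets the residual sensory
trace top up the cued item's representation — the mechanism behind the
early-cue benefit and its absence at $N = 1$. The decode gain uses the
asymptotic post-cue limit $\gamma^*_{wm} = \gamma_{wm}(\infty)$, exact
because the equation is linear with an integrating factor built from the
closed-form sensory integral; `vwm_gain_trace()` exposes the full trace and
is tested to $10^{-6}$ relative error against adaptive `deSolve`
integration. The sensory amplitude scale is fixed at 1: only
$\gamma_s/\tau_{wm}$ enters the accumulation equation, so a free scale
would be degenerate with $\tau_{wm}$.

Two design conventions follow the fixed-exposure (200 ms) task: encoding is
assumed complete at stimulus offset
($\gamma_{wm}(t_{offset}) = \check\gamma_{wm}/N$), and a simultaneous cue
yields the full amplitude $\check\gamma_{wm}$ with no diffusion or swaps
(a perceptual report). The boundary instant $t = t^*_{cue}$ belongs to the
pre-cue regime (a measure-zero choice).

### Noise and swaps

The stored value diffuses as Brownian motion from stimulus offset,
evaluated once at $t^*_{cue}$ (diffusion is slow relative to sensory decay,
so drift during the brief post-cue accumulation is neglected); negative
elapsed times clamp to zero variance. Rates are in doubled rad²/s; divide
by 4 and scale by $(180/\pi)^2$ for orientation deg²/s. Swaps follow the
spatial-uncertainty law

$$p_{swap} = (N-1)\left[(1/N - q)e^{-t_{offset}/\tau_{spatial}} +
  q\right],$$

with the bracket floored at 0 and the result clipped to $[0,1]$. The
fixed-exposure design never varies exposure, so its fits use a constant
total swap probability instead. In the masked design the cue delay is also
fixed, so the retention term is folded into a single fitted scalar; this
package takes $q = p/(N-1)$, making the fitted $p$ the *asymptotic total*
swap probability at long exposures for every set size. The alternative
reading ($q = p$) implies ~48% swaps at $N = 10$, which we judged
behaviourally implausible; this is a package choice where the
parameterization was genuinely open.

### Model variants

`dynr_variants()` enumerates ten architectures: the full model; fixed
signal (no post-offset sensory input) with constant or set-size-scaled
diffusion; no diffusion; scaled diffusion; direct sensory read-out (decode
the *sum* of memory and sensory activity at $t^*_{cue}$, with the sensory
population expressed on the memory spike-count scale — the natural
completion of the summation idea once the sensory amplitude is
dimensionless); zero and constant cue-processing time; mask-terminated
sensory; and constant accumulation rate (uptake
$\gamma_s/(M\tau_{wm})$ to the ceiling). The signature separating the
direct-read-out account is qualitative: it predicts an early-cue benefit
even at $N = 1$, where the full model's curve is flat.

## Likelihood and fitting

The decode-error density is not available in closed form, but conditional
on the total spike count $T$ it does not depend on the gain. The package
therefore tabulates conditional densities $g_T(\varepsilon)$ for
$T = 1,\dots,T_{max}$ on a 360-bin circular grid by stratified Monte Carlo
(100 000 streams per tuning-width node, fixed internal seed), and evaluates
any density as the exact Poisson mixture over $T$ plus the analytic uniform
guess component, interpolating linearly in $\log\kappa$ between 25
log-spaced nodes on $[0.55, 30]$. Gains are served exactly (no gain grid)
up to a ceiling of 640. Against fresh Monte-Carlo references the cached
densities agree to total-variation $\lesssim 0.007$ and per-trial
Kullback–Leibler $\sim 10^{-4}$. Histogram bin edges coincide with some
neuron angles, where low-count decodes have atoms; angles are rounded
before binning so edge assignment is identical across samplers.

A condition's predicted error density convolves the decode kernel with the
wrapped normal of the accumulated diffusion variance (exact Fourier-domain
convolution) and mixes in the swap component weighted by $p_{swap}$. The
trial-level negative log-likelihood evaluates each trial's wrapped error
under its condition's density. Non-target orientations are drawn
independently and uniformly in both standard designs, so the marginal swap
component is exactly uniform; fitting uses this analytic marginal by
default (`swap_component = "uniform"`), which is about six times faster
than the per-trial non-target kernels (`"nontargets"`), which are also
implemented and give a modestly sharper likelihood for the swap
parameters.

Fitting (`fit_dynr()`) maximizes the likelihood by Nelder–Mead on
transformed parameters (log for positive quantities, logit for the swap
probability) with a smooth penalty outside broad boxes that keep the
population gain and tuning width inside the cached range. Ten dispersed
log-uniform starts (fixed seed) each run a short exploration; the leading
three are polished to convergence (relative tolerance $10^{-8}$, up to
2000 iterations) and the best is reported, with the per-start table kept
for diagnosis. AIC is $2k + 2\,\mathrm{nll}$; `compare_dynr()` fits a list
of variants and sums AICs across subjects when given a list of trial
tables (group differences are assumed summed — an assumption, as the
pooling used for published group comparisons is not stated). Free
parameter sets follow the printed conventions: 7 parameters for the
fixed-exposure design ($\check\gamma_{wm}, \kappa, \tau_{decay}, \tau_{wm},
b, \dot\sigma^2_{diff}, p$) and 9 for the masked design (adding
$\tau_{rise}$ and $\tau_{spatial}$).

## The synthetic-data generator

`make_design()` reproduces the two study designs exactly: set sizes
$\{1, 4, 10\}$ crossed with, respectively, a 200 ms exposure and cue delays
of 0/100/200/400/1000 ms plus a simultaneous-cue condition, or exposures of
30/48/77/122/196/313/500 ms with a 100 ms mask and cue at offset + 0.1 s.
`simulate_dataset()` runs the full generative pipeline per trial (swap
draw, diffusion, Poisson encode, ML decode) with orientations uniform on
the circle. Defaults of `dynr_params()` are the printed group ML estimates
of each design. The generator emulates a single stationary observer: no
lapses beyond zero-spike guesses, no motor noise, no sequential or
attentional effects, no parameter drift; passing recovery tests therefore
demonstrates internal consistency of simulator, likelihood and optimizer —
not that real observers satisfy these idealizations. Per-subject
variability for recovery studies can be added by log-normal jitter of the
group values, off by default.

## Numerical choices

* 360-bin circular error grid (0.5° of orientation per bin); trial
  densities linearly interpolated on the grid.
* Monte-Carlo budgets: $10^5$ streams per cache node; fresh-density
  comparisons use $2\times10^5$–$10^6$ draws.
* The dynamics are evaluated in closed form per phase; the only numerics
  are the ODE oracle in the tests.
* Problem sizes in the acceptance studies: 5 (or 7, for the fixed-exposure
  median) replicate datasets of 300 trials per design cell, 10 restarts per
  fit — sizes chosen so a full study runs in minutes on one core.
* Degenerate inputs: zero gain yields the exact uniform density; zero
  diffusion variance is an identity convolution; `N = 1` forces
  $p_{swap} = 0$; empty trial tables read back with a warning and refuse to
  fit.

## Known limitations

* **A (τ_rise, τ_wm) likelihood ridge in the masked design.** At the
  single-subject scale (21 cells × 300 trials), the likelihood admits a
  slow-rise/fast-uptake regime (large $\tau_{rise}$, small $\tau_{wm}$ —
  effectively a quadratic uptake law) that fits roughly half of synthetic
  datasets within a few nats of the generating regime, and sometimes
  better. With tenfold data the generating regime dominates decisively, so
  this is a finite-sample identifiability limit, not an implementation
  defect: recovered $\tau_{rise}$ and $\tau_{wm}$ scatter widely (compare
  the large between-subject spread of the published group estimates), and
  median recovery of these two constants at that scale should not be
  expected to be tight. The parameter-recovery vignette of the acceptance
  suite reports this honestly rather than constraining the boxes to hide
  the second mode.
* The decode cache serves gains up to 640 and tuning widths in
  $[0.55, 30]$; box penalties keep fits inside, and the direct-read-out
  variant's summed gain saturates at the ceiling.
* Swap dynamics in the fixed-exposure design use a constant probability;
  the printed parameter lists omit the spatial constants there, and the
  exact published parameterization per experiment is ambiguous — both modes
  are provided.
* The likelihood treats the simultaneous-cue condition as a perceptual
  report: full gain, no diffusion, no swaps.
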