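---
title: "Methods: Bloch-McConnell analysis of imino 1H CEST and R1rho data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bloch-McConnell analysis of imino 1H CEST and R1rho data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmcest)
```

## The problem

Watson-Crick base pairs in duplex DNA transiently flip into Hoogsteen
geometry: a sparsely populated (typically 0.05-0.5 %), short-lived
excited state (ES) in dynamic equilibrium with the dominant ground state
(GS). The exchange is invisible in ordinary spectra but leaves a
signature in the rotating frame: saturation transferred from the ES
resonance position back to the observable GS peak. High-power imino
proton (G-H1, T-H3) CEST profiles - normalized peak intensity versus RF
carrier offset - show a minor dip or shoulder at the ES chemical shift,
upfield of the GS dip for Hoogsteen pairing. This package simulates and
fits such profiles (and the complementary off-resonance R1rho
experiment) under a two-state Bloch-McConnell (B-M) model, selects
between exchange and no-exchange descriptions, probes parameter
degeneracy, and decomposes the temperature dependence of the exchange
rates into activation thermodynamics.

## The two-state model

The state is the six-vector of magnetization components
$(M_x, M_y, M_z)$ for GS and ES. Under a continuous RF field of
amplitude $\omega_1 = 2\pi B_1$ applied at offset
$\Omega = \omega_{RF} - \omega_{obs}$ from the observed resonance, the
evolution is $\dot M = L M$ where $L$ combines precession about $z$ at
each state's angular offset, nutation about $x$ at $\omega_1$,
relaxation ($R_1$, $R_2$), and exchange with forward/backward rate
constants $k_1 = p_{ES} k_{ex}$, $k_{-1} = (1 - p_{ES}) k_{ex}$. The
free parameters with exchange are $p_{ES}$, $k_{ex}$, $\Delta\omega$
(ES $-$ GS shift difference, ppm), $R_1$ and $R_2$ ($K = 5$); the
no-exchange model freezes $p_{ES} = k_{ex} = \Delta\omega = 0$
($K = 2$).

Key modelling choices:

* **Propagation by matrix exponential.** The RF is piecewise constant
  over the irradiation delay, so $M(T_{EX}) = e^{L T_{EX}} M(0)$ is
  exact; a 6x6 exponential is far cheaper than stepwise integration.
  The test suite verifies the propagator against an independent
  adaptive ODE integration at $10^{-12}$ tolerance to better than
  $10^{-6}$ relative error.
* **No thermal-recovery source term.** During $T_{EX} \le 100$ ms
  $\ll 1/R_1$, recovery toward thermal equilibrium contributes little;
  magnetization simply relaxes toward zero, which matches common CEST
  fitting practice. This is an interpretation: published descriptions
  of comparable pipelines do not state whether a recovery term was
  included.
* **ES relaxation tied to GS** ($R_1^{ES} = R_1^{GS}$,
  $R_2^{ES} = R_2^{GS}$) during fitting. With only a dip shoulder to
  constrain them, independent ES rates are not identifiable.
* **Sign conventions.** CEST offsets are
  $\Omega = \omega_{RF} - \omega_{obs}$; R1rho offsets follow the
  opposite convention $\Omega_{eff} = \omega_{obs} - \omega_{RF}$ and
  are negated internally. $\Delta\omega$ is ES minus GS in ppm,
  converted with the spectrometer frequency (default 600 MHz); upfield
  Hoogsteen imino shifts make it negative (the fitted values should
  fall in the -1 to -2 ppm range).

## CEST data preparation and the error model

Raw peak intensities at each (power, offset) are normalized by the mean
of triplicate zero-delay reference scans recorded at the same power,
and every offset of that power inherits one uncertainty: the standard
deviation of those references on the normalized scale. Three replicates
estimate a standard deviation only coarsely (the sampling error is
roughly 50 %), which is faithful to how such data are actually
processed, and is why reduced chi-square values scatter around one from
profile to profile. Noiseless synthetic references would give a zero
standard deviation and infinite weights, so a floor uncertainty
(default $10^{-4}$) is substituted with a warning.

Offsets are restricted to a window about the observed resonance before
fitting - $\pm 6$ ppm for delays up to 100 ms, $\pm 3$ ppm for 400 ms
delays - to exclude regions where cross-relaxation (NOE) dips would
contaminate a real measurement. The generator does not simulate NOE
dips; the windows are retained so that synthetic and real pipelines are
identical.

## RF inhomogeneity

The B1 field is not a single value across the sample but approximately
Gaussian with a fractional FWHM that can be calibrated from a nutation
experiment: Fourier transform the on-resonance nutation curve, fit a
Gaussian to the magnitude peak, and divide its FWHM by the nominal
amplitude (`calibrate_inhomogeneity()`). The default fractional FWHM is
0.10, typical of proton channels on cryogenic probes; the forward model
and generator share it.

Averaging over the distribution matters more than is obvious. Near
resonance the magnetization nutates coherently at the effective field
for the full 100 ms delay; the continuous B1 distribution dephases
these oscillations completely, and the smooth dips seen in measured
profiles reflect that dephasing. A coarse quadrature (a handful of
nodes) leaves spurious coherent beats in the modelled profile: a
trapezoidal rule only reproduces the dephasing while its aliasing
revival time (one over the node spacing) exceeds the delay. The default
rule therefore spaces nodes by less than
$1/(T_{EX} + 4.3/2\pi\sigma)$ Hz over $\pm 3\sigma$ - about 31 nodes at
$B_1 = 1$ kHz, 10 % FWHM, 100 ms - and collapses to few nodes where the
product $\sigma T_{EX}$ is small. The tests verify the rule against a
201-node reference and against Monte Carlo sampling of the continuous
Gaussian.

## Fitting, model selection, degeneracy

Profiles from all powers are fit jointly (shared $R_1$, $R_2$ - the
physics of a single resonance - with the per-power uncertainties
weighting the residuals) by Levenberg-Marquardt. Because the objective
has local minima in ($p_{ES}$, $k_{ex}$, $\Delta\omega$), fitting is
multistarted from a grid: $p_{ES} \in \{0.05, 0.2, 1\}$ %,
$k_{ex} \in \{500, 3000, 20000\}$ s$^{-1}$,
$\Delta\omega \in \{-1, -2\}$ ppm, with $R_1$, $R_2$ seeded from the
no-exchange fit. The objective is evaluated once at all 18 starts and
full optimizations run from the best few (default 4): the triage
changes no result in practice and keeps the cost linear in the number
of promising basins. Bounds ($p_{ES} \in (10^{-5}, 0.3)$,
$k_{ex} \in (200, 10^6)$ s$^{-1}$, $R_1 \in (0.1, 10)$,
$R_2 \in (1, 100)$ s$^{-1}$) are physically motivated and prevent GS/ES
label swaps. The $k_{ex}$ floor of 200 s$^{-1}$ marks the validity
limit of the experiment itself: below it, cross-relaxation dominates
imino-proton exchange profiles (which is why slow-exchange studies
must lengthen relaxation delays or discard data), and it also marks an
identifiability floor — once $k_{ex} \ll \omega_1$ for every applied
power, the excited state saturates fully whenever irradiated and the
profile depends on the exchange parameters almost only through the
forward flux $k_1 = p_{ES} k_{ex}$. A fit that ends pinned at this
floor (flagged `at_bound`) signals that the data determine $k_1$ but
not $k_{ex}$ itself; adding weaker spin-lock powers
($B_1 \lesssim k_{ex}/2\pi$) is what restores separability in
practice. The default $\Delta\omega$ window of $(-3, -0.2)$ ppm is
deliberately tight: it is the physically meaningful range for an imino
proton moving into an upfield-shifted Hoogsteen excited state (expected
$-1$ to $-2$ ppm, with margin). Beyond its role as a prior, the window
regularizes the fast-exchange ridge: at $k_{ex}/|\Delta\omega|
\gtrsim 3$ the likelihood develops a shallow valley along which
$p_{ES}$, $\Delta\omega$ and $k_{ex}$ trade off, and with a wide bound
a noise draw can park the optimum at unphysically large shift
differences. Users fitting systems with other excited states should
widen it explicitly. Parameter errors are square roots of the diagonal
of the inverse approximate Hessian; a parameter ending at a bound is
flagged.

Model selection uses the residual sum of squares
$RSS = \sum_i (I_i^{fit} - I_i^{exp})^2$ over all power-offset
combinations, the information criteria
$AIC = N \ln(RSS/N) + 2K$ (with the small-sample correction
$+ 2K(K+1)/(N-K-1)$ when $N/K < 40$) and
$BIC = N \ln(RSS/N) + K \ln N$, and the weight
$w = e^{-\Delta/2} / (1 + e^{-\Delta/2})$. The criterion difference is
taken as (exchange $-$ no-exchange), so $w \to 1$ when the exchange
model is decisively better; the published description leaves the order
of the difference ambiguous, and this orientation restores the
standard Akaike-weight semantics of the reported "weight of the
exchange fit". Exchange is accepted only if **both** weights exceed
0.995 **and** the reduced chi-square $\chi^2_\nu$ (weighted residual
sum over $N - K$) decreases - a deliberately conservative dual
threshold.

Identifiability is probed by `degeneracy_scan()`: fix one of $k_{ex}$,
$\Delta\omega$, $p_{ES}$ along a log grid spanning threefold either
side of its fitted value, refloat the others, and track
$\chi^2_\nu$. Well-determined parameters produce a sharp rise
(severalfold) at the grid ends; a flat scan on null data is the
expected unidentifiability signature.

## Off-resonance R1rho

For spin-lock data the observable is the mono-exponential decay rate of
magnetization prepared along an effective field. `r1rho_value()`
aligns the initial magnetization along the GS effective field when
$k_{ex}/|\Delta\omega|$ (in rad/s) is below one - in slow exchange the
GS is spin-locked on its own - and along the population-averaged
effective field otherwise; the threshold of exactly one is this
package's choice, as the cited convention is stated only by reference.
Decay curves use six to seven delays with the longest under 60 ms,
placed so a typical exchange-broadened rate loses about 70 % of the
signal. Rates and Monte Carlo errors (`fit_decay()`, default 500
resamples at the residual scale) feed the dispersion transform
$(R_2 + R_{ex}) = (R_{1\rho} - R_1\cos^2\theta)/\sin^2\theta$ plotted
against $\Omega_{eff}/2\pi$, and `fit_r1rho_bm()` refits the rates with
the same B-M core. With equal $R_1 = R_2$ the no-exchange tilted-frame
decay is exactly mono-exponential and the transform is flat to
machine-level accuracy; with unequal rates the simulate-then-fit route
carries a small $O((R_2 - R_1)/\omega_{eff})$ oscillatory residue, so
closed-form comparisons in that regime are made at $10^{-3}$ relative
tolerance. In the fast-exchange regime the simulation is checked
against the independent Laguerre closed-form approximation
(`r1rho_laguerre()`), which is never used for fitting.

## Van 't Hoff thermodynamics

Forward and backward rate constants across temperatures are fit per
direction to
$$\ln\frac{k_i(T)}{T} = \ln\frac{k_B \kappa}{h}
 - \frac{\Delta G_i^\ddagger(T_{hm})}{R\,T_{hm}}
 - \frac{\Delta H_i^\ddagger}{R}\Big(\frac{1}{T} - \frac{1}{T_{hm}}\Big),$$
with $\kappa = 1$ and $T_{hm}$ the harmonic mean of the experimental
temperatures - the reference point that decorrelates the two
parameters against statistical compensation. The model is linear in
$\Delta G^\ddagger(T_{hm})$ and $\Delta H^\ddagger$, so the fit is a
weighted linear regression (weights $1/\sigma^2$ on $\ln(k/T)$ with
$\sigma = \sigma_k / k$; rate errors from the upstream fits are
heteroscedastic, and an unweighted option is kept since the original
protocol's weighting is not documented). $T\Delta S^\ddagger =
\Delta H^\ddagger - \Delta G^\ddagger$; equilibrium values are
differences of the two directions. $R^2$ is computed on the rate scale
(not the log scale), pooling both directions, as
$1 - SS_{res}/SS_{tot}$. Energies are in kcal/mol with
$R = 1.98720425 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$.

## The synthetic-data generator

`generate_cest_dataset()` emulates the statistical structure of the
experiment: B-M intensities on the acquisition grid (default offsets
$-6$ to $+6$ ppm in 0.1 ppm steps; powers 250, 500, 1000 Hz;
$T_{EX} = 100$ ms, shortened to 80 ms for the high-temperature
scenario; 600 MHz), homoscedastic Gaussian noise per power at 0.5 % of
the reference intensity, triplicate zero-delay references carrying the
same noise, and the shared 10 % B1 inhomogeneity. Seeds fix datasets
bit-for-bit without disturbing the caller's RNG stream.

What it deliberately does **not** emulate: NOE dips from
cross-relaxation, solvent-exchange effects on imino protons, duplex
melting species, spectral overlap between resonances, or temperature
calibration errors. Passing recovery tests on these simulations
therefore demonstrates the correctness and statistical calibration of
the fitting machinery under the stated noise model - not robustness to
the artifacts a real spectrum can contain, which the offset windows and
the recommended cross-checks against carbon/nitrogen relaxation
dispersion address in practice.

Benchmark scenarios used in the tests and the analysis scripts span the
regimes of interest: a slow, weakly populated A-tract case
($p_{ES} = 0.06$ %, $k_{ex} = 1000$ s$^{-1}$, $\Delta\omega = -2$ ppm),
an intermediate G-C+ case ($0.3$ %, $3000$ s$^{-1}$, $-1.5$ ppm), fast
cases at 6000 and (with the 80 ms delay) 10000 s$^{-1}$, an ultra-fast
25000 s$^{-1}$ case (auxiliary values $p_{ES} = 0.15$ %,
$\Delta\omega = -2$ ppm, chosen once as typical for a non-A-tract A-T
pair since no population is printed for that regime), and a
no-exchange control.

## Problem sizes and statistical checks

The recovery suite fits full-grid datasets (363 points across three
powers) for the benchmark scenarios and uses reduced acquisitions for
batch statistics, sized so the whole suite runs in minutes on one CPU:
the 50-dataset false-positive batch uses a single power and 0.5 ppm
offset steps (the selection statistics depend on $N$ and the noise
structure, not on the full grid), while the 3-fold-recovery property
uses 12 seeded datasets on the full three-power, 0.1 ppm grid - the
dense offset sampling carries the dip-width information that separates
$p_{ES}$ from $k_{ex}$ in slow exchange, and with a sparser grid the
collapsed slow-exchange solution (product $p_{ES} k_{ex}$ preserved,
$k_{ex}$ underestimated) can genuinely out-fit the truth. The van 't Hoff
coverage check uses 100 seeded series at 5 % log-normal rate noise and
expects the 95 % confidence intervals to cover the truth in at least
90 % of runs.

## Known limitations

* Two states only; a third state or melting intermediates bias the
  fitted parameters in ways the package does not diagnose.
* Cross-relaxation is handled by exclusion windows, not modelled.
* The triplicate-based uncertainty is a coarse estimator; reduced
  chi-squares are interpreted relatively (with/without exchange), not
  absolutely.
* In very fast exchange ($k_{ex}/|\Delta\omega| \gtrsim 3$) $p_{ES}$
  and $\Delta\omega$ become correlated and individually soft;
  $k_{ex}$ remains recoverable, which is why the ultra-fast benchmark
  asserts only the rate.
* At the opposite extreme — weak populations near 0.05 % with
  $k_{ex} \sim 1000$ s$^{-1}$ and only high-power irradiation — the
  likelihood can be nearly flat along decreasing $k_{ex}$ at constant
  $k_1$: on noiseless data a five-fold $k_{ex}$ displacement changes
  the profile by under one noise standard deviation per point, so on
  some noise realizations the global optimum sits far from the truth
  (often at the $k_{ex}$ floor, with the `at_bound` flag raised). Point
  estimates of $k_{ex}$ from such acquisitions should be read together
  with that flag and with a degeneracy scan, and low-power data added
  where slow exchange is suspected.
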