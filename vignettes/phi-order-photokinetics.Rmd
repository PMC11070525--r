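---
title: "Phi-order photokinetics under polychromatic light: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phi-order photokinetics under polychromatic light: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phikin)
```

## The physical model

`phikin` models unimolecular photoreactions -- isomerizations, ring
closures/openings, photodegradations -- in a well-stirred, slab-shaped
liquid sample exposed to a collimated polychromatic beam.  A mechanism is a
directed graph of photosteps between `nsp` species (the reactant `X` plus
photoproducts `Y1, Y2, ...`); each step `Yj -> Yj'` carries its own,
generally wavelength-dependent quantum yield $\Phi_{j \to j'}(\lambda)$.
The catalog covers the mechanism families operating common organic
actinometers and photochromes: a primary photoprocess with a transparent
(`m1`) or absorbing (`m2`) product, the photoreversible pair (`m3`), the
doubly photoreversible chain (`m4`), a photochrome whose product is pushed
back both inside and outside the reactant's absorption region (`m5`,
diarylethene-like), divergent branching (`phi_shaped`), and tri- and
tetra-molecular cycles.

The rate of species $Y_j$ sums, over every wavelength of the irradiation
range and every photostep touching $Y_j$, the absorbed-photon flux weighted
by the step's quantum yield:

$$\frac{dC_{Y_j}}{dt} \;=\; \sum_{\lambda}\,\sum_{j'}\Big[
  -\Phi_{j\to j'}(\lambda)\,P_a^{Y_j}(\lambda, t)
  +\Phi_{j'\to j}(\lambda)\,P_a^{Y_{j'}}(\lambda, t)\Big],$$

with the light absorbed specifically by $Y_j$ among all absorbers

$$P_a^{Y_j}(\lambda, t) = A_{Y_j}(\lambda, t)\; P_0(\lambda)\;
  \frac{1 - 10^{-A_{tot}(\lambda, t)}}{A_{tot}(\lambda, t)},$$

where $A_{Y_j} = \epsilon_j(\lambda)\, l_{irr}\, C_j$ and $A_{tot}$ adds
every species plus any photochemically inert spectator (SPM) absorbance.
The dimensionless ratio $(1-10^{-A})/A$ is the *photokinetic factor*; it
equals $\ln 10$ at $A = 0$ and decreases strictly with $A$, which is the
single mechanism behind photon competition, spectator slow-down, and
auto-photostabilization at higher loading.

All spectra live on one integer 1-nm wavelength grid and lamp values are
photon counts per grid step (einstein s$^{-1}$ dm$^{-3}$), so wavelength
integrals reduce to plain sums with no step weight.  Sums over the grid are
accumulated by `sum()`, i.e. in extended (80-bit) precision.

**Assumptions.**  Beer-Lambert additivity of absorbances, which in
practice confines the medium to its spectrophotometric linearity zone
(total in-band absorbance below about 0.5 -- the simulator warns beyond
it); no thermal (dark) steps and no bimolecular chemistry; no reflection,
scattering or emission corrections; collimated beam and perfect stirring.

## Integration

The rate law is integrated by a classic fixed-step fourth-order
Runge-Kutta scheme (via `deSolve::rk4`).  Fixed stepping is a
reproducibility choice: a trace is fully determined by the system, the
step and the duration.  The default step makes the reactant move at most
$10^{-3} C_{X,0}$ per step at $t = 0$; the default duration proceeds in
blocks of six initial time constants $C_{X,0}/|r_{0,X}|$ until the largest
species rate has dropped below $10^{-3}$ of its initial value (at most ten
blocks).  Stopping a trace far from its final state measurably biases the
subsequent model fit, which is why the duration is tied to stationarity
rather than fixed.

Recording keeps the first 33 raw steps densely and then a uniform stride
(about 161 points per block by default).  The dense opening matters for
multi-timescale systems: without it the fastest kinetic component can fall
entirely between recorded samples, and any initial rate estimated from the
record -- by finite differences or by fitting -- misses the true
rate-law slope at $t = 0$.

Concentrations more negative than $-10^{-15}$ M abort the run (the step is
too coarse); smaller negatives are floating-point undershoot and are
clamped to zero.  Mass conservation along catalog traces holds to
$10^{-10}$ relative and better.

## The Phi-order trace model

Every species trace and every total-absorbance trace is described by the
Phi-order equation

$$y(t) = y_\infty + \sum_{i=1}^{n} \omega_i\,
  \log_{10}\!\big(1 + cc\; e^{-k_i t}\big),$$

with one shared $cc > -1$ per trace and one $(\omega_i, k_i)$ pair per
mono-Phi-order term.  Its analytic derivative gives the trace rate, and at
$t = 0$ the closed-form initial rate

$$r_0 = -\sum_i \frac{\omega_i\, cc\, k_i}{(1 + cc)\,\ln 10}.$$

For the textbook limiting case -- monochromatic light, single step,
transparent product -- the equation is exact with $n = 1$,
$cc = 10^{A_0} - 1$, $\omega = 1/(\epsilon l)$ and
$k = \Phi\,\epsilon\, l\, P_0 \ln 10$, which is the package's closed-form
oracle.  For polychromatic light it is an empirical global model; the
package's standing benchmark (50 seeded random systems across the whole
mechanism catalog) fits every concentration trace to SSE below $10^{-10}$
M$^2$ and RMSD below $10^{-9}$ M, with squared correlations above 0.999 on
every trace.

The admissible number of terms is bounded by the mechanism: the number of
distinct reaction partners of the species for non-cyclic graphs (a
photoreversible pair needs a single term), the total step count for cyclic
mechanisms and for absorbance traces.  Which number is *adequate* depends
on the trace shape; the benchmark escalates from two terms (three for
absorbance) until the fit is tight both absolutely and relatively, up to
six.

### Fitting protocol

`fit_phi_order()` performs multistart Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`, analytic Jacobian).  The optimizer works on
unconstrained parameters: $\log k_i$, $\log(1 + cc)$, and raw $y_\infty$,
$\omega_i$.  Two guards keep the implied initial rate meaningful:

* $k$ is capped smoothly (harmonically) at twice the reciprocal of the
  finest sampling interval.  A term decaying between two samples is
  invisible to the data yet would contribute arbitrarily to $r_0$.  The
  cap's gradient never vanishes, so a start that overshoots it can always
  be pulled back.
* Optima whose $|r_0|$ exceeds ten times the largest difference quotient
  in the data are discarded: they are $cc \to -1$ log-singularity
  artifacts that fit the samples while hiding a spurious transient at
  $t = 0$.

Starting values measure the amplitude and half-decay time from the largest
excursion relative to the final sample (not from the first sample), so
rise-and-fall traces are not mistaken for flat ones; 19 seeded random
perturbations surround the deterministic guess.  The best-SSE optimum
wins; near-ties go to the smallest total $k$ so results are deterministic.
All multistart optima are retained in the result: distinct parameter sets
of equal quality are the rule, not the exception (the identifiability
issue), and inspecting the table shows that the initial rate is the
invariant across them while individual rate constants are not.

### The three routes to the initial rate

The initial rate can be computed theoretically (rate law at $t=0$),
numerically (third-order one-sided finite difference on the trace
opening), and from the fit (closed form above).  The theoretical and
numerical routes agree to better than one percent on every reactant,
first-product and absorbance trace of the benchmark; regressing either the
fit-derived or the numerical values on the theoretical ones gives a
through-origin slope of 1 within one percent and $r^2 > 0.999$.  A known
limitation: on rise-and-fall traces of richly interconnected (cyclic)
mechanisms the *fit-derived* rate is only regression-accurate -- single
fits can miss by a few percent even when the trace itself is reproduced to
RMSD $< 5\times10^{-10}$ M, because the shared-$cc$ model trades a small,
structured misfit near $t=0$ against the bulk of the trace.  When a
per-trace initial rate matters, prefer the finite-difference or rate-law
routes, and treat fitted rates of secondary species with induction shapes
as indicative.

## The synthetic-system generator

`generate_system()` builds deterministic systems from band-level
descriptions; `random_system(seed)` draws complete systems for benchmark
sweeps.  Shapes follow what near-UV organic photochemistry looks like:
Gaussian absorptivity bands (peaks 10$^3$-3$\times$10$^4$
M$^{-1}$cm$^{-1}$, FWHM 25-60 nm, centres 320-430 nm on a 300-450 nm
grid), constant or logistic (sigmoid) quantum-yield profiles with plateaus
0.05-0.9, and broadband Gaussian, LED-like, or flat ("same photon count at
every wavelength") lamps delivering about $10^{-6}$ einstein s$^{-1}$
dm$^{-3}$.  Initial concentrations are drawn log-uniformly on
$10^{-6}$-$10^{-4}$ M -- concentrations are scale parameters, so the
log-uniform measure spreads the draws evenly across decades -- and then
rescaled down if needed so the medium absorbance stays below 0.45 at all
times (mass conservation bounds every species by $C_{X,0}$), keeping
generated systems inside the linearity zone the rate law assumes.

Two deliberate idealizations: bands are truncated to exactly zero below
$10^{-4}$ of their peak, so spectral supports are compact and overlap
windows (OSIA) are sharply defined; and all randomness flows through one
seed per draw with the caller's RNG state restored.  What the generator
does **not** emulate: measurement noise, baseline drift, instrument
bandwidth, inner-filter artifacts beyond Beer-Lambert, thermal reactions,
and non-ideal (uncollimated, unstirred) geometry.  Passing tests therefore
validate the numerical machinery and the model algebra under ideal-data
conditions; they do not certify performance on noisy experimental traces.

## Derived studies

* **Initial-concentration scans** (`c0_scan`): the canonical seven-point
  series $1.3\times10^{-6}$ ... $10^{-4}$ M is simulated on one shared
  time grid.  Fractional conversion is compared at one twentieth of the
  shared duration -- while every run is still evolving -- because at long
  times conversions converge to their final values and the slow-down
  becomes invisible.  The auto-photostabilization signature is
  $|r_{0,X}|$ strictly increasing with $C_{X,0}$ while conversion at the
  comparison time strictly decreases.
* **Spectator scans** (`spm_scan`): percent reductions are reported
  against the spectator-free baseline of the same system and settings.  A
  spectator overlapping only one branch's band of a divergent system
  suppresses that branch selectively -- but only when the branches differ
  in their wavelength weighting (two-band reactant with complementary
  quantum-yield profiles); with wavelength-invariant quantum yields all
  rates shrink by the same factor.
* **Reactivity-optimum profiling** (`wror_profile`, `led_scan`): the
  per-wavelength score $\epsilon_X(\lambda)\sum_{j'}\Phi_{X\to
  Y_{j'}}(\lambda)$ locates the wavelength range of optimal reactivity;
  the window is the contiguous region within 95% of the peak score (the
  construction rule is a package convention -- only the window's existence
  and location, not its exact width, are substantive).  The LED scan
  cross-checks the profile empirically with equal-photon Gaussian bands.
* **Photostationary ratios** (`pss_ratios`): stationarity requires the
  terminal rates to satisfy $|dC/dt|\, t_{end}/C_{X,0} < 10^{-6}$
  (configurable).  Ratios are exactly invariant with $C_{X,0}$ where the
  wavelength weighting cancels: monochromatic photostationary pairs, and
  end-product ratios of constant-quantum-yield branching.  For general
  polychromatic reversible systems the invariance is approximate because
  the photokinetic-factor weighting shifts with total absorbance.

## Kinactinometry

Actinometer standardization regresses fit-derived initial rates on
delivered photon counts through the origin (the proportional law has no
intercept); a calibration below $r^2 = 0.999$ is an error, not a warning,
since it signals a broken premise such as absorbance drift out of the
linearity range.  Every slope, photon count and yield carries a mandatory
(lamp, range) tag pair -- `dl` for the lamp/actinometer overlap window,
`dl_plus` for the full lamp output -- and operations refuse to mix tags:
a line standardized for one lamp cannot price another, which the type
discipline enforces rather than documentation.  The two bookings are
linked by the lamp's out-of-OSIA photon ratio $\beta$ through
$\alpha^{\Delta\lambda} = \alpha^{\Delta\lambda^+}(1+\beta)$.  The
relative disposition of lamp span, actinometer window and species window
is classified (`sit1`/`sit2`/`sit3`), and the under-counting `sit3` case
warns.  The photonic yield (converted amount per *incident* photon count,
time-dependent) and the efficiency $PY = -r_0/P_0$ (time-independent;
equal to $-\alpha$ across an intensity scan) are provided with the same
tag discipline.  A reviewer of high-concentration "zeroth-order" quantum
yield protocols will recognize that what they estimate is numerically this
photonic yield, not an absolute quantum yield.

Quantum yields proper are recoverable only under declared premises: a
single depletion step with a wavelength-invariant yield inverts the
initial-rate equation (`quantum_yield_single_step`, warning above 1); the
general expression (`quantum_yield_general`) solves the full rate law for
one step's yield and needs every other quantum-yield profile and
absorbed-flux term -- a calculation-only mode by construction.

## Numerical choices and problem sizes

$1 - 10^{-A}$ is evaluated as `-expm1(-A log 10)` (no cancellation); the
photokinetic factor switches to its analytic series below $A = 10^{-6}$,
with the two branches agreeing to $10^{-12}$ relative at the switch.
Fit metrics are the squared correlation of fitted versus input series,
the sum of squared errors, and the root-mean-square deviation.

The validation sweep behind the package's headline numbers uses 50 random
systems (about 180 fitted traces), roughly 160 recorded points per
simulation block, 10 optimizer starts per fit with term escalation -- a
size chosen to exercise every mechanism family and both trace kinds while
a full sweep completes in a few minutes on a single core.
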