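---
title: "Methods: predicting AST-120 drug interactions from dissolution and absorption kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting AST-120 drug interactions from dissolution and absorption kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ast120di)
```

## The prediction problem

AST-120 is an oral spherical-carbon adsorbent given in chronic kidney
disease. It binds small organic molecules non-specifically, so a
co-administered drug is at risk of adsorption — but only the fraction of the
dose that is still in solution, unabsorbed, when the adsorbent arrives in
the gut. Two first-order clocks therefore determine the risk at a dosing
interval of $t$ minutes (drug first, adsorbent after $t$):

* the **theoretical dissolution rate**
  $R_d(t) = 100\,[1 - e^{-k_d (t - T_{lagd})}]$, and
* the **theoretical absorption rate**
  $R_a(t) = 100\,[1 - e^{-k_a (t - T_{laga})}]$,

both clamped to $[0, 100]$ and set to $0$ at or before their lag.
"Simultaneous" co-administration is encoded as $t = 1$ minute throughout: a
one-minute head start is physiologically indistinguishable from none, and it
keeps $t > 0$ so the formulas are total.

## Dissolution: extended Noyes-Whitney fits

A measured profile (percent dissolved vs. time, graph-read from
Pharmacopoeia dissolution tests at pH 1.2 and pH 6.8) is fitted with
$x(t) = x_e\{1 - e^{-k_d (t - T_{lagd})}\}$, the solution of the
Noyes-Whitney equation $dC/dt = kS(C_s - C)$ under constant surface area,
with $k_d = kS$ folded into one rate constant. Parameters and units:

* $k_d$ — dissolution rate constant, stored in s$^{-1}$ (reported as
  $\times 10^{-4}$ s$^{-1}$, the conventional scale for these values);
* $T_{lagd}$ — lag time in hours, defined operationally as the earliest time
  the measured profile reaches 1 % dissolved, located by linear
  interpolation between bracketing samples;
* $x_e$ — equilibrium percent, free within $(0, 110]$ (assay overshoot up
  to 110 % is tolerated on input).

Two decisions here were genuinely open:

* **Lag handling.** $T_{lagd}$ is estimated from the data by the 1 %-crossing
  rule and *held fixed* during the least-squares fit rather than
  co-estimated. Co-estimating lag and rate creates an identifiability ridge
  on profiles with few early points; the two-step rule is reproducible and
  cheap. Its cost is a small bias when sampling is coarse relative to the
  dissolution timescale (the interpolated crossing then precedes or lags the
  model's own 1 % time); the test suite exercises both regimes. A lag is
  used automatically only when the first measured value is below 1 % and the
  estimated lag exceeds one minute.
* **Completeness.** $R_d$ is only meaningful for drugs that dissolve
  completely, and is then evaluated with $x_e := 100$ exactly. A fit counts
  as complete when fitted $x_e \ge 95$ % *and* the last measured point is at
  least 95 % — graph-read data carry a few percent of noise, so demanding
  100 % would spuriously exclude drugs. Drugs complete in neither medium are
  excluded via a classed condition (`ast120_excluded_drug`), never silently
  dropped; when both media complete, the larger $k_d$ governs.

Fitting is bounded Levenberg-Marquardt (`minpack.lm::nls.lm`) on
$(k_d, x_e)$ with $k_d$ initialized from the slope of $-\log(1 - x/100)$
over the rising phase and three log-spaced restarts ($0.1\times$, $1\times$,
$10\times$); convergence tolerances are tightened to `ftol = ptol = 1e-15`
so noiseless synthetic curves are recovered to $10^{-6}$ relative, the
contract the unit tests enforce across $k_d \in [10^{-5}, 10^{-2}]$
s$^{-1}$.

## Absorption: compartmental oral models

Plasma curves are fitted on the linear concentration scale, unweighted —
graph-read data have roughly uniform absolute error, and no replicate
information exists to support weights. The one-compartment solution is

$$C(t) = A\,\frac{k_a}{k_a - k_e}\left(e^{-k_e \tau} - e^{-k_a \tau}\right),
\qquad \tau = \max(t - T_{laga}, 0),$$

evaluated by its analytic limit $A\,k_a \tau e^{-k_e \tau}$ when $k_a$ and
$k_e$ agree within $10^{-8}$ relative, so the prediction is continuous
across the degeneracy. The two-compartment model is parameterized directly
in macro constants, $C(t) = A\,[f e^{-\alpha\tau} + (1-f) e^{-\beta\tau} -
e^{-k_a\tau}]$ with $\alpha > \beta > 0$ and amplitude fraction
$f \in (0,1)$; the coefficients sum to zero so $C(T_{laga}) = 0$ exactly,
and the form has no removable singularities to patch. Rate constants and
the amplitude are optimized on the log scale, $f$ on the logit scale, and
$\alpha > \beta$ is enforced by fitting $\log(\alpha - \beta)$. Starting
values come from curve stripping: the terminal log-linear slope gives the
slow disposition constant, the method of residuals on pre-peak points gives
$k_a$, and the lag starts at the last time with zero observed
concentration; five multi-start perturbations of $k_a$ guard against local
minima.

Three further choices deserve justification:

* **Model order** is chosen by the small-sample corrected information
  criterion (AICc, with the residual variance counted as a parameter); ties
  within 2 units go to the one-compartment model. The original procedure
  for such fits is visual inspection, which is not reproducible; AICc with
  a parsimony window is the standard automated surrogate.
* **Lag parsimony.** Each fit is run twice, with $T_{laga}$ free and with
  it pinned at 0, and the free-lag variant is kept only when it wins the
  AICc by more than 2 units. The rationale is a likelihood ridge: $k_a$
  and $T_{laga}$ trade off, so a free lag on a curve that needs none
  inflates the variance of $\hat{k}_a$ and, because the ridge is one-sided,
  biases it upward. A genuine lag — zero early concentrations — passes the
  AICc test decisively, as the recovery tests on lagged truths confirm. A
  negative fitted lag is clamped to 0 after optimization and the unclamped
  value kept in the `tlaga_unclamped` diagnostic, so the clamp is
  observable.
* **Flip-flop kinetics.** The one-compartment likelihood is symmetric under
  exchanging $k_a \leftrightarrow k_e$ (with a compensating amplitude). The
  labeling with $k_a \ge k_e$ is reported by default and flagged in
  `flipped`; since only $k_a$ enters $R_a$, users fitting genuinely
  flip-flop formulations (slow-release) should override with
  `assume_ka_ge_ke = FALSE` and identify the labeling from external
  knowledge. The ambiguity is surfaced, not hidden.

## Threshold optimization

Against a threshold pair, a study is predicted equivalent when
$R_d \ge R_{dth}$ **and** $R_a \ge R_{ath}$, non-equivalent when both are
strictly below, and mixed (always counted inconsistent) otherwise; equality
sits on the equivalent side, exactly as the rule is stated. The predictive
value is the percent of studies whose prediction matches the observed E/NE
label.

As a function of the thresholds the predictive value is piecewise constant:
it can only change when a threshold crosses an observed $R_d$ or $R_a$
value. `optimal_region()` therefore evaluates one representative per
constancy cell — the cells on each axis are $[0, v_{(1)}]$,
$(v_{(1)}, v_{(2)}]$, …, $(v_{(k)}, 100]$ over the sorted distinct observed
values — and returns the exact global maximum with the attaining set as
axis-aligned boxes. The representative of the open top cell sits $\epsilon$
above the largest value, with $\epsilon$ half the smallest nonzero gap
between sorted values, capped at 0.05, which guarantees a point strictly
inside every cell. The boundary semantics make lower box bounds that sit at
data values *open* and upper bounds *closed*; the printed region endpoints
are therefore interval endpoints with explicit open/closed flags, and
`region_contains()` honors them. When the attaining set is not a single
box, the `rectangles` table partitions it into boxes (runs of attaining
cells merged along both axes); each rectangle is fully attaining, which the
property tests spot-check against a 0.1 % brute-force grid sweep.

The operating point $(Th_{Rd}, Th_{Ra}) = (90, 30)$ used for risk grouping
is a configuration default — a round-number point inside the optimal region
computed from the bundled studies — not an output of the optimization;
classification warns if a user-chosen point falls outside a supplied
region.

## Risk groups

Groups are the four quadrants of the $(R_d, R_a)$ plane at the operating
point: 1 (both at/above), 2 (only $R_a$ above), 3 (only $R_d$ above),
4 (both below). Because $R_d$ and $R_a$ are non-decreasing in the interval,
group-1 membership is upward-closed: once a drug reaches the low-risk group
it stays there at every longer interval, which is what makes
`min_interval_to_group()` a simple ascending scan. The default interval
grid is $\{1, 30, 60, 90, 120, 240\}$ minutes, the union of the grids used
in the interaction studies and the grouping analysis; neither subset is
privileged.

## Synthetic data and what the tests show

`generate_dissolution_curve()` and `generate_pk_curve()` produce curves
from the model solutions plus seeded Gaussian noise — in percent for
dissolution (default studies use sd 2 %, the scatter expected of graph-read
profiles), and as a fraction of the peak concentration for plasma curves
(studies use 5 %). Noise is clipped to the assay range $[0, 110]$ for
dissolution and floored at 0 for concentrations. All randomness flows
through an explicit `seed` argument (`with_seed()` restores the caller's
random stream), so every generated curve is bit-for-bit reproducible.

The recovery studies in the test suite use these sizes, chosen for
Monte-Carlo precision: 200 seeds for dissolution (6-point profiles over
5–60 min) and 300 seeds for plasma curves (a standard absorption-phase-dense
12-point schedule over 0.25–24 h), asserting mean relative bias of
$\hat{k}_d$ and $\hat{k}_a$ within 2 %. The $\hat{k}_a$ estimator is
heavy-tailed under noise — occasional draws move the global least-squares
optimum far along the lag ridge — so the mean over a few hundred seeds, not
any single fit, is the meaningful quantity.

What the generator does *not* emulate, and the tests therefore cannot show:
graph-digitization error is not Gaussian or independent across points;
dissolution profiles of real formulations can be sigmoidal or biphasic
(surface-area change, coating rupture) where the single-exponential model
is only an approximation; plasma curves carry inter-subject variability
that graph-read mean curves average away; and fed-state absorption (one
bundled drug's data are fed-state) is treated like any other curve.
Passing recovery tests demonstrate correctness of the estimation machinery
under the stated model, not validity of the model for any particular
formulation.

## Degenerate inputs and numerical conventions

* Profiles never reaching 1 % dissolved have no lag (classed
  `ast120_no_dissolution` error); curves with fewer than 3 (dissolution) or
  5 (plasma) points are rejected at construction.
* One-compartment fits need 4 points, two-compartment 6; AICc is $+\infty$
  when the sample cannot support the parameter count, which automatically
  defers to the simpler model.
* $R_d$/$R_a$ clamps (negative values to 0, values above 100 to 100) and
  lag clamps are applied inside the rate functions, and the pipeline log
  records exclusions, medium selections and clamp events.
* Public reports round rates and predictive values to one decimal;
  all internal computation keeps full precision.
* All tabular I/O is plain CSV (header row, UTF-8, "." decimal); the
  region summary is JSON with explicit open/closed flags.

## Known limitations

The bundled evidence base is 14 study results over 6 drugs, so the optimal
threshold region is a coarse object — its predictive value changes in steps
of $100/14 \approx 7.1$ % — and the choice of (90, 30) within it is
conventional. The method consumes E/NE labels as given and does not
re-derive them from AUC/Cmax confidence intervals; it ignores the
adsorbent's own kinetics (adsorption capacity and rate), pH-dependent
solubility, and nonlinear absorption. Drugs with incomplete dissolution in
both media fall outside the method entirely and are reported as
unclassifiable.
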