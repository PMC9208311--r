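---
title: "Equilibrium unfolding of homodimeric proteins: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium unfolding of homodimeric proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerfold)
```

## The model

An effector-procaspase zymogen is a homodimer: two protomers, each folding
as one domain, joined across a conserved interface.  Denaturant-induced
equilibrium unfolding of such a dimer is described here by a *single-chain
mechanism*: an ordered set of conformational species running from the native
dimer to the unfolded monomer, connected by reversible transitions of which
exactly one is a dissociation.  The package ships three chains —

* `three_state`: N2 &#8644; I2 &#8644; 2U,
* `four_state`: N2 &#8644; I2 &#8644; I2' &#8644; 2U,
* `monomer_intermediate`: N2 &#8644; I2 &#8644; 2I &#8644; 2U,

and the solver is generic over any chain obeying the one-dissociation rule.
N2 is the native dimer, I2 and I2' partially folded dimeric intermediates,
I a partially folded protomer, U the unfolded monomer.

Each transition *i* carries a linear-extrapolation free energy

$$\Delta G_i(\mathrm{urea}) = \Delta G_i^\circ - m_i\,[\mathrm{urea}],$$

with $\Delta G_i^\circ$ the stability at zero denaturant (kcal mol⁻¹) and
$m_i$ the cooperativity index (kcal mol⁻¹ M⁻¹), proportional to the surface
area newly exposed in that step.  Equilibrium constants follow as
$K_i = \exp(-\Delta G_i / RT)$ with $R = 1.9872\times10^{-3}$
kcal mol⁻¹ K⁻¹ and $T = 298.15$ K throughout; no temperature dependence is
modelled.  Dissociation constants are expressed on a **1 M protomer
standard state**, so per-stage free energies sum directly to the total
conformational free energy $\Delta G_\mathrm{total}$.  At the pH values
where the chain starts from I2 rather than N2, the leading stage is treated
as an isomerization on the same footing; whether the original analyses used
an identical reference cannot be established from the available summaries,
and this choice is deliberately the one that keeps totals additive.

### Solving the species distribution

Writing $v$ for the concentration of the dissociation product (the first
monomeric species), mass action expresses every species as
$c_i = e^{\ell_i} v^{o_i}$ with order $o_i \in \{1, 2\}$ and a
log-coefficient $\ell_i$ accumulated along the chain.  Protomer
conservation, $\sum_i o_i c_i = P_t$, is then a quadratic
$a v^2 + b v = P_t$ solved in the cancellation-free form
$v = 2 P_t / (b + \sqrt{b^2 + 4 a P_t})$.  Coefficients are accumulated in
log space so chains spanning 24 orders of magnitude in $K$ remain exact;
should $a$ or $b$ still overflow, a bracketed root search on
$\log v$ (monotone conservation residual, tolerance $10^{-15}$) takes over.
The test suite cross-checks both paths against a brute-force oracle that
scans $v$ on a dense log grid, over a thousand random draws with
$K \in [10^{-12}, 10^{12}]$ and $P_t \in [10^{-8}, 10^{-4}]$ M.

Two signatures distinguish isomerization from dissociation and drive all
identifiability below: isomerization midpoints sit at the closed form
$\Delta G^\circ/m$ independent of protein concentration, while the
dissociation midpoint — defined as the urea where the total monomeric
protomer fraction crosses one half — moves to higher urea as $P_t$ rises
(at that point $K_\mathrm{diss} = P_t$, giving
$\mathrm{urea}_{1/2} = (\Delta G^\circ + RT\ln P_t)/m$ when upstream
species are depleted).

## Observables

Fluorescence scans are reduced to the **average emission wavelength**,

$$\langle\lambda\rangle = \frac{\sum_i I_i \lambda_i}{\sum_i I_i},$$

a scale-invariant summary that shifts red on unfolding.  AEW (rather than
intensity at a fixed wavelength) is the fitted fluorescence observable;
circular dichroism is fitted as ellipticity at its single monitored
wavelength.  The predicted signal of an equilibrium ensemble is the
**protomer-fraction**-weighted sum of per-species linear baselines,
$Y(u) = \sum_s f_s(u)\,(\alpha_s + \beta_s u)$: both fluorophore count and
residue count scale with protomers, so protomer (not particle) fractions
weight every probe.  Native and unfolded species carry intercept and urea
slope; intermediates carry intercepts only, because they are populated over
narrow urea windows in which a slope is not identifiable.

## Global fitting

All datasets at one pH — by default eleven: AEW at 280 and 295 nm
excitation for 0.5, 1, 2 and 4 µM protomer, CD for 2, 4 and 8 µM — are fit
simultaneously.  The thermodynamic parameters are *linked* (shared across
datasets); the spectroscopic baselines are *local*.  Requiring at least two
protein concentrations is what makes the dissociation stage identifiable,
and the package warns when that condition fails.

Residuals are weighted per dataset by the reciprocal of its empirical
pre-transition standard deviation (points at ≤ 1.5 M urea, linearly
detrended), falling back to the signal range when the pre-transition is
noiseless or too short.  This puts AEW traces (nanometres) and CD traces
(millidegrees) on comparable footing without requiring declared
uncertainties, and it makes the fit invariant to affine rescaling of any
single dataset.

The optimizer exploits the model's conditional linearity: given the linked
parameters, every baseline solves by weighted least squares (variable
projection), collapsing an ~70-parameter problem to the 2–6 linked ones.
The search proceeds in three phases:

1. **Screen.**  A coarse grid per stage
   ($\Delta G^\circ \in \{2, 5, 10, 15\}$, $m \in \{0.5, 1.5, 3\}$, all
   stage combinations) is evaluated exhaustively with baselines profiled
   out.
2. **Multi-start.**  Bounded Levenberg–Marquardt
   (`minpack.lm::nls.lm`, $\Delta G^\circ \in [-5, 40]$,
   $m \in [0.01, 10]$, tolerances $10^{-10}$) runs from the 20
   best-screened candidates plus any user start.  Twenty is an empirical
   choice: in four-state problems with a sub-kcal middle stage the global
   basin can rank behind a dozen shallow impostors in the screen, and
   running local fits from every grid point would only re-find basins the
   screen has already ranked.  Starts stop early once a run reaches an
   objective at the double-precision floor of the data, which no later
   start can meaningfully beat.
3. **Refinement.**  The winner is re-optimized over linked *and* local
   parameters jointly to tolerance $10^{-15}$; the covariance of the linked
   block is $s^2 (J^\top W J)^{-1}$ from this full model, with $s^2$ the
   weighted residual variance.  A rank-deficient information matrix raises
   an identifiability warning naming the unconstrained linked parameters.

On noiseless synthetic data this pipeline returns the generating parameters
to ~10⁻¹⁰ relative and standard errors collapse to zero; the model choice
(three- versus four-state) is always user-specified, never automatic.

## pH titrations

The pH-linked conformational change of the native dimer is fit with a
single-site protonation sigmoid with optional Hill coefficient,

$$Y(\mathrm{pH}) = Y_\mathrm{high} +
  \frac{Y_\mathrm{low} - Y_\mathrm{high}}{1 + 10^{\,h(\mathrm{pH} - pK_a)}},$$

applied identically to AEW-versus-pH data and to first-transition-midpoint
($\Delta G_1^\circ/m_1$) versus pH data.  The functional form is a package
choice — the source analyses defer to earlier work without reproducing an
equation — and $h$ defaults to 1 (single proton) with a `free_hill` option;
the analysis scripts report both.  The limits enter linearly and are
profiled out over a 0.05-unit $pK_a$ grid before a Levenberg–Marquardt
polish, which makes the fit equivariant under affine transforms of the
value axis.  A transition is declared absent when the value range falls
below three times a second-difference noise estimate, and a fitted $pK_a$
outside the sampled pH range ± 1 is flagged as extrapolated.

## The synthetic-data generator

Because no raw unfolding curves are deposited alongside the reference
parameter table, every pipeline stage is validated on synthetic data with
known truth.  The generator emulates the study conditions: urea 0–9 M in
0.25 M steps, the eleven-dataset probe/concentration design above, and iid
Gaussian noise per point (default noiseless; the analysis scripts use 2% of
each probe's signal range).  Refolding datasets have identical means by
construction — equilibrium reversibility — and differ only in metadata.

Default spectroscopic anchors follow the measured end states: native
emission peaks at 338/342 nm and unfolded at 347/352 nm for 280/295 nm
excitation.  Everything about the intermediates' spectra is *not* knowable
from the available summaries: their AEW intercepts (set above the native
values, matching the observed less-quenched intermediate plateau), their
Gaussian peak placement (midway, amplitude elevated ~30%) and the common
25 nm FWHM are invented fixtures, labelled non-physiological.  Peak width
is interpreted as FWHM (σ ≈ 10.6 nm): a 25 nm σ would truncate the peaks
on the 300–400 nm grid and bias the AEW, which the generator instead
detects and warns about.  The CD baselines give the two dimeric
intermediates identical values, mirroring the observation that no CD
change separates them.

What passing tests therefore show: the estimator is consistent and unbiased
*under the generator's assumptions* — linear baselines, iid Gaussian noise,
exact LEM thermodynamics, no drift.  They cannot show robustness to
urea-correlated drift, inner-filter effects, aggregation at low pH (the
modelled protein precipitates below pH 5, which is exactly why no such data
exist), or baseline curvature; none of those are modelled.

## Reference table and problem sizes

`drpcp3b_stability_table()` stores the per-pH reference estimates for the
zebrafish procaspase-3b dimer used as generator truth, with `NA` for stages
absent at a given pH; where two roundings of the pH-7 dissociation m-value
are in circulation (0.9 and 0.87 kcal mol⁻¹ M⁻¹) the table keeps the more
precise one.  The study sizes used throughout the package are deliberate
choices: global fits use 11 × 37 data points; the Monte-Carlo bias check
runs 20 noisy replicates at 2% noise (bias is required to sit within three
Monte-Carlo standard errors); the solver oracle uses 1000 random draws; and
the standard-error scaling law is probed at 0.5% and 1% noise, where its
first-order premise actually holds — at 2% noise and above the pH-7
first-stage estimate already wanders enough for curvature to change between
noise levels.

## Known limitations

* One dissociation per chain; no heterodimers, no kinetics, no thermal
  denaturation.
* The $pK_a$ is not linked into the urea-unfolding model; the two analyses
  are deliberately separate.
* Middle stages with $\Delta G^\circ$ well under 1 kcal mol⁻¹ (the
  four-state chains near neutral pH) are exactly recoverable from noiseless
  data but effectively unidentifiable at realistic noise; the fit reports
  this through its covariance rather than hiding it.
* The weighting heuristic assumes the pre-transition is flat enough to
  estimate noise after linear detrending; strongly curved pre-transitions
  would misweight.
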