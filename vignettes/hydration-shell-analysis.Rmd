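---
title: "Quantifying solute-affected water: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying solute-affected water: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroshell)
```

## The two-state model and the difference-spectra method

Isotopic dilution of D2O in H2O produces HDO, whose uncoupled OD stretching
band is a clean probe of the hydrogen-bond state of individual water
molecules. hydroshell analyses series of such spectra under the two-state
assumption: in a solution of molality $m$ (mol solute per kg water), water is
either *bulk* (spectroscopically identical to pure water, molar absorptivity
$\varepsilon_b(\nu)$) or *affected* (perturbed by the solute,
$\varepsilon_a(\nu)$), with $N$ moles of affected water per mole of solute.
With $M$ the molar mass of water (kg/mol), the fraction of affected water is
$N M m$ and

$$\varepsilon(\nu; m) = (1 - N M m)\,\varepsilon_b(\nu) + N M m\,
\varepsilon_a(\nu).$$

Because the model is linear in $m$ with intercept $\varepsilon_b$, the
affected spectrum follows from the slope of the series at infinite dilution:

$$\varepsilon_a(\nu) = \varepsilon_b(\nu) + \frac{1}{N M}
\left(\frac{\partial \varepsilon}{\partial m}\right)_{m \to 0}.$$

`slopeAtInfiniteDilution()` fits this slope at every wavenumber by least
squares with the intercept *fixed* at the measured bulk spectrum. Fixing the
intercept rather than fitting it stabilises the extrapolation when the series
has few members, which is the usual experimental situation. The per-point
residual variance of so short a series is itself a noisy quantity (a handful
of degrees of freedom), so the variance is pooled with a running mean across
neighbouring wavenumbers (`varPool`, default 21 points) before the standard
error is formed; the underlying noise level varies smoothly with wavenumber,
so pooling sharpens the error estimate without biasing it.

### Determining N by non-negativity

An absorptivity cannot be negative, and $\varepsilon_a(\nu; N)$ moves
monotonically with $N$ at every wavenumber. `determineN()` therefore returns
the smallest $N$ for which the extracted affected spectrum stays above
$-(\delta + 3\,\mathrm{se}_a(\nu))$ across the window, where $\delta$ is a
user tolerance (default 0) and $\mathrm{se}_a$ the propagated slope error.
The feasibility condition is linear in $N$, so the minimal feasible $N$ is
computed in closed form as the maximum over wavenumbers of a pointwise bound
— the exact limit of a bisection search, without grid rounding. The criterion
is identifiable only when the affected band genuinely vanishes somewhere in
the window (a negative-slope region); otherwise the function stops and asks
for an explicit $N$, which every caller accepts as an override.

For noisy series the pointwise maximum is an extreme-value statistic. In the
spectral region where the affected band is zero, however, the identity
$-\partial\varepsilon/\partial m = N M \varepsilon_b(\nu)$ holds at *every*
point, so the estimate is refined by an inverse-variance weighted regression
of $-$slope on $M\varepsilon_b$ through the origin over the near-binding
candidate set. Candidates are selected in a two-sided window of $\pm 2.5$
pointwise standard errors around the current estimate — symmetric in the
noise, so the selection does not bias the fit — and each contiguous candidate
run is eroded by five points at both ends to drop the transition zones where
the band has not quite reached zero. Two selection/refit iterations are
performed. For a noiseless series the standard errors are at rounding level,
no refinement is triggered, and the closure
$\varepsilon_a(\hat N) \equiv \varepsilon_a^{\mathrm{true}}$ holds to machine
precision — a property the test-suite asserts at $10^{-8}$.

## Two-solute mixtures: theoretical reference, shared and excess water

For a peptide–osmolyte mixture at osmolyte mole fraction $x$ (mole fractions
are taken among the solutes only), the *theoretical* affected spectrum is the
non-interacting reference: the pure-solute affected spectra combined in
proportion to their affected numbers,

$$N_{theor} = (1-x) N_p + x N_o, \qquad
\varepsilon_{theor} = \frac{(1-x) N_p \varepsilon_p + x N_o
\varepsilon_o}{N_{theor}}.$$

$\Delta N = N_{exp} - N_{theor}$ classifies the interaction: negative values
mean hydration spheres overlap and some water is *shared* between both
solutes; positive values mean *excess* water — additional molecules perturbed
only when both solutes are present. All mixture quantities are normalised per
mole of solute *pair*; the alternative (per mole of peptide) differs by a
factor $1/(1-x)$ and is easy to convert, but the per-pair convention keeps
$N_{exp}$ and $N_{theor}$ directly comparable across $x$.

### The constrained decomposition

`decomposeSharedExcess()` splits the experimental affected intensity curve
$C(\nu) = N_{exp}\varepsilon_{exp}(\nu)$ into retained pure-solute parts and
a remainder attributed to shared/excess water. The retained fractions
$(w_p, w_o) \in [0,1]^2$ maximise the retained water count

$$w_p (1-x) N_p + w_o\, x N_o \quad \text{s.t.} \quad
r(\nu) = C - w_p (1-x) N_p \varepsilon_p - w_o x N_o \varepsilon_o
\ge -\delta(\nu)\ \forall\nu,$$

i.e. as much water as possible is explained by unchanged pure-solute
hydration, and only the spectroscopically unexplainable remainder $r$ is
called shared/excess. This "maximal retention" objective is the only
assignment under which the remainder cannot be reduced by attributing more
intensity to the pure components; the non-interacting construction then
yields $w_p = w_o = 1$ and $r \equiv 0$ exactly. Degenerate optima are broken
by maximising $w_p + w_o$, then preferring $w_p = w_o$. The feasible set is
the intersection of half-planes, and the objective is concave and piecewise
linear along $w_p$ after eliminating $w_o$; the solver scans a two-stage grid
with local refinement, and the test-suite keeps an exhaustive
$(w_p, w_o)$-grid oracle that the solver must never be beaten by.

The water bookkeeping $w_p(1-x)N_p + w_o x N_o + N_{sh} = N_{exp}$ holds
exactly by construction; the shared/excess spectrum is $r/N_{sh}$ and its
intensity share is $100\int r\,d\nu / \int C\,d\nu$.

Three numerical guards matter on real (noisy) inputs:

* **Joint smoothing** (`smooth`): a Savitzky–Golay filter (cubic, default
  window 41 points at 1 cm$^{-1}$) applied *identically* to $C$ and to both
  component curves. The filter is linear, so it commutes with the mixture
  bookkeeping — the weights are unchanged in expectation — while the
  constraint noise shrinks several-fold.
* **Constraint slack** (`delta`): `decompositionTolerance()` supplies
  $1.75\,\mathrm{se}_C(\nu) + \mathrm{se}_N\,\varepsilon_b(\nu)$ — the
  propagated error of the intensity curve plus the bulk-shaped leak of the
  $N_{exp}$ uncertainty. The multiplier was calibrated on simulated series:
  smaller slack lets downward noise dips crush the retained weights (shares
  biased high), larger slack lets absent components creep in (weights biased
  high). 1.75 standard errors balances the two at realistic noise.
* **Support floor** (`supportFloor`, default 1 % of the joint component
  maximum): wavenumbers where both pure components are essentially zero carry
  no information about the weights — the constraint ratio there degenerates
  to noise over noise — and are excluded from the constraint set (not from
  the remainder or the share integral).

The $\Delta N$ label uses a tolerance equal to the quadrature sum of the two
affected-number uncertainties (floored at $10^{-6}(N_{exp}+N_{theor})$ so
that rounding-level differences are reported as "none").

## Band parameters and O–O distance distributions

`bandParameters()` reports the band position at maximum (parabolic refinement
through three points), the gravity centre $\nu^g = \int\nu\varepsilon\,d\nu /
\int\varepsilon\,d\nu$ (a proxy for the mean hydrogen-bond energy), the full
width at half height (linear interpolation of the half-maximum crossings;
with more than two crossings the outermost pair is used under a warning), and
the trapezoid integrated intensity.

`toDistanceDistribution()` converts a band into the probability density of
oxygen–oxygen distances between hydrogen-bonded waters through an empirical
monotone correlation $\nu(R)$:

$$P(R) = \varepsilon(\nu(R))\,\left|\frac{d\nu}{dR}\right| / Z,$$

normalised to unit area on a 0.001 Å grid over the overlap of the band
support and the calibration domain. Because the Jacobian weights the band
non-uniformly, orderings can invert: a band peaking at a *higher* wavenumber
can still have its most likely O–O distance at a *smaller* $R$ when it
carries a heavy red shoulder — the transform is band-shape dependent, which
is also why the calibration cannot be reverse-engineered from (band position,
distance mode) pairs.

The correlation is supplied as a knot table (`R_angstrom,nu_cm1`, monotone
cubic interpolation with Hyman filtering). The package ships
`synthetic_od_oo_calibration.csv`, a synthetic table assembled to follow the
slope and range of published ice/hydrate-type correlations (roughly 900–1300
cm$^{-1}$/Å around 2.7–2.85 Å, flattening towards the free-OD limit near
2727 cm$^{-1}$); it is a placeholder so that the machinery is runnable
end-to-end, and every report records which calibration produced its
distances. For quantitative distances, replace it with a laboratory
calibration. Small negative intensities from noise are clipped to zero
before normalisation and the clipped fraction is logged in the result
metadata.

## Trajectory solvation-shell statistics

The trajectory side works on orthorhombic boxes under the minimum-image
convention; atom indices are 1-based.

* `geometricCenter()` unwraps a fragment minimum-image relative to its first
  atom before averaging; fragments wider than half the box are ambiguous and
  rejected.
* `rdfAroundCenter()` estimates $g(r) = (V/N)\,dN/dV$ around the fragment
  centre by shell-volume normalised histogramming (default bin 0.1 Å, range
  capped at half the smallest box length). Poisson standard errors
  ($g/\sqrt{\mathrm{count}}$) accompany every bin.
* `angleDistribution()` bins, per probe distance shell, the angle between a
  probe bond vector (e.g. urea C=O or TMAO N–O) and the vector from the
  probe's reference atom to the fragment centre; each distance bin is
  normalised to unit area over degrees (default 5° bins). Isotropically
  oriented probes give the $\sin\theta/2$ density; empty bins are flagged
  rather than NaN-filled.
* `countHBonds()` / `shellHBondStats()` use a geometric hydrogen-bond
  criterion — O···O $\le$ 3.5 Å and H–O···O angle at the donor $\le$ 30°,
  standard literature values, both configurable and echoed into every result
  — and classify waters as shell (oxygen within 4.0 Å of any solute heavy
  atom, closed interval at the boundary) or bulk reference. Unordered oxygen
  pairs are counted once.

## What the synthetic generators emulate — and what they do not

`makeBinarySeries()` and `makeTernarySeries()` produce series that obey the
two-state mixture model *exactly*, built from pseudo-Voigt bands
(asymmetry by multi-component sums). Affected bands are "zero-anchored":
clipped at a small fraction (default 2 %) of their maximum so that they
vanish identically in the far wings — the feature that makes $N$
identifiable by non-negativity, mirroring real affected spectra that decay to
zero inside the analysis window. Defaults emulate an OD-stretch study: bulk
band at 2509 cm$^{-1}$ with fwhh 162 cm$^{-1}$ and integrated intensity
$\approx 10^4$ dm$^3$mol$^{-1}$cm$^{-2}$; a peptide-like solute with
$N = 6$ and a red-shifted two-component band; an osmolyte-like (urea-like)
solute with $N = 2.7$ and a slightly blue-shifted band. Series molalities
default to 0.5–2.5 mol/kg in five steps, typical of difference-spectra work
on these solutes; noise is multiplicative Gaussian (relative sigma), applied
to the solution spectra while the bulk reference is treated as noise-free
(in practice it is measured once with far higher effective signal-to-noise).
`makeTrajectory()` covers uniform gases, exact-distance shells, H-bonded
water lattices with known bond counts, and oriented diatomic probes.

What passing these tests shows: the estimators are unbiased and correctly
calibrated *under the two-state model with smooth multiplicative noise*.
What they do not show: robustness to baseline drift, atmospheric residuals,
concentration-dependent band shifts (breakdown of the two-state picture at
high $m$), HDO-molarity errors, or instrument lineshape effects — none of
which the generators emulate. The trajectory generators likewise contain no
physical water structure; they validate counting and normalisation, not
force fields.

## Degenerate inputs and edge conventions

* A spectrum needs $\ge 2$ points, strictly ascending grid (descending input
  is reversed; duplicated wavenumbers are an error).
* `determineN()` on a series with no negative-slope region beyond noise:
  unidentifiable, explicit error.
* Decomposition with $x = 0$ or $x = 1$: the absent component's weight is
  unconstrained and settled by the tie-break rules.
* $N_{sh}$ below $10^{-6} N_{exp}$ (the solver's resolution): the shared
  spectrum is reported as zero rather than a noise quotient.
* Experimental curves whose negative intensity beyond the tolerance exceeds
  1 % of the total intensity: validation error (data problem, not noise).
* RDF bins with zero counts have undefined standard errors (`NA`), not zero.

## Problem sizes used in the shipped checks

The bundled tests and the acceptance script run at the study scale the
package targets: 601-point spectra (2200–2800 cm$^{-1}$ at 1 cm$^{-1}$),
five molalities, 50-seed Monte-Carlo repeats for the noisy recoveries, and
trajectories of 200 frames × 1000 atoms (RDF) or 50 frames × 2000 probes
(orientation statistics). A full run of both completes in well under a
minute on a single core.

## Known limitations

* The non-negativity rule for $N$ is one defensible reconstruction of the
  infinite-dilution method; laboratories using a different criterion should
  pass their $N$ explicitly.
* The bundled frequency–distance calibration is synthetic (see above);
  distance values are only as good as the calibration supplied.
* Only orthorhombic boxes are supported on the trajectory side, and no
  dynamical quantities (residence times, H-bond lifetimes) are computed.
* The decomposition fits exactly two pure components; it does not assign
  shared water to specific molecular contacts.
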