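---
title: "Slab-model co-refinement of contrast-variation neutron reflectometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slab-model co-refinement of contrast-variation neutron reflectometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slabnr)
```

## The measurement and the model

Specular neutron reflectometry measures the reflectivity $R(Q)$ of an
interface as a function of momentum transfer $Q = 4\pi\sin\theta/\lambda$
(Å$^{-1}$).  For a supported lipid bilayer (SLB) at the Si/water
interface, $R(Q)$ encodes the scattering-length-density (SLD) profile
perpendicular to the surface.  `slabnr` models that profile as a stack of
homogeneous slabs, each described by four numbers: thickness $d$ (Å),
intrinsic SLD $\rho$ ($10^{-6}$ Å$^{-2}$), solvent volume fraction
$\phi$, and the Gaussian roughness $\sigma$ (Å) of its substrate-side
interface.  Solvent penetration mixes SLDs linearly,
$\rho_\mathrm{eff} = \phi\,\rho_\mathrm{solv} + (1-\phi)\,\rho$.

Reflectivity is computed exactly by the Abeles optical matrix method: in
layer $n$ the perpendicular wavevector is
$k_n = \sqrt{(Q/2)^2 - 4\pi(\rho_n - \rho_\mathrm{Si})}$ (complex in
evanescent regions), interface Fresnel coefficients
$r_n = (k_n - k_{n+1})/(k_n + k_{n+1})$ are damped by the Névot–Croce
factor $\exp(-2 k_n k_{n+1} \sigma_{n+1}^2)$, and the characteristic
matrices are multiplied from the silicon fronting to the solvent
backing.  The same physics coded independently as a Parratt recursion
serves as a cross-check in the test suite; the two agree to a relative
$10^{-10}$ on random stacks.

Névot–Croce damping was chosen over error-function sub-slab slicing
because it is exact to first order for $\sigma \ll d$, is what generic
slab-fitting software applies, and keeps the kernel fast.  Its known
limitation is that $\sigma$ approaching the thickness of an adjoining
layer stretches the approximation; the stack constructor warns (and does
not fail) in that regime, which real SLB fits do visit.

Time-of-flight resolution is handled by Gaussian smearing with constant
$\Delta Q/Q$ (FWHM; default 0.08): each model point is averaged over 21
quadrature nodes spanning $\pm 3.5\sigma_Q$ with
$\sigma_Q = (\Delta Q/Q)\, Q/2.355$.  An optional constant background
(default $10^{-7}$) is added to every model curve; the synthetic data
carry the same background, so fits are unbiased at high $Q$ where the
signal approaches it.

## SLDs from composition

Layer SLDs can be computed from elemental composition:
$\rho = \sum_i b_i / V$ with tabulated bound coherent scattering lengths
(H $-3.739$, D $6.671$, C $6.646$, N $9.36$, O $5.803$, P $5.13$ fm).
Water is assigned a 30.0 Å$^3$ molecular volume for both isotopologues,
giving the endpoints $-0.56$ and $6.38\times10^{-6}$ Å$^{-2}$; solvent
mixtures interpolate linearly in D$_2$O volume fraction.

The bundled fragment library covers the three headgroup classes of an
*E. coli* polar extract — PE, PG and cardiolipin at mole fractions
0.75/0.13/0.12 — with cardiolipin counted per molecule (four chains,
double glycerophosphate head).  Headgroup labile hydrogens (PE 3, PG 3,
CL 2 by default; all configurable in the plain-text library) take the
solvent's H/D ratio, which is why the headgroup SLD is
contrast-dependent while the tail SLD is not.  A per-deuterated extract
swaps every non-labile H for D, raising the tail SLD from about $-0.3$
to about $6.8\times10^{-6}$ Å$^{-2}$.

Fragment volumes are genuinely uncertain for natural extracts.  The
equal-area constraint (below) uses POPC reference volumes
($V_\mathrm{head} = 319$ Å$^3$, $V_\mathrm{tails} = 937$ Å$^3$) because
POPC is exceptionally well characterised and shares the dominant
16:0/18:1 chain architecture.  With these defaults the coupled headgroup
hydration computed from a 7 Å head on a 27 Å/12% tail region is about
42%, whereas fits of such bilayers typically report around 35%; the gap
reflects the volume choices, is documented rather than hidden, and both
volumes are user-configurable.  For the same reason the recovery studies
anchor layer SLDs at the preset (fitted-literature) values rather than
at the composition-calculated ones, and the fit exposes a bounded
($\pm 0.5\times10^{-6}$) additive SLD offset rather than a free SLD.

## The two bilayer parameterizations

**Three-layer (hydrogenated bilayer).**  SiO$_2$ | water gap
($\phi = 1$) | head | tail | head | solvent.  The two head slabs are
constrained to be identical, and the headgroup solvent fraction is never
fitted: requiring identical mean molecular areas for heads and tails,

$$A = \frac{2 V_\mathrm{tails}}{d_t (1-\phi_t)}, \qquad
  \phi_h = 1 - \frac{V_\mathrm{head}}{d_h A},$$

fixes it from the tail region (the factor 2 because the tail slab holds
the chains of both leaflets).  Free parameters: water-gap thickness,
head and tail thicknesses, tail solvent fraction, one tied roughness for
all film interfaces, and the head SLD offset.  If a parameter
combination drives $\phi_h$ outside $[0,1]$ the builder clamps it and
reports a violation magnitude, which the objective converts into a
smooth quadratic penalty ($10^6 v^2$) — an optimiser can then walk out
of the unphysical region instead of crashing.

**One-layer with sparse vesicles (per-deuterated bilayer).**  A single
bilayer slab (the head/tail contrast is weak when the whole lipid is
deuterated) plus an optional extension representing a small population
of unfused vesicles sitting on the membrane: one further pure-water gap
and one dilute bilayer slab whose thickness and SLD are tied to the SLB
and whose lipid fraction is the vesicle *coverage*.  Only the flat part
of a bound vesicle is registered coherently, which justifies modelling
it as a single aligned slab.  The extension can be active in no
contrast, all contrasts, or only the H$_2$O contrast — the last mirrors
loosely bound vesicles being rinsed away by the first solvent exchange.
The switch keys on the D$_2$O fraction ($\le 0.05$) rather than dataset
order, so the objective is invariant under reordering of the datasets.
The gap's lower interface carries the SLB roughness and only the diffuse
vesicle slab carries its own (larger) roughness; with zero coverage the
extension is then exactly invisible, a property the tests check to
$10^{-10}$.

## Co-refinement

All contrasts are fitted simultaneously with every structural parameter
shared; only the solvent SLD and the exchanged headgroup SLD differ
between contrasts.  The objective is

$$\chi^2 = \sum_c \sum_Q
  \left(\frac{R_\mathrm{model}(Q) - R_c(Q)}{\Delta R_c(Q)}\right)^2,$$

with 5% relative weights where a dataset quotes no uncertainty.
Optimisation is bounded quasi-Newton (`nlminb`) repeated from eight
starts — the nominal start plus seeded uniform $\pm 20\%$ jitter — and
the lowest-$\chi^2$ solution wins; exact ties break to the
lexicographically smallest parameter vector so that results are
bit-reproducible for a given seed.  Whether the four contrasts should be
fitted simultaneously or sequentially is genuinely open in practice; we
default to simultaneous sharing because it is what makes contrast
variation informative, and the single-contrast alternative is available
by passing one dataset.

Uncertainties default to a residual bootstrap (100 resamples):
standardized residuals are resampled within each contrast, added back to
the best-fit curve, and the model is refitted from the optimum.
Standardization matters — reflectivities span six decades, so raw
residuals cannot be exchanged between $Q$ points.  A profile-$\chi^2$
method ($\Delta\chi^2 = 1$ crossings with the other parameters
re-optimised) is available as a cross-check.  Model variants are
compared on reduced $\chi^2$; an extension is reported as *necessary*
when it improves the simpler model's reduced $\chi^2$ by a configurable
factor (default 1.3) on identical data.

## What the synthetic generator does and does not emulate

`simulate_contrast_series()` produces one dataset per water contrast
from a ground-truth model on a logarithmic $Q$ grid spanning the union
of per-angle bands of a two-angle time-of-flight reflectometer
(wavelengths 2–30 Å; 0.624°/3.78° for the FIGARO-like preset, clipped to
0.005–0.3 Å$^{-1}$; 0.8°/3.2° for the D17-like preset).  Noise is
multiplicative Gaussian, $R(1+\epsilon)$ with
$\epsilon \sim N(0, \sigma_\mathrm{rel})$ and $\sigma_\mathrm{rel} =
0.03$ by default, plus the constant background; quoted uncertainties are
$\Delta R = \sigma_\mathrm{rel} R + b$.  This emulates the magnitude
structure of counting statistics without simulating wavelength-dependent
flux, detector efficiency, or Poisson statistics at low count rates.
Consequently, passing recovery tests demonstrates that the analysis
chain is unbiased and well-conditioned under realistic noise magnitudes
and resolution — not that it is robust to instrument artefacts
(misalignment, imperfect footprint correction, structured backgrounds)
that real data can carry.

Three ground-truth presets are bundled, representing fitted structures
of hydrogenated and per-deuterated *E. coli*-extract SLBs reported in
the literature: a symmetric three-layer bilayer (7/27/7 Å, 12% tail
solvent, 4 Å roughness, head SLD 1.55/2.16 in H$_2$O/D$_2$O, tail
$-0.55$), and two one-layer deuterated bilayers (41–42 Å, SLD 6.60–6.66)
with sparse (3–4%) vesicle layers.  Published fits of the deuterated
50 °C structure report the SLB roughness inconsistently as 10 Å
(tabulated) and 7 Å (narrative); the preset adopts 7 Å, the value
consistent with the headgroup length scale, and keeps 10 Å for the
diffuse vesicle slabs.

## Numerical choices and degenerate inputs

* Reflectivity is clipped to $\le 1$ within $10^{-12}$; totals below the
  critical edge are exact to the same order.
* The smearing quadrature guards against non-positive $Q$ nodes at the
  lowest grid points by clamping, which affects only the far tail of the
  resolution kernel.
* Zero-thickness slabs, zero-contrast stacks and $\phi = 1$ layers are
  all legal inputs and reduce analytically (the tests pin these down).
* The substrate (SiO$_2$ thickness 12 Å, roughness 3 Å, SLD 3.47; Si
  2.07) is treated as characterised and held fixed during bilayer fits,
  as one would after a bare-block measurement; all four values are
  configurable.
* Problem sizes: the recovery studies use the four-contrast FIGARO-like
  grid (about 73 points per contrast); unit tests of the optimiser use
  coarser 12–15 points-per-decade grids, which preserve the physics
  while keeping the suite quick.

## Known limitations

Single uniform slabs cannot express asymmetric leaflets or headgroup
sublayer structure; no off-specular or magnetic scattering; no
instrument-specific raw-data reduction (inputs are reduced $R(Q)$
columns); the vesicle extension models only the aligned flat part of
bound vesicles and says nothing about their size distribution; and MCMC
posterior exploration is deliberately out of scope — the bootstrap and
profile intervals cover the reporting needs of slab fits, and the
objective interface does not preclude plugging in a sampler.
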