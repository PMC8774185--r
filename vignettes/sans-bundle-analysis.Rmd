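---
title: "Solution-state analysis of helix-bundle unfolding by SANS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solution-state analysis of helix-bundle unfolding by SANS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlesans)
```

## The problem

A four-alpha-helix bundle protein such as cytochrome c' can populate several
distinct solution states as conditions change: a compactly folded dimer near
neutral pD, a fully unfolded random coil at strongly acidic pD, and -- most
interestingly -- a monomeric *open-bundle* intermediate at strongly alkaline
pD, in which the four helices persist but the inter-helix packing is lost.
Small-angle neutron scattering (SANS) distinguishes these states because it
measures, in one dilute-solution experiment, the overall size (radius of
gyration, Rg), the association state (through the forward intensity I(0)),
and the shape class (through the momentum-transfer dependence of the
intensity).

`bundlesans` implements the complete analysis chain for this problem: the
model-free transforms, the pair-distance inversion, theoretical curves from
crystal structures, and a dedicated *joint-clubs* form factor for the
open-bundle state, plus a generator of realistic synthetic data so that every
stage is testable without any experimental download.

## Model-free analyses

**Guinier.** For a dilute monodisperse solution,
$I(Q) \approx I(0)\,e^{-Q^2 R_g^2/3}$ at low $Q$. `guinier_fit()` performs a
weighted linear regression of $\ln I$ on $Q^2$ inside a window given in
$Q^2$; the default window of $0.001$--$0.002\ \mathring{A}^{-2}$ suits a
folded protein of a few tens of kDa but is an ordinary argument, not a
constant. The conventional $QR_g \le 1.3$ validity guideline is reported and
can be flagged, but deliberately never fails the fit: unfolded states are
routinely and usefully fit beyond it, at the price of a downward bias in
$R_g$ that the user sees in the reported `qrg_max`.

**Debye coil.** A Gaussian chain has the closed form
$I(Q) = I(0)\, \frac{2(e^{-u} + u - 1)}{u^2}$, $u = (QR_g)^2$.
`debye_fit()` fits $(I(0), R_g)$ by weighted nonlinear least squares, with a
series expansion below $u = 10^{-4}$ to avoid cancellation and a restart grid
over $R_g \in \{5, 10, 20, 40, 80\}\ \mathring{A}$ when the
Guinier-initialized start fails.

**Kratky.** The transform $Q^2 I(Q)$ separates compact from coil-like
scatterers: a compact globule gives a low-$Q$ bell, an ideal coil a flat
high-$Q$ plateau at $2 I(0)/R_g^2$. The published descriptions of these
shapes are qualitative, so the feature thresholds here are explicit package
choices, all exposed as arguments: a bell is a local maximum of the smoothed
transform below $0.15\ \mathring{A}^{-1}$ exceeding the high-$Q$ median by at
least 25%; a plateau requires the relative drift of the smoothed transform
above $0.2\ \mathring{A}^{-1}$ to stay within $\pm 20\%$. Curves showing
both features -- or neither, which happens for elongated-but-rigid particles
whose cross-section decay defeats both detectors -- classify as
`partially_flexible`, the honest middle ground.

**Molecular-weight ratio.** At fixed contrast, $I(0) \propto M\,C$, so
$M/M_{st} = \frac{I(0)/C}{I(0)_{st}/C_{st}}$ against a standard sample.
`mw_ratio()` reports the full-precision value together with a half-up
1-decimal rounding, which is the convention used when such ratios are
tabulated. No absolute calibration is attempted; only ratios are meaningful
here, which also makes every analysis in the package scale-covariant.

**Trace aggregation.** A slight low-$Q$ upturn is modeled by
`aggregate_fraction()` as a second Guinier population of fixed large
$R_g$ (default 100 Angstrom). Converting the fitted intensity ratio to a
number fraction assumes per-particle $I(0) \propto V^2$ and
$V \propto R_g^3$; both assumptions are echoed in the result object because
the answer -- typically a fraction of a percent -- is only meaningful at
order-of-magnitude precision.

## Pair-distance distribution

`ift()` inverts $I(Q) = 4\pi \int_0^{D_{max}} P(r)\,\mathrm{sinc}(Qr)\,dr$
on a basis $\phi_n(r) = r \sin(n\pi r/D_{max})$, $n = 1..20$ by default,
which vanishes at both endpoints by construction. The coefficients solve a
weighted least-squares problem with a second-derivative roughness penalty
$\alpha$; negative excursions of $P(r)$ are permitted but carry a tenfold
penalty, applied in a few reweighting passes. With `alpha = "auto"` the
weight is picked at the corner (maximum discrete curvature) of the L-curve
of residual norm against roughness norm, a reproducible stand-in for the
interactive perceptual criteria of the classic IFT programs. $R_g$ and
$I(0)$ come from the moments of the returned distribution -- so the
extrapolation to $Q = 0$ uses the basis, never the data, which matters when
the fitted window starts at $0.05\ \mathring{A}^{-1}$ -- with uncertainties
from the posterior covariance of the coefficients.

$D_{max}$ is a required user input. `scan_dmax()` assists by tabulating
reduced chi-square, $R_g$, and a quality score (sign changes of $P(r)$ plus
the endpoint slope) over a candidate grid; it deliberately makes no
automatic choice, because on coil-like data the chi-square decreases
monotonically with $D_{max}$ and only the elbow is meaningful.

## Theoretical curves from coordinates

`debye_sum_curve()` computes
$I(Q) = \sum_{ij} f_i f_j\, \mathrm{sinc}(Q r_{ij})$ with neutron
amplitudes $f_i = b_i - \rho_s V_i$: coherent scattering lengths, a
displaced-volume term with per-element van der Waals volumes, and a solvent
scattering-length density interpolated between H2O and D2O. Crystal
structures usually lack hydrogens, so a united-atom scheme folds each
residue's hydrogen inventory into its heavy atoms, counting labile
hydrogens as deuterium with probability `exchange_fraction` (default 0.9 in
D2O). No hydration-shell term is included; for a compact protein this
shifts $R_g$ by a few tenths of an Angstrom, which the package's
consistency checks (coordinate $R_g$ versus Guinier $R_g$ of the computed
curve, agreement within 1 Angstrom) absorb. The exact $O(N^2)$ sum is the
default; a distance-histogram acceleration (bin width 0.1 Angstrom,
kernel evaluated at each bin's mean pair distance) agrees with it to better
than 0.1% and is preferred above ~10^4 atoms.

Helix geometry supports the structural interpretation: the helix axis is
the dominant principal component of the C-alpha coordinates in a residue
range, the length is the peak-to-peak C-alpha projection onto that axis,
and the diameter is twice the radial RMS distance of the backbone atoms
(N, C-alpha, C, O) from the axis. The C-alpha-extent convention is a
package choice among several reasonable ones; it reproduces ideal generated
helices to a fraction of an Angstrom (a 20-residue, 1.5-Angstrom-rise test
helix measures 28.5 Angstrom).

## The joint-clubs model

The open-bundle state is modeled as `n_clubs` identical rigid cylinders
("clubs" -- the helices) of length $L$ and **diameter** $R$, joined
end-to-end by short loops of length `loop_gap` (default 5 Angstrom,
matching the 3--7 residue inter-helix loops; fixed, not fitted, to keep the
fit at two structural parameters). The diameter convention for $R$ is the
single most consequential one in the package and is asserted in the
documentation: internally the cylinder radius is $R/2$.

The intensity is a Monte-Carlo conformational average. Joint orientations
are drawn uniformly on the sphere, rejecting consecutive-axis angles of 150
degrees or more to prevent a club folding back through its predecessor --
an explicit, documented approximation to the unknown true joint-angle
distribution. Each rigid conformation is orientationally averaged with the
analytic cylinder amplitude, for axis angle $\gamma$ and radius $r = R/2$,
$A(Q, \gamma) = \mathrm{sinc}\!\left(\tfrac{QL\cos\gamma}{2}\right)\cdot
\frac{2 J_1(Qr\sin\gamma)}{Qr\sin\gamma}$, and inter-club phase
factors over a Fibonacci-sphere grid (128 directions by default); because
every conformation already carries a random global orientation, the
residual quadrature error averages out across the ensemble. A single club
reproduces the classical orientationally averaged cylinder form factor to
better than $10^{-4}$ relative, and the $Q \to 0$ limit is exactly
`scale + background`.

`joint_clubs_fit()` draws the conformational ensemble once per fit (common
random numbers), so the objective is deterministic and smooth in $(L, R)$;
scale and background are profiled out linearly at every step, leaving a
two-parameter search (L-BFGS-B, with a 3x3 restart grid over
$L \in \{20, 30, 40\}$, $R \in \{8, 10, 14\}$). Parameter errors come from
the numeric Jacobian at the optimum inflated by the root reduced
chi-square. Defaults are 2000 conformations for fitting and 20000 for
final curves; every fit object records its seed.

## Synthetic data and what it does (not) show

`generate_curve()` evaluates an exact model -- sphere, Gaussian coil,
cylinder, joint-clubs chain, two-population Guinier mixture, or weighted
mixtures -- on a grid (default $0.01$--$0.45\ \mathring{A}^{-1}$, 120
points, covering a Guinier region plus the working window of a typical SANS
measurement) and perturbs it with Gaussian noise
$\sigma(Q) = I(Q)\,(\text{floor} + k/\sqrt{I(Q)\,t_{eff}})$. The defaults
(1% floor, $k = 8\times 10^{-4}$) were chosen once to give roughly 3%
relative error at $0.25\ \mathring{A}^{-1}$ on a folded-dimer-scale curve,
matching how published SANS error bars at ~5 mg/mL behave. Ground truth is
returned alongside (and written as a JSON sidecar by `write_generated()`),
so recovery tests never parse truth from filenames.

`generate_bundle_scenarios()` emits the four canonical states -- coil
(Rg 25), folded dimer (globular, Rg 18), a 9:1 dimer:monomer mixture, and
an open-bundle chain (L 31.5, R 10.6, four clubs) -- with forward
intensities scaled so the dimer's $I(0)/C$ is exactly twice the monomer's.
What passing these tests shows is that the estimators are correct and the
state logic coherent under the stated noise model; what they do not show is
robustness to instrument resolution smearing, inter-particle structure
factor at high concentration, or imperfect buffer subtraction, none of
which the generator emulates (resolution smearing is explicitly out of
scope throughout the package).

## The pipeline and its state rules

`run_pipeline()` runs Guinier, Kratky, P(r), a Debye fit, and optionally a
joint-clubs fit per condition, takes MW ratios against a designated
standard condition, and assigns a state. The ratio bands (dimer at
$\ge 1.7$, monomer at $\le 1.3$) are package discretizations of the
empirically observed clustering of such ratios near 1 and 2; both are
arguments. The open-bundle call additionally requires a
`partially_flexible` Kratky class and a joint-clubs fit that beats the
Debye fit in reduced chi-square -- the same two pieces of evidence a
practitioner would cite. Every assignment carries at least two evidence
strings; all numbers in the written report are copied from stage results.

## Numerical choices and limitations

* Problem sizes in the shipped tests are chosen for a laptop-class run:
  Monte-Carlo ensembles of 300--5000 conformations, 100-replicate noise
  ensembles, 120--200 point curves. The estimators themselves have no such
  limits.
* Negative intensities are retained throughout and only masked under
  logarithms (Guinier); the IFT weights them like any other point.
* `sinc(0) = 1` is handled by series everywhere; Debye sums accumulate in
  extended precision.
* The aggregate-fraction estimate and the joint-angle distribution of the
  joint-clubs chain are stated approximations; both are parameterized so
  that better-informed choices can be substituted without code changes.
* The Guinier window, P(r) window, and $D_{max}$ remain scientific choices
  of the analyst. The package reports enough diagnostics ($QR_g$, L-curve
  $\alpha$, chi-square, quality scores) to make those choices auditable,
  but does not automate them.
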