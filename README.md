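# bundlesans

Solution-structure analysis of small-angle neutron scattering (SANS) curves
for helix-bundle proteins and their unfolding intermediates.

## The problem

A four-α-helix bundle protein (the motivating case is cytochrome c′) can
populate several distinct solution states as pD changes: a compactly folded
dimer near neutral pD, a fully unfolded random coil under strong acid, and a
monomeric **open-bundle** intermediate under strong alkali, in which the four
helices survive but their mutual packing is lost. Dilute-solution SANS
resolves these states in a single experiment because it reports

* overall size — the radius of gyration `Rg` from the Guinier law
  `I(Q) ≈ I(0)·exp(−Q²Rg²/3)` and from the pair-distance distribution `P(r)`;
* association state — the forward intensity `I(0) ∝ MW·C`, so the ratio
  `(I(0)/C) / (I(0)_st/C_st)` against a standard sample measures relative
  molecular weight;
* shape class — the Kratky transform `Q²·I(Q)` (bell = compact,
  high-Q plateau = coil), the Debye coil function
  `I(Q) = I(0)·2(e^{−u}+u−1)/u²` with `u = (QRg)²`, and, for the
  open-bundle state, a **joint-clubs** form factor: four rigid cylinders
  (length `L`, diameter `R`) joined end-to-end by short loops, with
  Monte-Carlo averaging over joint orientations and fitting of `(L, R)`.

The package covers the full chain: curve and PDB I/O, the model-free
analyses, a regularized indirect Fourier transform to `P(r)` (Moore sine
basis, L-curve regularization), theoretical neutron curves from atomic
coordinates (contrast-weighted Debye sum with united-atom hydrogens and
D₂O exchange), helix-axis geometry, the joint-clubs model, a synthetic-data
generator with counting-statistics noise, and a per-condition pipeline that
assigns solution states from the combined evidence.

## Worked example

Generate the four reference scenarios and run the pipeline (the standard
condition is the acid-unfolded coil):

```r
library(bundlesans)
sc <- generate_bundle_scenarios(seed = 11)
conds <- list(
  condition_config(sc$coil$curve,         "pD 1.7", 5.5, standard = TRUE,
                   model = "debye",       dmax = 100),
  condition_config(sc$folded_dimer$curve, "pD 6.4", 5.5, model = "none", dmax = 50),
  condition_config(sc$dissociating$curve, "pD 9.6", 5.3, model = "none", dmax = 50),
  condition_config(sc$open_bundle$curve,  "pD ~13", 5.3, model = "joint_clubs",
                   dmax = 90, jc_init = joint_clubs_params(30, 10, 4)))
run_pipeline(conds, seed = 3, n_conformations = 600)
```

```
State report
  pD 1.7         -> random_coil
      - MW ratio 1.00 (monomer band)
      - Kratky classification: random_coil
  pD 6.4         -> folded_dimer
      - MW ratio 1.90 (dimer band)
      - Kratky classification: folded
  pD 9.6         -> folded_dimer
      - MW ratio 1.86 (dimer band)
      - Kratky classification: folded
  pD ~13         -> open_bundle_monomer
      - MW ratio 0.93 (monomer band)
      - Kratky classification: partially_flexible
      - joint-clubs chi2_red 0.9 vs Debye 30.3
```

Reading the report: the coil is its own standard (ratio 1); the folded
conditions scatter twice as strongly per concentration and show bell-shaped
Kratky profiles (dimer); the alkaline condition scatters like a monomer,
is neither cleanly folded nor a pure coil, and is fit far better by the
jointed-cylinder chain than by a Gaussian coil — the open-bundle signature.
Fitting the open-bundle curve directly recovers the generating geometry:

```r
fit <- joint_clubs_fit(sc$open_bundle$curve, joint_clubs_params(25, 12, 4),
                       n_conformations = 800, seed = 5)
fit
#> Joint-clubs fit (n_clubs = 4): L = 31.8 +/- 0.2 A, R = 10.9 +/- 0.1 A
#>   scale = 0.07622, background = 0.0001048, chi2_red = 0.965, seed = 5, 800 conformations
```

A thin command-line front end over the same functions is installed at
`inst/cli/bundlesans.R` (subcommands `guinier`, `debye`, `kratky`,
`mwratio`, `pr`, `theory`, `jointclubs`, `simulate`, `run`).

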