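---
title: "Methods: CSP titration analysis and dissociation-constant estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSP titration analysis and dissociation-constant estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspfit)
```

## The measurement

A protein–ligand titration followed by ¹H-¹⁵N HSQC yields one amide peak per
residue per titration point. When binding kinetics are fast on the chemical
shift timescale, each peak sits at the population-weighted average of its
free and bound positions and migrates along a straight line from the free
shift toward the bound shift as the ligand concentration increases. The
per-residue binding readout is the weighted shift distance relative to the
free spectrum,

$$\Delta\delta_w = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2},$$

with a weight that compresses the ~10× wider ¹⁵N scale onto the ¹H scale.
`cspfit` defaults to $\alpha = |\gamma_N/\gamma_H| = 0.1014$, the most
literal gyromagnetic-ratio weighting; the widely used empirical values 0.14
and 0.154 are available through the `alpha` argument of every function that
computes shift distances. The choice rescales the ¹⁵N contribution but does
not change which residues stand out, and the fitted $K_d$ is invariant up to
the per-residue amplitude.

Peaks that broaden away mid-titration (intermediate exchange) have biased
positions, so the package treats them strictly: they are flagged `missing`
in CSP profiles, never imputed, excluded from every curve fit and from
hotspot statistics, and reported separately as qualitative binders.

## Single-site model with ligand depletion

The titrations this package targets run protein at 0.08–0.78 mM, which is
the same order as the dissociation constants being estimated, so the free
ligand concentration is materially below the total and the hyperbolic
isotherm is wrong. With total protein $a$, total ligand $b$, ratio
$x = b/a$, the 1:1 equilibrium gives the quadratic ("ligand depletion")
binding curve

$$y = \frac{\Delta\delta_\infty}{2}\Big(B + x - \sqrt{(B+x)^2 - 4x}\Big),
  \qquad B = 1 + K_d/a,$$

which equals $\Delta\delta_\infty$ times the bound fraction of protein.
`single_site_shift()` implements this closed form;
`single_site_oracle()` solves the same equilibrium numerically by bisection
on the mass balance and shares no algebra with it. The two agree to below
$10^{-9}$ ppm across the parameter grid the tests sweep, which is the
package's defence against sign or bracketing slips in the closed form.

## Two-site model for tandem domains

A tandem construct with two WW domains is modelled as two independent sites
on one chain (2:1 ligand:protein stoichiometry), each with its own $K_i$ and
saturation shift $\delta_i$. The free ligand $L$ then satisfies the cubic
mass balance

$$L + \frac{pL}{K_1+L} + \frac{pL}{K_2+L} = L_{tot},$$

with exactly one root in $[0, L_{tot}]$. The printed legacy form of this
model (the xcrvfit "XY2" equation) is the standard trigonometric solution of
this cubic; the package implements the model from the mass balance itself
and solves the cubic trigonometrically, because the physics — not the
typography of any particular rendering — defines the model. Two numerical
choices matter:

* the cosine argument is clamped to $[-1, 1]$ when floating-point error
  pushes it out by up to $10^{-12}$; beyond that the solver falls back to
  bisection with a warning;
* the closed-form root is polished with at most five Newton steps (the
  derivative of the balance is $\geq 1$, so the iteration is
  unconditionally safe), which holds the mass-balance residual at machine
  precision even for strongly separated $K_1 \ll K_2$.

An independent bisection oracle (`two_site_free_ligand_bisect()`) validates
the solver, and an analytic reduction pins both models together: two
identical independent sites are indistinguishable from a single site at
doubled receptor concentration, so
$y_{2site}(L_{tot};p,K,K,\delta,\delta) =
y_{1site}(L_{tot}/2p;\,2p,K,2\delta)$ must hold to $10^{-9}$ ppm, and does.

## Hotspot selection and averaging

Binding-site residues are selected by the mean + 1 SD rule: at a chosen
titration point, residues whose shift distance is at least the mean plus one
sample standard deviation (n − 1 denominator) of all usable residues are
retained. The reference point is not dictated by the procedure's verbal
description; the package uses the **final** titration point by default,
because it maximizes dynamic range and therefore the contrast between
binders and bystanders. For tandem constructs the rule is applied per domain
via `residue_range`, so each site gets its own hotspot set.

"Hotspot residues were averaged to calculate the $K_D$" admits two readings,
and both are implemented in `fit_site_average()`:

* **curve-average** (default): average the selected residues' shift
  distances per point into one curve and fit it once. This weights residues
  by amplitude and produces one asymptotic SE.
* **kd-average**: fit each residue separately and average the $K_d$
  estimates; the SD of the per-residue estimates becomes the uncertainty.

On a site whose residues share one true $K_d$ the two agree to numerical
precision; when selected residues disagree (e.g. mixed true affinities) the
modes diverge and the kd-average SD exposes the heterogeneity. Neither is
asserted to be the original procedure.

## Two-site fitting: summed versus joint

The tandem procedure sums the two per-site hotspot mean curves and fits the
two-site model to the single summed curve (`fit_two_site(mode = "summed")`).
A summed curve cannot know which fitted $(K_i, \delta_i)$ pair belongs to
which domain; the package assigns the larger fitted amplitude to the site
whose mean curve saturates higher and warns that this is a heuristic.
`mode = "joint"` instead fits both site curves simultaneously with a shared
free-ligand concentration, preserving site identity by construction and
using twice the data. On seeded noisy replicates the joint mode is at least
as accurate as the summed mode; the summed mode's much larger standard
errors — of the order of the tight site's value itself — quantify the
identifiability cost of collapsing two curves into one, and mirror the
reported precision of published tandem estimates.

A caution that the simulations made concrete: a site with zero shift
amplitude ($\delta_2 = 0$) does *not* drop $K_2$ from the model under
ligand depletion, because an amplitude-less site still sequesters ligand
through the shared mass balance. $K_2$ only becomes unidentifiable when the
site is genuinely inert ($K_2$ far above the sampled ligand range); the
fitter flags that case with an unbounded standard error rather than a
failure.

## Optimizer and uncertainties

All fits are bounded nonlinear least squares ($K$'s in $[10^{-6}, 10^3]$ mM,
$\delta$'s in $[0, 10]$ ppm) run by a self-contained Levenberg–Marquardt
loop with box projection and a relative cost tolerance of $10^{-10}$;
a minpack-style fitter is not among the available dependencies, and the
noiseless recovery tolerances ($10^{-5}$ relative) need direct control over
the stopping rule. Starting values are derivative-free:
$\Delta\delta_{\infty,0} = 1.2\times$ the largest observed shift distance,
$K_{d,0}$ = the ligand concentration at half of it (linear interpolation),
and the two-site fit starts from two independent single-site fits of the
separate site means. Standard errors are asymptotic — the
residual-variance-scaled inverse of $J^\top J$ — matching the "value ± SD"
style of reported constants; parameters the residuals do not depend on get
an infinite SE instead of a crash. Whether published "±" values are
asymptotic SEs or something else is not stated anywhere authoritative; the
package documents its choice rather than guessing the original.

## The synthetic world

Raw titration peak positions for the real system are not deposited
(assignments and the structure ensemble are, but neither contains the
titration trajectories), so the package ships a generator rather than data.
`simulate_titration()` draws free-state peaks uniformly in the amide window
(¹H 6.5–10.5, ¹⁵N 102–132 ppm), gives each binder a bound-state offset of
weighted magnitude drawn from `ddmax_range` in a random direction, and
places every peak at free + (bound − free) × occupancy, with occupancy
computed by the numeric equilibrium oracle of the chosen model — never by
the closed form the fits use, so end-to-end recovery is a genuine
round-trip. Defaults state the simulated world once:

* schedules and concentrations follow the experimental designs (0.78 mM
  with ratios 1:0…1:4 in seven points; 0.08 mM with ratios 1:0…1:8.4 in
  ten points);
* true $K$'s in `paper_fixtures()` are the published estimates, reused as
  simulation settings (1.19 / 0.5 / 0.237 mM single-site; 20.57 and
  249.3 µM two-site);
* 30 assigned residues per single-domain construct (a WW domain plus
  solubility tag, minus prolines and unassigned termini), 60 for the
  tandem; binder fraction 0.3; weighted amplitudes 0.05–0.25 ppm, the range
  the published shift-distance plots span;
* position noise 0.003 ppm, a typical HSQC peak-position repeatability;
  applied independently to $\delta_H$ and to $\delta_N$ scaled by $\alpha$,
  and only to ligand-bearing points — the free reference defines the
  coordinate origin of the shift-distance measurement;
* intermediate exchange is emulated by deleting the configured residues at
  points where their occupancy lies in (0.2, 0.8), the coalescence window
  where broadening is maximal. Deletion is the observable consequence of
  broadening in a peak list; no lineshapes are simulated.

What the generator does **not** emulate: scalar couplings, peak overlap,
t₁ noise, temperature or pH drifts between points, non-specific binding at
high ligand excess, and any slow-exchange behaviour. A green end-to-end test
therefore establishes that the analysis correctly inverts its own stated
forward model at realistic noise — not that it is robust to every artifact
of real spectra.

## Degenerate inputs and edge cases

* Residues missing from the free reference cannot be referenced and are
  excluded with a warning.
* Hotspot selection requires ≥ 3 usable residues; fits require ≥ 4 observed
  points including the free point; two-site fits require ≥ 6 points.
* All-tied shift distances give SD 0 and select every residue (threshold
  equals the mean).
* A flat profile (all distances under 0.005 ppm, the scale of HSQC digital
  resolution) is a non-binding error, not a fit.
* $K_d = 0$ is legal in the forward model (the stoichiometric limit) but the
  fit bounds keep estimates strictly positive.

## Known limitations

The two-site model assumes independent sites; cooperative or anti-
cooperative coupling between tandem domains is outside its parameter space,
so a genuine interaction would surface only as lack of fit. Constant-protein
titrations are assumed by default; the `mode` field expresses
dilution-corrected designs but per-point protein concentrations enter the
fits only through the configured values. Uncertainties are asymptotic and
can be optimistic at few points; a seeded residual bootstrap is the natural
extension and was deliberately left out of scope.
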