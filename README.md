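# cspfit

NMR chemical-shift-perturbation (CSP) titration analysis for protein–ligand
binding, built for the regime where receptor concentration is comparable to
the dissociation constant (WW-domain/peptide interactions followed by
¹H-¹⁵N HSQC are the motivating case).

Given assigned peak lists for a titration series, the package

1. computes gyromagnetic-ratio-weighted shift distances per residue,
   `Δδ_w = sqrt(ΔδH² + (α·ΔδN)²)` with `α = 0.1014` by default;
2. classifies each residue's exchange regime (fast / intermediate /
   unperturbed) and keeps intermediate-exchange residues out of all fits;
3. selects binding-site hotspot residues by the mean + 1 SD rule;
4. estimates `K_D` by bounded nonlinear least squares under
   - the single-site fast-exchange model with ligand depletion
     `y = (Δδ∞/2)(B + x − sqrt((B+x)² − 4x))`, `B = 1 + K_d/a`, or
   - a two-site model for tandem domains (2:1 ligand:protein), whose free
     ligand solves the cubic mass balance
     `L + pL/(K₁+L) + pL/(K₂+L) = L_tot`
     (trigonometric closed form, Newton-polished, bisection-verified);
5. reports `K_D ± SD` in mM and µM with fit diagnostics.

Because raw titration peak positions for the real system are not publicly
deposited, the package includes a seeded synthetic-titration generator
(`simulate_titration()`, `paper_fixtures()`) that reproduces the
experimental designs — schedules, concentrations, published `K_D` values as
ground truth, position noise, intermediate-exchange peak loss — so the whole
pipeline is testable end to end. See
`vignettes/csp-titration-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

The analysis is organised as numbered scripts over the package:

```sh
Rscript analysis/01_simulate.R     # write the four synthetic titrations
Rscript analysis/02_csp.R          # CSP profiles + exchange calls
Rscript analysis/03_fit_single.R   # single-domain K_D fits
Rscript analysis/04_fit_tandem.R   # tandem two-site fits
```

`analysis/03_fit_single.R` prints, for the recombinant single-domain
dataset (protein 0.08 mM, ten ratio points 1:0 → 1:8.4, true
K_d = 0.237 mM, position noise 0.003 ppm):

```
ww4_smad7_recombinant
  hotspots (>= 0.1122 ppm): 2, 5, 6, 14, 22, 28
  curve-average: K_D = 0.2332 mM +/- 0.007 (true 0.237)
  kd-average:    K_D = 0.2326 mM +/- 0.024
```

The hotspot line is the mean + 1 SD selection at the final titration point;
the two `K_D` lines are the two readings of "hotspots were averaged"
(fit the averaged curve once, vs. average per-residue fits), both within a
few percent of the simulated truth. `analysis/04_fit_tandem.R` prints the
tandem fit (true K₁ = 0.02057 mM, K₂ = 0.2493 mM):

```
  joint:  K1 = 0.01902 mM +/- 0.00081, K2 = 0.2263 mM +/- 0.015
  summed: K1 = 0.02316 mM +/- 0.022, K2 = 0.257 mM +/- 0.12
```

Both modes recover the constants; the summed mode (sum of the two site-mean
curves, the conventional procedure) pays for collapsing two curves into one
with an uncertainty on the tight site of the order of the value itself,
while the joint mode (both curves fit simultaneously with shared free
ligand) keeps site identity and much smaller errors.

Equivalent programmatic entry points: `run_fixture("ww4_smad7_recombinant")`
and `run_pipeline(series, model = , site_ranges = )` for data loaded with
`load_titration()`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline (simulate → CSP → hotspots → fit) on all four
named fixtures with seeds derived from `--seed`, prints the recovered
dissociation constants, and writes the JSON summary to `--out`.
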