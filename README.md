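# hepatokin

Physiologically based whole-body kinetics of the hepatocyte-specific MRI
contrast agent gadoxetate (Gd-EOB-DTPA), for quantitative liver-function
analysis of dynamic contrast-enhanced MRI (DCE-MRI).

Gadoxetate is taken up from blood plasma by hepatocytes (OATP transporters)
and excreted into bile (MRP2), with parallel renal elimination. `hepatokin`
implements the compartmental model family M0–M9 around four concentration
states — plasma $C_p$, whole-body extracellular extravascular space $C_e$,
hepatocytes $C_h$, splenic intracellular space $C_s$ (structurally inert) —
and two sinks, bile $A_b$ and urine $A_u$:

$$\dot C_x = \frac{\sum J_{in} - \sum J_{out}}{V_x}, \qquad
  J = k\,C_{src}\,V_{ref} \ \text{ or } \
  J = \frac{v_{max} C_{src}}{K_m + C_{src}}\,V_{ref},$$

with a step-function injection $u = D/\tau$, plasma–EES diffusion driven by
the free (non albumin-bound) concentration, a fixed renal rate
$k_{kid} = CL/V_p$ ($CL$ = 118 mL/min), and an MRI signal model
$y_i = \xi \sum_j \gamma_{ij} r_{1j} C_j$ over each region of interest
(liver, spleen, vein). On top of the simulator the package provides:

* chi-square **ensemble estimation** by simulated annealing — the fit
  archives *every* parameter vector passing the chi-square test, not just
  the optimum (`fit_model()`);
* the **physiological-realism filter** (>1% of dose in plasma at 3 h,
  `apply_adhoc_constraint()`);
* **profile-likelihood identifiability** with the absolute acceptance
  threshold (`profile_likelihood()`, `profile_all()`);
* **core-prediction envelopes** over the acceptable ensemble
  (`core_prediction_band()`);
* ±20% **volume sensitivity** and a simulated gradual **loss of liver
  function** (`volume_sensitivity()`, `simulate_function_loss()`);
* a **synthetic-data generator** emulating the clinical bolus DCE-MRI
  design and the high-dose infusion blood-sampling design
  (`generate_estimation_like()`, `generate_validation_like()`), so the
  whole pipeline is testable without any cohort download.

See the vignette (`vignettes/hepatobiliary-kinetics.Rmd`) for the model,
the flux reference-volume calibration, and all stated-world choices.

## Worked example

```r
library(hepatokin)
phys <- physiology()
par  <- reference_parameters()        # published optimal estimates
prot <- injection_protocol()          # 0.025 mmol/kg x 73 kg over 7 s

traj <- simulate_model(build_variant("M0"), par, phys, prot,
                       c(0, 600, 2400, 10800))
elimination_fractions(traj)
#> bile_pct urine_pct
#>    45.01     37.58
plasma_dose_fraction(traj, t = 10800)
#> [1] 1.1
```

At 3 h, 45.0% of the administered dose has been excreted into bile and
37.6% into urine — inside the published profile-likelihood prediction
intervals [38.4, 63.5]% and [30.6, 40.6]% — and 1.10% of the dose is still
circulating in plasma, satisfying the >1% physiological-realism bound.

```r
ds  <- generate_estimation_like(par, noisy = TRUE, seed = 1)
fit <- fit_model(build_variant("M0"), ds, seed = 1,
                 restarts = 3, evals_per_restart = 6000)
fit
#> Fit of variant M0: lowest cost 14.14 (threshold 23.68) -> model accepted
#>   ensemble: 620 acceptable parameter vectors (seed 1, 18678 evaluations)
#>   xi                           = 1.612
#>   k_diff                       = 0.001749
#>   k_ph                         = 0.004772
#>   k_hp                         = 0.0002686
#>   k_hb                         = 0.0004089

profile_all(build_variant("M0"), ds, fit,
            phys = phys, protocol = prot)$n_finite
#> [1] 5
```

The fit to a synthetic noisy replicate of the clinical design passes the
chi-square test (14.14 < 23.68, the 0.95 quantile at 18 − 4 degrees of
freedom) and recovers rate constants near the generating values
(e.g. uptake $k_{ph}$ 4.77e-3 vs true 4.776e-3 s⁻¹); all five fitted
parameters have finite profile-likelihood intervals, reproducing the
published identifiability result for the minimal model.

## Command line

```sh
Rscript -e 'hepatokin::hepatokin_cli()' simulate --out out/
Rscript -e 'hepatokin::hepatokin_cli()' generate --out out/ --seed 1
Rscript -e 'hepatokin::hepatokin_cli()' fit --dataset out/estimation_data.tsv --out out/
```

Subcommands: `generate`, `simulate`, `fit`, `constrain`, `profile`,
`predict`, `sensitivity`, `select`; flags `--config` (JSON), `--seed`,
`--out`, `--variant`, `--dataset`. Every run writes its resolved
configuration and seed next to its results.

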