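# gliomaTME

Stochastic population-dynamics simulator of the glioblastoma
microenvironment, for computational biologists studying how
tumor–stroma signaling shapes tumor initiation, progression and
response to microenvironment-targeted therapy.

The model couples five cell populations — quiescent (QSC) and activated
(ASC) glioma stem-like cells, glioma cells (GC), astrocytes and
microglia — to 15 cytokines/growth factors through 69 Hill-modulated
signaling pathways, giving 20 coupled differential equations in a
well-mixed 1-ml volume. Each cell population follows

    dc/dt = jumps + r·Π M(x)·L·A·c − d·Π M(x)·c + conversions

with logistic crowding `L = max(0, 1 − Σc/c̄)` on total cell density, a
VEGF-driven angiogenesis gate `A = A_min + (1−A_min)·h(VEGF)`, and
multiplicative Hill factors `M` per pathway edge
(`h(x) = xⁿ/(Kⁿ+xⁿ)`); cytokines follow modulated secretion minus
half-life decay. Three stochastic layers — truncated Gaussian noise on
secretion rates, sine-Wiener bounded noise on proliferation/conversion
rates, and Poisson jump events for microglia recruitment and stem-cell
conversion bursts — run on a fixed-step RK4 core (compiled, seeded,
bitwise reproducible). On top of the simulator sit virtual-patient
profiles (29 tunable production/receptor multipliers), trigger-based
therapy plans (microglia depletion, cytokine combination blockade) with
seed-paired controls, and local sensitivity analysis of a
survival-proxy objective by central finite differences with common
random numbers.

## Worked example

```r
library(gliomaTME)

spec <- default_glioma_spec()        # 5 cells, 15 cytokines, 69 edges
tr   <- integrate_stochastic(spec, t_span = 365, dt = 0.01, seed = 1)
detect_phases(tr)
#> # A tibble: 1 × 7
#>   activation_complete_time detection_crossing_time saturation_time
#>                      <dbl>                   <dbl>           <dbl>
#> 1                     4.34                    196.            331.
#> # plateau_level 18718082, pre_tumor_end 196, expansion_end 331, horizon 365
```

The stem-cell pool activates within the first week; the glioma
population crosses the clinical detection threshold (10^6 cells/ml)
around day 196 (month 6.5) and saturates near 1.9×10^7 cells/ml — the
three-phase pattern (pre-tumor, rapid expansion, malignant plateau).

Therapy, with a seed-paired control:

```r
plan <- microglia_depletion_plan(2e5)      # 10x microglia apoptosis at GC = 2e5/ml
out  <- simulate_with_therapy(spec, plan, t_span = 365, seed = 1)
out$outcome[, c("trigger_day", "benefit_metric", "postponement_months",
                "recurrence_within_horizon")]
#> # A tibble: 1 × 4
#>   trigger_day benefit_metric          postponement_months recurrence_within_horizon
#>         <dbl> <chr>                                 <dbl> <lgl>
#> 1        178. detection_postponement                 1.09 TRUE
```

Treating this run while the tumor is still at 2×10^5 cells/ml postpones
detection (this seed recurs after a one-month delay; across a
seed-paired ensemble the median postponement at this stage is several
months, and treatment before 5×10^4 cells/ml prevents recurrence
entirely). Triggering the same plan at 10^6 cells/ml leaves the
trajectory unchanged — the tumor is already self-sustained.

Sensitivity-guided combination design:

```r
prof <- sensitivity_profile(spec, patient = fixture_patient(1),
                            n_reps = 8, master_seed = 1)
design_combination(prof, k = 4)     # most negative S -> inhibition targets
autoplot(prof)                      # ranked sensitivity landscape
```

A CLI wrapper with `simulate`, `therapy`, `sensitivity`,
`validate-spec` and `make-patient` subcommands ships in
`inst/cli/gliomatme.R`.

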