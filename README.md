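# n2opart

Partitioning gross N2O production and consumption from acetylene-inhibition
soil microcosms, with temperature-sensitivity (Q10) estimation and
N2O-reducer community statistics.

## What it does and for whom

Soil emits N2O as the *net* outcome of two simultaneous microbial
processes: gross production (nitrification + denitrification to N2O) and
gross consumption (reduction of N2O to N2 by `nosZ`-carrying organisms).
`n2opart` is for soil biogeochemists and microbial ecologists running
microcosm incubations with the three-level acetylene inhibition design —
0 Pa (control), 10 Pa (nitrification inhibited) and 10 kPa C2H2
(nitrification + N2O reduction inhibited) — who want a tested, reproducible
pipeline from raw headspace concentrations to process rates, temperature
sensitivities and community-trait correlations.

The core estimator pairs the three headspace treatments of the same
replicate:

    R_con = R_10kPa - R_10Pa
    R_pro = R_10kPa - R_10Pa + R_0Pa

so that `R_pro - R_con = R_0Pa` (the net rate) holds exactly. The ratio
`R_con / R_pro` estimates the denitrification product ratio N2/(N2O + N2).
Temperature sensitivity is the van't Hoff `Q10 = exp(10 * beta)` from an
ordinary-least-squares fit of `ln R = ln alpha + beta * t` to cumulative
emissions at 15/25/35 degC. Uncertainty for all derived rates comes from a
case bootstrap over replicates combined with Monte-Carlo measurement noise,
which avoids overstating significance when comparing two estimators that
share sampling error by construction.

Because raw datasets for this design are rarely deposited, the package also
ships a calibrated synthetic study generator (`scenario_default()`,
`generate_study()`) producing the full factorial design — gas
concentrations, nutrient trajectories, T-RFLP peak tables for both `nosZ`
clades, and qPCR Cq tables — so every stage is testable end to end.

## Worked example

```r
library(n2opart)

scenario <- scenario_default()
study    <- generate_study(scenario, seed = 1)
rates    <- flux_rates(study$gas)
cells    <- partition_rates(rates[rates$day %in% c(3, 15, 30), ])

cells[cells$fertilization == "NPK" & cells$day == 15, ]
#>   fertilization temperature_C   day     n production production_se consumption
#> 1 NPK                      15    15     4       5.48         0.565        3.76
#> 2 NPK                      25    15     4       9.61         0.197        5.31
#> 3 NPK                      35    15     4      13.1          1.04         6.40
#>   consumption_se   net net_se ratio ...
#>            0.344  1.72  0.259 0.686
#>            0.124  4.29  0.105 0.553
#>            0.440  6.65  0.605 0.490

mean(cells$ratio)
#> 0.622
```

Gross production (ng N2O-N per g dry soil per day) rises steeply with
temperature in the NPK regime while consumption trails it, so the
N2/(N2O+N2) ratio falls from 0.69 at 15 degC to 0.49 at 35 degC; averaged
over all 27 treatment cells the ratio is 0.62 — most of the N2O produced in
these soils is consumed again before it escapes.

```r
cum <- dplyr::summarise(
  dplyr::group_by(rates[rates$arm == "net_monitoring", ],
                  fertilization, temperature_C, replicate),
  cumulative_ngN_g = cumulative_emission(day, rate_ngN_g_d), .groups = "drop")

fit_vant_hoff(cum$temperature_C[cum$fertilization == "CT"],
              cum$cumulative_ngN_g[cum$fertilization == "CT"])
#> van't Hoff fit (log-ols, n = 12): alpha = 48.16, beta = 0.0198 per degC,
#>   Q10 = 1.219 (R2 = 0.686)

compare_q10(cum[cum$fertilization == "NPK", ],
            cum[cum$fertilization == "CT", ], B = 1000, seed = 2)
#> Q10 NPK - CT: 0.59 (95% CI 0.29..0.93, p = 0.002)
```

The unfertilized control has a weak net-emission temperature response
(Q10 1.22) while long-term synthetic fertilization nearly doubles it
(Q10 1.79); the replicate bootstrap puts the difference at 0.59 with
p = 0.002 — temperature sensitivity of the *production* process, not
consumption, drives the difference.

The whole chain (simulate -> fluxes -> partition -> Q10 -> community ->
qPCR) runs as one call with CSV outputs and a manifest:

```r
run_pipeline(list(outdir = "out", simulate = list(scenario = "default", seed = 1)))
```

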