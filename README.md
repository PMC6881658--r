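# nitrateRisk

Non-carcinogenic health risk assessment of nitrate in drinking-water
supplies, for environmental-health scientists and water-quality managers.
Elevated nitrate in groundwater is a public-health concern chiefly because
of infant methemoglobinemia ("blue baby syndrome"), so risk is assessed
separately for exposure groups with very different intake-to-body-weight
ratios.

The package implements the standard two-step exposure model. For a nitrate
concentration *C<sub>f</sub>* (mg/L), a daily water intake *C<sub>d</sub>*
(L/day) and a body weight *B<sub>w</sub>* (kg), the estimated daily intake
is

    EDI = Cf · Cd / Bw        [mg/kg/day]

and the hazard quotient against the oral reference dose *RfD*
(1.6 mg/kg/day for nitrate, per the US EPA IRIS database) is

    HQ = EDI / RfD.

HQ ≤ 1 means no adverse non-carcinogenic effect is expected; HQ > 1 flags
risk above the acceptable level. Four built-in exposure groups are
provided: infants (0.08 L/day, 10 kg), children (0.85 L/day, 15 kg),
teenagers (2 L/day, 50 kg) and adults (2.5 L/day, 78 kg), all with
RfD = 1.6.

On top of the deterministic model the package provides:

- a **Monte-Carlo engine** (`simulate_hq()`) that treats any of
  *C<sub>f</sub>*, *C<sub>d</sub>*, *B<sub>w</sub>* as a distribution
  (point mass, normal, lognormal, uniform, triangular or empirical, with
  optional truncation), reports mean, SD, percentiles (P90), the
  probability of HQ > 1, and a rank-correlation contribution-to-variance
  sensitivity breakdown;
- **distribution fitting** (`fit_concentration_dist()`) selecting among
  candidate families by Kolmogorov–Smirnov statistic;
- **IDW spatial interpolation** (`interpolate_grid()`) of well
  concentrations onto a regular lon/lat grid, with guideline exceedance
  masks, ESRI-ASCII raster and GeoJSON output;
- a **synthetic well-network generator** (`generate_wells()`) for
  validating every stage without external data;
- the bundled 66-sample groundwater nitrate survey of Iranshahr, Iran
  (`iranshahr_nitrate()`), together with its published per-sample EDI/HQ
  reference table (`iranshahr_hq_reference()`).

## Worked example

```r
library(nitrateRisk)

wells <- iranshahr_nitrate()        # 66 wells, 6.0-49.0 mg/L
res   <- assess(wells)              # 264 sample-group records
summarize_risk(res)[, c("group", "hq_mean", "hq_max")]
#>      group    hq_mean    hq_max
#> 1   infant 0.07548485 0.2450000
#> 2 children 0.53468434 1.7354167
#> 3 teenager 0.37742424 1.2250000
#> 4   adults 0.30242327 0.9815705
```

Mean HQ orders children > teenager > adults > infant, and only the worst
well (49 mg/L) pushes HQ above 1 — for children (1.7354) and teenagers
(1.2250). Probabilistically:

```r
cf  <- fit_concentration_dist(wells)   # lognormal wins the K-S comparison
print(cf)
#> <dist_spec> lognormal(meanlog=2.65186, sdlog=0.343616)

children <- subset(default_exposure_groups(), name == "children")
simulate_hq(children, mc_config(cf = cf, n_iterations = 5000, seed = 7))
#> <mc_result> group: children  n = 5000
#>   HQ mean 0.5335  sd 0.1899  P(HQ > 1) 0.0266
#>   percentiles: P5 0.2868  P25 0.3997  P50 0.5023  P75 0.6265  P90 0.7790  P95 0.8971
#>   contribution to variance: cf 1.000
```

So with the fitted concentration distribution and fixed intake/body
weight, a child's HQ stays below 1 in about 97% of draws, and all of the
variance comes from the concentration. `write_report()` collects the
deterministic and probabilistic summaries side by side;
`interpolate_grid()` + `write_esri_ascii()` map the concentrations. A
command-line front end with `assess`, `mc`, `map`, `synth` and `fixture`
subcommands ships in `inst/cli/nitrate-risk.R`.

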