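# radmibg

Sphere dosimetry and efficacy analysis for preclinical studies that combine
external-beam radiotherapy (EBRT) with ^131I-mIBG molecular radiotherapy
(MRT) in neuroblastoma xenografts.

Such studies ask a scheduling question — does irradiating a tumour shortly
before (or after) administering ^131I-mIBG increase the radionuclide's
tumour uptake, absorbed dose and the animals' time to a humane
tumour-volume endpoint? Answering it requires three distinct computations
that this package implements end to end for analysts of small-animal
radiotherapy data:

1. **MIRD-schema tumour dosimetry.** The absorbed dose is
   `D = Ã · m · S`, where the cumulated activity `Ã` is the time integral
   of the tumour activity (trapezoids between %ID/g samples plus a
   physical-decay tail `A_last/λ`), and the S-value (Gy per Bq·s) comes
   from event-by-event Monte Carlo transport of the full ^131I emission
   inventory — allowed-shape Fermi beta spectra, conversion electrons and
   gamma/X-ray lines — in unit-density water spheres (CSDA electrons,
   analog Klein–Nishina/photoelectric photons).
2. **DCE-MRI permeability quantification.** Relative T1 enhancement
   `(S − S̄_pre)/S̄_pre` against the pre-injection baseline, summarised over
   the post-injection window and compared between imaging sessions with
   paired t-tests; slice-area × thickness tumour volumetry.
3. **Efficacy statistics.** Pooled/Welch t-tests computed directly from
   group summary statistics, one-way ANOVA of percent volume change,
   Kaplan–Meier estimation of time to the 800 mm³ endpoint with day-53
   censoring, and Weibull accelerated-failure-time regression with
   treatment contrasts.

A calibrated synthetic-cohort generator (`gen_biodistribution()`,
`gen_growth_cohort()`, `gen_dce()`) emulates the three-study animal design
so the whole pipeline runs and is tested without any external data.

## Worked example

Dose to a 0.5 g tumour sphere from the shipped group-mean uptake curves
(20 MBq injected), with the S-value simulated at 10⁵ histories:

```r
library(radmibg)
sc  <- load_i131_scheme()
res <- simulate_sphere(sc, sphere(0.5), 1e5, seed = 1)
res
#> <transport_result> 100000 histories, sphere 0.5 g (seed 1)
#>   phi_beta     = 0.9255 +/- 0.0009
#>   phi_electron = 0.9351 +/- 0.0044
#>   phi_photon   = 0.0113 +/- 0.0002
#>   phi_total    = 0.3211 +/- 0.0007
sv <- s_value(res)
sv
#> <s_value> 5.8602e-11 +/- 1.4e-13 Gy/(Bq s), sphere 0.5 g

su   <- uptake_summaries()
tacs <- lapply(split(su, su$group), function(g)
  time_activity_curve(g$time_h, g$mean_pct_id_g, injected_mbq = 20,
                      label = g$group[1]))
d1 <- absorbed_dose(cumulated_activity(tacs[["EBRT+MRT"]], sc), 0.5, sv)
d2 <- absorbed_dose(cumulated_activity(tacs[["MRT"]], sc), 0.5, sv)
d1
#> <dose_report> [EBRT+MRT] dose = 45.2 Gy
#>   A~ = 428.1 MBq h/g, mass = 0.5 g, S = 5.860e-11 Gy/(Bq s)
#>   conventions: decay_corrected=FALSE, start=zero, tail=TRUE
dose_ratio(d1, d2)
#> [1] 4.411793
```

About 93 % of the beta energy but only ~1 % of the photon energy is
absorbed in a half-gram sphere, giving S ≈ 5.9 × 10⁻¹¹ Gy/(Bq·s). EBRT
priming more than doubles the absorbed dose (here ×4.4); the ratio is
independent of the S-value and holds under every supported integration
convention. Absolute doses depend on conventions (tumour mass, decay
correction, start segment) that every `dose_report` records in its
`assumptions` block.

Uptake significance from the group summaries alone:

```r
t_test_from_summary(group_summary("EBRT+MRT", 10.47, 1.86, 3),
                    group_summary("MRT",       3.57, 1.57, 3))
#> t = 4.91, df = 4, p = 0.0080
```

A full synthetic experiment — generation, all three analyses, and the
qualitative result pattern — is one call:

```r
res <- run_all(synth_config(), seed = 1)
res$pattern
```

A thin command-line wrapper with `synth`, `svalue`, `dose` and `all`
subcommands ships in `inst/scripts/radmibg.R`.

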