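# fibrostage

Stepwise non-invasive staging of liver fibrosis and cirrhosis in
non-alcoholic fatty liver disease (NAFLD).

Liver biopsy is the reference standard for staging fibrosis (NASH CRN stages
F0–F4, with F3–F4 "advanced fibrosis" and F4 cirrhosis), but it is invasive
and impractical for the large NAFLD population. Clinicians therefore triage
with non-invasive tests: simple blood scores (FIB-4, NAFLD fibrosis score),
patented specialized blood tests (FibroMeterV3G, CirrhoMeterV3G), liver
stiffness by vibration-controlled transient elastography (VCTE, kPa), and
elastography–blood composites (Agile3+, Agile4). `fibrostage` implements a
sequential diagnostic framework built from these tests, for biostatisticians
and hepatology researchers who want to study, extend or stress-test such
algorithms:

- **Four-group classifications.** Agile3+/4: (i) Agile3+ < 0.451;
  (ii) 0.451–0.678; (iii) ≥ 0.679 with Agile4 ≤ 0.474; (iv) ≥ 0.679 with
  Agile4 > 0.474. FM/CM: (i) FMV3G < 0.31; (ii) 0.31–0.76; (iii) > 0.76 with
  CMV3G ≤ 0.40; (iv) > 0.76 with CMV3G > 0.40.
- **Sequential study algorithm.** Elastography-based scores first; the
  specialized blood tests are run only when Agile3+ ≥ 0.451; the crossing of
  the two classifications yields one of four diagnoses: F0-2, Biopsy
  (undetermined), F34, or F4. A guideline-style three-tier comparator
  (FIB-4 → stiffness → specialized blood test) is included.
- **Risk prediction charts.** A logistic model with hinge terms,
  `logit P(target) = b0 + b1·Agile3+ + b2·Agile4·[Agile3+ > 0.678] +
  b3·FMV3G + b4·CMV3G·[FMV3G > 0.76]`, fitted for both F4 and F34, with
  chart grids on the composite elastography/blood axes and configurable risk
  bands (7 bands for cirrhosis, 10 for advanced fibrosis).
- **Evaluation statistics.** Midrank AUROC with DeLong variance and paired
  test, operating characteristics, binned calibration with mean signed
  difference, accuracy/biopsy-rate reports, Mann-Whitney / chi-squared /
  Fisher descriptives, Spearman correlation.
- **Calibrated synthetic cohorts.** Patient-level NAFLD cohort data of this
  kind are not publicly deposited, so the package ships a seeded generator
  whose latent stage-shifted binormal model is deterministically calibrated
  (by 2-D root-finding on analytic mixture AUROCs, plus exact quantile
  links) to published whole-cohort stage prevalences, score quartiles and
  AUROCs, with Gaussian-copula correlation across tests and morphometry
  areas calibrated to stated stage correlations.

## Worked example

```r
library(fibrostage)

cohort <- simulate_cohort(sim_config(n = 20000, seed = 1))

auroc(cohort$agile3p, cohort$stage >= 3)
#> AUROC 0.854 (95% CI 0.849-0.859), 7679 pos / 12321 neg

result <- study_algorithm(cohort)
accuracy_report(result$final_diagnosis, cohort$stage)
#> <accuracy_report: n = 20000>
#>   F0-2 Biopsy    F34     F4
#>  10812   2369   5782   1037
#> accuracy 79.9% (excl. biopsy) / 70.5% (incl.), biopsy rate 11.8%, off-by-one 95.2%

model <- fit_risk_model(cohort, "F4")
risk <- predict_risk(model, agile3p = 0.85, agile4 = 0.68,
                     fmv3g = 0.91, cmv3g = 0.40)
round(risk, 3)
#> [1] 0.527
assign_band(model, risk)   # band 5 of the 7-band cirrhosis chart
#> [1] 5
```

Reading the output: the simulated Agile3+ discriminates advanced fibrosis
with AUROC 0.854 (the generator's calibration target is 0.852); the
sequential algorithm gives a definite diagnosis to 88% of the cohort and
defers 12% to biopsy; of the definite calls, 79.9% match the biopsy stage,
and 95% of the errors are off by a single stage group. The fitted cirrhosis
chart places a patient with Agile3+ 0.85, Agile4 0.68, FMV3G 0.91 and
CMV3G 0.40 at 53% predicted risk — in the fifth of seven risk bands. (On
the real derivation cohort this profile sits in the 60–80% band; the
difference reflects the synthetic generator's assumed joint correlation
structure, see the methods vignette.)

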