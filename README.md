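# msord

Open-population capture-recapture inference for photo-identification studies
sampled under Pollock's robust design — built for the situation faced by
small-boat dolphin surveys: a population that is open *between* seasonal
primary periods (survival, temporary emigration) and open *within* them
(animals drift in and out of the surveyed strip during a season), observed
through imperfect detection of the distinctively marked fraction only.

The package provides, as testable R functions:

* the **multi-state open robust design (MSORD)** likelihood over an
  observable state P and an unobservable temporary-emigrant state E, with an
  open within-primary entry/persistence sub-model — fitted by maximum
  likelihood (`fit_msord()`), yielding apparent survival S, detection p,
  entry/persistence (pent, phi), Markovian/random/no emigration
  (psi<sup>P→E</sup>, psi<sup>E→E</sup>), and derived per-season marked
  abundance N&#770;<sub>m,t</sub> = n<sub>t</sub>/p&#770;\*<sub>t</sub>;
* the **Jolly-Seber POPAN** super-population likelihood on season-pooled
  occasions (`fit_popan()`);
* **mark-rate estimation** from group sightings by two independent methods
  (image-based and count-based) and the **scaling chain**
  N&#770;<sub>total</sub> = N&#770;<sub>m</sub>/θ&#770; with delta-method SE
  `sqrt(N_total^2 (se_Nm^2/Nm^2 + (1-θ)/(nθ)))` and log-normal 95% CIs;
* **AICc/QAICc ranking**, Akaike weights and 2-unit model averaging;
  **goodness of fit** (per-primary time-varying CJS deviance c-hat,
  RELEASE-style TEST 2 / TEST 3 contingency components); **data-cloning**
  identifiability screening;
* **simulators** for every data type, so the whole stack is testable with no
  field data, plus a `run_analysis()` orchestrator driven by one (YAML)
  config.

## Worked example

Simulate a study at a realistic scale — 8 seasonal primary periods of 6
surveys each, 200 animals, seasonal-decay entry — fit the MSORD, and scale a
marked-abundance estimate to total abundance:

```r
library(msord)

design <- study_design(6, n_primary = 8)
truth <- list(S = 0.95, p = 0.30, pent = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1),
              phi = 0.75, psiPE = 0.35, psiEE = 0.60)
sim <- simulate_msord(truth, design, 200, seed = 1)
sim$data
#> Capture histories: 168 individuals, 8 primary periods ( 6+6+6+6+6+6+6+6 occasions )
#>   total detections: 556

fit <- fit_msord(sim$data, "S(.) p(.) pent(.) phi(.) psi(Markovian)")
fit
#> MSORD fit: S(.) p(.) pent(.) phi(.) psi(Markovian)
#>   168 histories, 6 parameters, logLik -1606.702, AICc 3225.925

head(derive_abundance(fit)[, c("period", "n", "pstar", "N_m", "se_N_m")], 3)
#>     period  n     pstar       N_m    se_N_m
#> 1 primary1 56 0.5451813 102.71813 10.633847
#> 2 primary2 45 0.5451813  82.54135  9.302909
#> 3 primary3 49 0.5451813  89.87836  9.795332
```

Here `pstar` is the fitted probability that an animal present in a season is
detected at least once, so 56 distinct animals seen in the first primary
scale to about 103 marked animals present (SE 10.6, Horvitz-Thompson
variance included). Scaling a marked estimate by a mark rate of 0.30 (72
identified individuals that season):

```r
abundance_table(data.frame(period = "Spring 2021", n = 72,
                           N_m = 89, se_N_m = 3.5), theta = 0.30)
#> Total abundance by primary period (marked abundance / mark rate):
#>       period  n      N_m             N_total
#>  Spring 2021 72 89 (3.5) 297 (54.7, 208-425)
```

that is, 89/0.30 ≈ 297 dolphins in total, with the delta-method SE of 54.7
and a log-normal interval of 208–425 that is geometrically symmetric about
the estimate.

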