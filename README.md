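# distrem

Hybrid distance-sampling × time-removal hierarchical models for avian
point-count surveys: simulation, single-season and multi-year Bayesian
inference, survey-design evaluation, and sample-size calculation.

Point counts in bottomland hardwood and riparian forests (and anywhere
else) face three nested losses between the population and the data
sheet: a bird may be off the plot during the visit (presence, p_p), on
the plot but silent (availability, p_a per removal interval, phi
overall), or singing yet missed because it is far away (perceptibility,
p_d, declining with distance).  `distrem` implements the hierarchical
model that unpicks these from counts recording, for every detection,
both the distance class and the time interval of first detection:

    N_super_k  ~ Poisson(lambda)                      superpopulation at point k
    N_pres_kt  ~ Binomial(N_super_k, p_p)             random temporary emigration
    N_avail_kt ~ Binomial(N_pres_kt, phi)             phi = 1 - (1 - p_a)^J
    y_kt       ~ Binomial(N_avail_kt, p_d)            p_d = sum_b g(r_b) 2 r_b delta_b / B^2
    g(r) = exp(-r^2 / (2 sigma^2))                    half-normal detection

with per-detection multinomial cells `pi_d_b / p_d` (distance) and
`p_a (1-p_a)^(j-1) / phi` (time removal).  A multi-year extension drives
annual abundance with a stationary AR(p) process,
`lambda_kt = sum_i gamma_i N_[k,t-i] + (1 - sum gamma_i) exp(X beta)`,
plus refuge random effects, and reports percent annual trends.  A
closed-form calculator turns a pilot survey into the number of point
counts required for a target coefficient of variation,
`k = k0 (CV_obs / CV_target)^2`.

The package is written Bioconductor-style: S4 classes with validity
checks (`DistanceBinning`, `ScenarioConfig`, `SimulatedDataset`,
`PosteriorSummary`, ...), accessors, and camelCase exports.  The
single-season sampler uses an exactly marginalized likelihood with a
compiled kernel; the trend model runs in JAGS via `rjags`.

## Worked example

```r
library(distrem)

## survey-design detection probability: sigma = 55 m, 4 bins to 150 m
dc <- distanceCellProbs(distanceBinning(), sigma = 55)
round(dc$p_d, 2)
#> [1] 0.27

## simulate a season and fit it
cfg <- scenarioConfig(lambda = 5, pPresence = 0.8, availability = 0.8,
                      nPoints = 300, nVisits = 3)
d   <- simulateDataset(cfg, seed = 7)
fit <- fitStatic(d, seed = 1)
subset(posteriorSummary(fit), parameter %in% c("p_a", "p_d", "sigma", "D_pres"))
#>   parameter   mean     sd   q2.5    q50  q97.5 rhat n_eff
#>         p_a  0.827 0.0118  0.804  0.828  0.849 1.00  1027
#>       sigma 55.402 1.1326 53.334 55.401 57.781 1.01   320
#>         p_d  0.270 0.0102  0.252  0.270  0.292 1.01   320
#>      D_pres 56.384 2.9876 50.776 56.269 62.408 1.01   401
```

The generating values were `p_a = 0.8`, `sigma = 55` (so `p_d = 0.267`)
and a present-bird density of `5 * 0.8 / (pi * 0.15^2) = 56.6`
birds/km²; each 95% credible interval covers its target.  (Numbers vary
with the simulation seed.)

```r
## how many point counts does a pilot with 50 detections at 100 points
## and an observed CV of 0.30 need for research-grade precision?
requiredPoints(pilotSummary(n0 = 50, k0 = 100, cvObs = 0.30), cvTarget = 0.15)
#> Required points for CV 0.15: 400.0 (rounded: 400)

literatureLookup("Swainson's Warbler")$avg_min_n
#> [1] 61
```

A thin command-line shim wraps the same functions:

```sh
Rscript inst/scripts/distrem simulate --points 50 --seed 1 --out survey.csv
Rscript inst/scripts/distrem samplesize --n0 50 --k0 100 --cv-obs 0.30 --cv-target 0.15
```

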