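# ogttda

Mechanistic OGTT phenotyping and post-operative glycemic outcome
prediction.

Adolescents with severe obesity who undergo bariatric surgery vary widely
in whether their glucose metabolism normalises by 12 months. `ogttda`
estimates two latent physiological parameters per patient from a sparse
120-minute oral glucose tolerance test (glucose ± insulin at 0, 30, 60,
120 min): insulin sensitivity *S*<sub>I</sub> and the maximal insulin
secretion capacity σ of the β-cell mass. Estimation is Bayesian — a
random-walk Metropolis–Hastings chain over a mechanistic
glucose–insulin–exocytosis ODE model,

- d*G*/d*t* = OGTT(*t*) + HGP(*I*) − (*E*<sub>G0</sub> + *s·S*<sub>I</sub>·*I*)·*G*
- d*I*/d*t* = (β/*V*)·ISR − *k·I*,  ISR = *C*<sub>ISR</sub>(*G*, γ)·*N*<sub>5</sub>
- d*N*<sub>5</sub>/d*t* = *c*<sub>55</sub>*N*<sub>5</sub> + *c*<sub>56</sub>*N*<sub>6</sub>,  d*N*<sub>6</sub>/d*t* = *c*<sub>60</sub> + *c*<sub>65</sub>*N*<sub>5</sub> + *c*<sub>66</sub>*N*<sub>6</sub>

with uniform priors on *S*<sub>I</sub> ∈ [0.005, 3] and σ ∈ [0.01, 10] and
a Gaussian error model (γ fixed at −0.076 and σ at steady state on the
OGTT timescale). Posterior means and SDs of *S*<sub>I</sub>, σ and the
per-sample product σ·*S*<sub>I</sub> then join clinical covariates in a
class-weighted regularized logistic regression predicting 12-month
post-operative impaired glucose metabolism (IGM), evaluated by 1,000-fold
bootstrap out-of-bag AUROC and average precision. A synthetic-cohort
generator reproduces the statistical structure of such a cohort (two
latent subgroups, ~32% positive prevalence, forward-model OGTT curves plus
noise) so every stage is testable offline.

See the methods vignette (`vignettes/ogtt-data-assimilation.Rmd`) for the
model, the estimation protocol, and the design decisions.

## Worked example

Simulate a patient with unimpaired physiology, fit the posterior, and
summarise:

```r
library(ogttda)

obs <- generate_ogtt_observation(sigma = 3.0, SI = 0.3,
                                 noise_sd_glucose = 2,
                                 insulin_noise_frac = 0.05, seed = 42)
rbind(glucose = round(obs$glucose, 1), insulin = round(obs$insulin, 1))
#>         [,1]  [,2]  [,3] [,4]
#> glucose 92.7 168.7 177.9 96.6
#> insulin 12.8  44.5  94.0 25.7

chain <- run_rwmh(obs, inference_config(n_iter = 50000, burn_in = 5000,
                                        seed = 7))
summarize_posterior(chain)[, c("mean_SI", "sd_SI", "mean_sigma",
                               "sd_sigma", "mean_product")]
#>     mean_SI      sd_SI mean_sigma  sd_sigma mean_product
#> 1 0.2906062 0.02798304   3.047596 0.2048578    0.8831692
```

The chain recovers the latent parameters (truth 0.3 and 3.0) within
posterior uncertainty; the acceptance rate (`chain$acceptance_rate`,
here 0.24) sits in the 0.2–0.5 band targeted by the burn-in adaptation.
The product σ·*S*<sub>I</sub> (here 0.88) is the strongest single derived
feature downstream: low values flag patients who are both insulin
resistant and secretion limited.

At cohort scale:

```r
out <- run_pipeline(cohort_config(n_patients = 300, seed = 1),
                    inference_config(n_iter = 4000, burn_in = 1000, seed = 2),
                    n_boot = 1000)
subset(out$report$metrics, metric %in% c("auroc", "ap"))
#>   metric      mean     ci_lo     ci_hi
#> 1  auroc 0.8711996 0.7980298 0.9340450
#> 2     ap 0.8314033 0.7347694 0.9069737
```

A model using the six posterior-summary features alone separates the
latent groups well above chance, and the fitted coefficient on
σ·*S*<sub>I</sub> is negative: lower joint secretion-capacity ×
sensitivity means higher predicted risk of post-operative IGM.

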