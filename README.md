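# polyacal

Nonparametric Bayesian calibration of binary classifier scores via Polya
trees.

## The problem

Clinical decision support systems built on machine-learning classifiers
usually emit a raw score that is thresholded into a yes/no answer. Clinicians
and patients want probabilities — "this patient has a 51% chance of
developing heart disease" — and they want them *granular* (many distinct
probability levels) and *dynamic* (spanning a wide range, including the
extremes that matter for risk assessment). Standard calibrators (Platt
scaling, isotonic regression, quantile binning) impose a binning or a
parametric form; their granularity degrades exactly where calibration is
hardest, when the two classes' score distributions overlap heavily.

`polyacal` calibrates a score by asking a two-sample question: given the
held-out training scores **X**₁ of the positive class and **X**₂ of the
negative class, which parent distribution did the new score *X*ₚ come from?
The posterior of the hypothesis *H*₁ ("*X*ₚ shares a parent with **X**₁") is

> Pr(H₁ | Xₚ, X₁, X₂) ∝ Pr(Xₚ, X₁, X₂ | H₁) Pr(H₁),

with the likelihood modelled nonparametrically by a Polya tree: the score
axis is halved recursively into nested dyadic bins, each branch probability
carries a Beta(α_L, α_L) prior with α_L = L² at level L, and integrating the
branch probabilities out leaves a closed-form product of Beta-binomial
(Dirichlet-multinomial) terms over the tree's nodes,

> Pr_j(...|H₁) = [Γ(2α)/Γ(α)²]² · Γ(l₀+m₀+α)Γ(l₁+m₁+α)/Γ(l₀+l₁+m₀+m₁+2α) ·
> Γ(n₀+α)Γ(n₁+α)/Γ(n₀+n₁+2α)

where (l, m, n) are the left/right counts of *X*ₚ, **X**₁, **X**₂ at node
*j*; under H₂ the roles of **X**₁ and **X**₂ are exchanged. All arithmetic is
done in log space. Because nothing parametric is assumed about the score
distributions, the method inherits the classifier's quirks — multimodality,
skew, point masses — instead of fighting them, and the finite-sample
uncertainty of the training distributions is propagated into the posterior
automatically.

## Worked example

Simulate a classifier whose class-conditional score distributions are
unit-variance Gaussians with overlap coefficient 0.5, fit a calibration
model, and calibrate a few scores:

```r
library(polyacal)

train <- simulate_scores(overlap = 0.5, n_pos = 50, n_neg = 50, seed = 11)
model <- pt_calibrate(train$x1, train$x2)
model
#> Polya-tree calibration model
#>   class 1: 50 scores, class 2: 50 scores
#>   prior Pr(H1) = 0.5000, max level 18

round(predict(model, c(-2, 0.5, 1.23, 3)), 4)
#>   score posterior_h1 log_lik_h1 log_lik_h2
#> 1 -2.00       0.7652  -557.4531  -558.6342
#> 2  0.50       0.6421  -568.1181  -568.7025
#> 3  1.23       0.2281  -559.4237  -558.2043
#> 4  3.00       0.1864  -562.1000  -560.6263
```

The positive class is centred at 0 and the negative class at ≈1.35 (the
separation implied by overlap 0.5), so a score of −2 calibrates to a 77%
chance of being a positive case while a score of 3 calibrates to 19%; with
this much overlap the method correctly refuses to be more confident than
the data allow. `posterior_h1` is the calibrated probability;
`log_lik_h1`/`log_lik_h2` are the Polya-tree log marginal likelihoods under
the two hypotheses.

Evaluate the calibration on fresh test scores with a 10-bin reliability
diagram:

```r
test <- simulate_scores(overlap = 0.5, n_pos = 50, n_neg = 50, seed = 12)
pred <- predict(model, c(as.numeric(test$x1), as.numeric(test$x2)))
reliability_diagram(pred$posterior_h1, rep(c(1, 0), each = 50))
#> Reliability diagram: 100 predictions in 6 occupied bins
#>  bin mean_predicted frac_positive count sd_predicted
#>    2         0.1568       0.09091    22     0.022438
#>    3         0.2473       0.25000    28     0.020532
#>    4         0.3012       0.00000     1     0.000000
#>    7         0.6602       0.71429    14     0.007297
#>    8         0.7812       0.70000    10     0.011275
#>    9         0.8373       0.96000    25     0.011055
#> chi2 = 4.418 on 6 dof, p = 0.6203; range = 0.681
```

Six distinct probability levels are emitted (granularity), the mean
predictions span 0.68 of the unit interval (range), and the weighted χ² fit
to the diagonal is comfortably compatible with perfect calibration
(p = 0.62).

Held-out score distributions for a real feature table come from
cross-validation with any scorer satisfying the `train`/`score` contract;
the built-in k-means distance-ratio discriminant is the deliberately
marginal example:

```r
cv <- cv_scores(features, labels, kmeans_scorer(), scheme = "loo")
model <- pt_calibrate(cv$x1, cv$x2,
                      provenance = list(scheme = cv$scheme, seed = cv$seed))
```

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/cli/polyacal.R fit      --scores scores.csv --out model.json
Rscript inst/cli/polyacal.R predict  --model model.json --scores new.csv --out pred.csv
Rscript inst/cli/polyacal.R evaluate --model model.json --scores test.csv \
                                     --out metrics.csv --diagram diagram.csv
Rscript inst/cli/polyacal.R simulate --overlaps 0.3,0.6,0.9 --reps 20 --seed 1 --out sweep.csv
```

Score CSVs have header columns `id,score,label` with label 1 = positive.
Models are serialized as JSON holding the raw score arrays — the model *is*
the data.

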