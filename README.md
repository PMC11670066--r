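# coralAllee

Tools for quantifying **reproductive (component) Allee effects in
broadcast-spawning corals** from mapped colony data. When surviving
colonies become too far apart, sperm dilution limits cross-fertilization:
fertilization success declines steeply with the distance to the nearest
gravid neighbour. This package implements the full analysis chain for a
mapped spawning site — spatial neighbourhood metrics, overdispersed
regression of colony-level fertilization counts, spawning-synchrony
analysis, and a site-level fertilization-potential metric — together with
a synthetic-data generator so every stage can be exercised and validated
without field data.

It is aimed at coral reproductive ecologists and restoration practitioners
who map colonies (increasingly via photogrammetry) and score fertilization
from egg samples collected during mass-spawning nights.

## The model

For colony *c* sampled on night *t*, the number of fertilized eggs *k* out
of *n* scored is modelled as beta-binomial,

    k ~ BetaBinomial(n, mu, phi),    a = mu * phi,  b = (1 - mu) * phi
    logit(mu) = b0 + b_nn * nn_c + b_n2 * I(night 2) [+ further terms]

where `nn_c` is the distance (m) to the colony's nearest gravid neighbour
and `phi` is a precision parameter absorbing the overdispersion that egg
samples always show. Candidate proximity metrics — nearest gravid
neighbour, gravid-colony density within 2/5/10 m, and exponentially
distance-weighted gravid colony area within 10 m — are compared by AIC;
an optional colony random intercept is integrated out by adaptive
Gauss–Hermite quadrature. All likelihoods are maximised numerically by the
package's own optimiser.

The fitted night-1 decline is summarised by an ordinary cubic on the
percent scale,

    F(nn) = c3 nn^3 + c2 nn^2 + c1 nn + c0,   F0 = F(0),

and the spatial configuration of a whole site is reduced to its
**fertilization potential**

    Potential (%) = 100 / C * sum_c F(nn_c) / F0,

the mean, over the site's *C* colonies, of each colony's predicted
fertilization success relative to the maximum achievable at zero
separation. Spawning synchrony is analysed by regressing the absolute
pairwise difference in release minute on intercolony distance (with an
observer factor), with a within-night permutation test for the distance
slope that respects the non-independence of shared-colony pairs.

## Worked example

```r
library(coralAllee)

fx  <- make_study_fixture(seed = 42)        # synthetic two-night spawning site
dir <- tempfile(); write_study_fixture(fx, dir)

cfg <- run_config(seed = 1)
rep <- run_pipeline(cfg,
                    file.path(dir, "colonies.csv"),
                    file.path(dir, "spawn_events.csv"),
                    file.path(dir, "fert_samples.csv"))
rep
#> Allee-effect analysis report
#>   best model: nn (AIC 311.0)
#>   synchrony slope: 0.150 min/m (perm p 0.0001)
#>   F0: 26.8%; fertilization potential: 75.9% (cubic), 75.9% (direct)

rep$best_fit
#> betabinomial regression fit [nn+night]
#>             Estimate Std. Error Pr(>|z|)
#> (Intercept)  -1.0062     0.2199   0.0000
#> nn           -0.1674     0.0586   0.0043
#> night2       -0.7760     0.3062   0.0113
#> dispersion phi: 7.643  RE variance: 0
#> logLik: -151.5  AIC: 311.001  n: 36  converged: TRUE

rep$curve
#> fertilization-distance cubic: F(nn) = -0.0026646 nn^3 + 0.15588 nn^2 + -3.3311 nn + 26.784
#> F0 = 26.78%; fitted over [0, 20] m; clamped to [0, 100]
```

Reading the output: nearest gravid neighbour is the most parsimonious
proximity metric (lowest AIC among the five candidates); its negative
coefficient (−0.167 per metre on the logit scale) is the Allee effect —
each additional metre of isolation multiplies the odds of fertilization by
about `exp(-0.167) ≈ 0.85`. Night 2 roughly halves the odds. Pairwise
spawn-time differences grow by ~0.15 min per metre of separation (nearby
colonies spawn more synchronously). The site realises ~76% of the
fertilization it would achieve if every colony sat next to its neighbour;
`rep$potential` holds the per-colony breakdown. The synthetic truth behind
this fixture uses an intercept of −0.849, an nn slope of −0.16 and a
night-2 offset of −1.01 (see `reference_fit()`), so the fitted values are
sampling noise around those.

A thin command-line front end over the same functions is installed at
`inst/scripts/coralAllee` (subcommands `simulate`, `metrics`, `fit`,
`compare`, `synchrony`, `potential`, `run-all`).

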