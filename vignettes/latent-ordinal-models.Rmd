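---
title: "Latent ordinal models for attitude surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent ordinal models for attitude surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveyprobit)
```

## The model

Attitude questions offer K ordered answer options (for a five-point scale:
strongly oppose, oppose, neutral, support, strongly support). Treating the
answer codes 1..K as a metric variable assumes equal spacing between
categories and is known to distort inference, so `surveyprobit` uses the
ordered-probit construction instead: each respondent holds a latent opinion

$$z \sim \mathcal{N}(\mu, \sigma^2),$$

and answers category $k$ when $z$ falls between the thresholds
$\theta_{k-1}$ and $\theta_k$, so that

$$p(y = k \mid \mu, \sigma, \{\theta_j\}) =
  \Phi\!\left(\frac{\theta_k - \mu}{\sigma}\right) -
  \Phi\!\left(\frac{\theta_{k-1} - \mu}{\sigma}\right),$$

with virtual thresholds $\theta_0 = -\infty$ and $\theta_K = +\infty$.

**Identification.** With $\mu$, $\sigma$ and all thresholds free, the latent
scale is not identified. We anchor it to the response scale: categories are
coded 1..K, the extreme thresholds are fixed at
$\theta_1 = 1.5$ and $\theta_{K-1} = K - 0.5$ (never sampled), and the
interior thresholds are estimated. Under this anchoring, a latent mean of
$(K+1)/2$ means "exactly neutral", and equal-width bins correspond to
$\theta_j = j + 0.5$. Other anchorings (for example $\mu = 0$, $\sigma = 1$)
would identify the same likelihood; we chose the scale-bound anchoring
because it keeps $\mu$ interpretable in units of the answer scale.

**"I don't know" answers.** A DK option is not an ordinal category — it does
not sit between "oppose" and "support". It is modelled as a separate mixture
component: a respondent answers DK with probability $\delta$, and otherwise
draws an ordinal answer from the probit cell probabilities, giving the
(K+1)-vector $(\delta, (1-\delta)p_1, \ldots, (1-\delta)p_K)$. Item
non-response (a blank cell) is a different phenomenon; it is excluded from
the likelihood and only counted. That distinction is a package decision: only
the DK channel is modelled, because only DK is an answer the respondent
actively gave.

## Priors

Weakly informative defaults, all overridable via `prior_spec()`:

| parameter | prior | default rationale |
|---|---|---|
| $\mu$ | normal$((K+1)/2,\, K^2)$ | centred at the scale midpoint, sd of one full scale width |
| $\sigma$ | uniform$(0.01,\, 10K)$ | broad; excludes degenerate zero |
| free $\theta_j$ | normal$(j + 0.5,\, K^2)$ | centred at the equal-spacing value |
| $\delta$ | uniform$(0, 1)$ | no prior information on DK rates |
| coefficients $\beta_i$ | normal$(0,\, (10K)^2)$ | effectively flat |

Threshold ordering is enforced by rejection (the log prior is $-\infty$ for
an unordered vector) rather than by reparameterizing to increments: the
sampler contract is simpler and the posterior never visits measure-zero
boundaries in practice.

## The rural/urban group model and country weighting

Balanced panels deliberately sample equal rural and urban quotas, which does
not match any country's population. The group model therefore estimates
group-specific latent means and standard deviations
$(\mu_R, \sigma_R, \mu_U, \sigma_U)$ — and, where applicable, group DK
probabilities $(\delta_R, \delta_U)$ — while sharing one threshold vector
across groups, since the answer categories mean the same thing for
everybody. Priors are independent across groups: no assumption of
rural/urban similarity or difference.

Country-level answer probabilities are computed **per posterior draw** as

$$p_{\text{country}} = w_R \, p(\mu_R, \sigma_R, \theta, \delta_R)
  + (1 - w_R) \, p(\mu_U, \sigma_U, \theta, \delta_U),$$

where $w_R$ is the country's actual rural population share, and then
summarized across draws. Mixing probability vectors per draw (rather than
pooling latent draws across groups) is the direct way to propagate joint
posterior uncertainty into the weighted estimate, and it makes the posterior
mean of the country vector exactly the weighted combination of the group
posterior means — a property the tests check to machine precision. Point
estimates are posterior means; medians and central 95% intervals are also
reported (`country_posterior()` keeps the full draw matrix).

## The covariate model

The second model replaces the common latent mean with a linear predictor per
respondent $i$:

$$\mu_i = \alpha + \beta_1 \,\text{location}_i + \beta_2 \,\text{sex}_i
  + \beta_3 \,\text{age}_i + \beta_4 \,\text{politics}_i,$$

with reference levels rural, female and political centre, and politics
entering as four dummies (extreme left, left, right, extreme right).
$\sigma$ is modelled independently of the predictors; the DK probability
remains a single covariate-free $\delta$. Age is standardized to mean 0, sd 1
within the fitted stratum — a numerical choice for sampler stability, not a
modelling claim; `coefficient_report()` returns both the per-sd estimate and
the per-year conversion (divide by the stratum age sd). Respondents missing
the answer or the politics item are removed listwise and counted
(`build_design()` reports the count); a stratum whose politics column is
entirely missing is refused because the model as specified is then
unidentifiable. A covariate that is constant in a stratum (for example
location in a rural-only sample) is flagged as unidentifiable and its
coefficient simply follows its prior.

"Significant" in reports means: the central 95% equal-tailed credible
interval excludes zero (`ci_excludes_zero`).

## Sampling and convergence

`sample_posterior()` is a multi-chain adaptive random-walk Metropolis
sampler over an arbitrary log-posterior. Parameters are updated in blocks:
scalar blocks use a normal random walk tuned towards 44% acceptance; the
covariate model's eight linear coefficients form one multivariate block
whose proposal covariance is estimated from the burn-in history (tuned
towards 23% acceptance). All adaptation stops at the end of burn-in, so
retained draws come from a fixed Markov kernel. Chains run sequentially;
chain $c$ seeds its RNG with `seed + c`, making every fit bit-reproducible
from its configuration. Defaults are six chains of 10,000 iterations with
5,000 burn-in.

Convergence is assessed with the classic (non-split) Gelman–Rubin potential
scale reduction factor, computed per parameter:
$\hat R = \sqrt{\hat V / W}$ with
$\hat V = \frac{n-1}{n} W + \frac{B}{n}$. The split-chain variant differs
slightly; the classic form is used deliberately and documented so the
reported numbers are unambiguous. Parameters with $\hat R > 1.1$ are
flagged, and the batch runners return a nonzero status when any parameter
exceeds the threshold. Chains with zero within-chain variance raise an
explicit undefined-diagnostic condition rather than returning NaN.

The sampler is validated against fixed targets rather than against itself: a
standard-normal target, a conjugate normal-mean posterior with a closed-form
answer, and parameter-recovery simulations (below).

## The synthetic-survey generator

`simulate_survey()` produces respondent-level datasets with exactly the
structure the models assume, so every stage is testable by parameter
recovery without any real deposit. The default scenario mirrors a balanced
multi-country online panel: 23 countries, ~500 respondents each, exactly
equal rural/urban and female/male counts, ages from a normal(49, 17)
truncated to 18–95 years, political orientation drawn from a fixed
five-category distribution (8/24/36/24/8%). Group truths vary smoothly
across countries with a small urban–rural gap and DK shares of roughly
0.1–0.3, echoing the empirical pattern that neutral/no-opinion shares in
attitude surveys about wildlife are large. The per-scenario random stream
has a documented draw order — demographics, then DK indicators, then latent
values — so datasets are reproducible bit for bit.

What the generator does **not** emulate: correlations between questions
(each question is simulated independently), non-response mechanisms that
depend on covariates, measurement error in demographics, or panel selection
effects. Passing recovery tests therefore demonstrates correctness of the
estimation machinery under the model's own assumptions, not robustness to
violations of them.

`recovery_experiment()` wraps the simulate–fit loop: per replicate it
records posterior means, sds, 95%-interval coverage of the truth and R-hat,
excludes non-converged replicates (any $\hat R > 1.1$) from the coverage
summary with a logged count, and reports bias, RMSE and empirical coverage
per parameter.

## Problem sizes used in the shipped checks

The test suite exercises recovery at the scale the models are meant for:
single-group fits at n = 5,000 with six chains of 10,000 iterations;
group fits at 1,500–2,500 per stratum; and a 20-replicate coverage
experiment for the covariate model at n = 2,000 with four chains of 4,000
iterations per fit. Four chains with a shorter run are the package's default
for replicated recovery experiments: with the blocked, covariance-adapted
proposal the effective sample size per fit is ample for interval coverage,
and replication across 20 independent datasets is the stronger check.
Smaller fixtures (a few hundred respondents, 1,000–3,000 iterations) are
used where the property under test is structural rather than statistical.

## Degenerate inputs and numerical choices

* Probabilities are computed as differences of `pnorm` values; a cell
  probability that underflows to zero with an observation in it yields a
  log-likelihood of $-\infty$ (rejection), never NaN.
* $\sigma \to 0$ concentrates all mass in the bin containing $\mu$; the
  uniform prior's lower bound (0.01) keeps the sampler away from the
  degenerate point.
* Empty strata are explicit objects (`n_total == 0`) that every fitting
  function refuses with a named error.
* `K = 3` has no free interior thresholds — both are fixed — and the code
  path is exercised in tests.
* Display percentages round half up at whole-percent granularity
  (`percent_half_up()`); exported tables keep full precision.

## Known limitations

* No pooling across countries: each country is fitted independently, by
  design. A hierarchical country model is out of scope.
* The probit link is the only link offered; the latent-normal assumption is
  what fixes the cell-probability formula.
* No covariate interactions and no covariate effects on $\sigma$ or
  $\delta$.
* Real-survey features the generator does not emulate (see above) are
  untested territory; the package's guarantees are about the model it
  implements.
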