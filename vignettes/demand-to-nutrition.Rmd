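---
title: "From food demand systems to nutrient adequacy: methods"
author: "easidemand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From food demand systems to nutrient adequacy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(easidemand)
```

# What the package models

`easidemand` estimates how household food demand — and through it, nutrient
intake and diet quality — responds to total expenditures and food prices,
using the kind of multi-wave household consumption survey collected in
low-income countries (7-day recall of food quantities and values by item and
acquisition source, plus a household roster and non-food spending). The
demand side is an incomplete Exact Affine Stone Index (EASI) system over `J`
food groups plus a composite non-food numeraire; including the numeraire
means food/non-food substitution is modelled rather than assumed away by
separability.

The latent budget share of food group $j$ is

$$ w_j \;=\; \sum_{r=0}^{R} b_{jr}\, y^r \;+\; \sum_k a_{jk} \ln p_k
   \;+\; y \sum_k d_{jk} \ln p_k \;+\; g_j' z \;+\; m_j' \bar c \;+\; \varepsilon_j $$

with $y$ implicit utility (real expenditures), $\ln p$ log group price
indices (numeraire normalised to zero), $z$ demand shifters (household
size, urbanity, head age and sex, wave indicators) and $\bar c$ cluster
means of the time-varying regressors — the Mundlak–Chamberlain device that
absorbs time-invariant unobserved preference heterogeneity at the community
level. Symmetry ($A = A'$, $D = D'$) and homogeneity (zero row sums, with
the numeraire column implied by adding-up) are imposed in estimation; the
numeraire share is $1 - \sum_j w_j$.

## Implicit utility: exact-affine versus Stone-deflated

Two conventions exist for $y$. The *Stone-approximate* form deflates
nominal expenditures by the household's own Stone price index,
$y = \ln x - \sum_k w_k \ln p_k$. The *exact-affine* form solves the cost
function identity and gives

$$ y \;=\; \frac{\ln x - \sum_k w_k \ln p_k + \tfrac12 \ln p' A \ln p}
               {1 - \tfrac12 \ln p' D \ln p}. $$

The package defaults to the exact-affine form (`utility = "exact"`) and
offers the approximation as an option. The reason is substantive: under the
exact form the envelope condition $\partial y/\partial \ln p_k = -w_k\,
\partial y / \partial \ln x$ holds at the fixed point, and one can show the
quantity $w_j \epsilon^H_{jk} = a_{jk} + y\,d_{jk} + w_j w_k -
\delta_{jk} w_j$ is symmetric in $(j,k)$ *exactly* — Slutsky symmetry of
the Hicksian elasticities is an algebraic identity, not an approximation.
Under the Stone form the deflator contributes extra direct price terms and
symmetry only holds up to terms of order $a \cdot \ln p^2$. All four
classical identities (Engel aggregation, Cournot aggregation, homogeneity,
Slutsky symmetry) are exact at every observation under the default, and the
test suite asserts them at `1e-8`.

Since $y$ depends on the shares and the shares on $y$, prediction solves a
one-dimensional fixed point per observation (damped iteration, damping 0.5,
tolerance `1e-10`, initialised at $y = \ln x$); a scalar root-finder oracle
in the tests confirms the solution.

# Estimation

`easi_fit()` runs an iterated, restricted, system instrumental-variables
estimator on the `J` food share equations (the numeraire equation is
dropped and recovered by adding-up):

1. **Restrictions.** A restriction matrix maps a free parameter vector to
   all equation coefficients: off-diagonal upper triangles of $A$ and $D$
   are free, diagonals are the negative row sums, symmetry ties the
   cross-equation blocks. Restrictions therefore hold exactly for the
   point estimates and for every simulated parameter draw.
2. **Endogeneity, source one.** The household's own shares sit inside its
   Stone index, hence inside $y$. The utility regressors (powers of $y$,
   and $y \ln p$ interactions) are instrumented with versions built from
   the *average-share* Stone index (sample-average budget shares in place
   of own shares).
3. **Endogeneity, source two.** Unit-value price indices embed quality
   choice and price search. Price regressors are instrumented with
   leave-one-out cluster-wave mean log prices of neighbouring households,
   which retain the cluster-level market price variation but purge
   household-specific premia. First-stage strength is reported in the fit
   report.
4. **Censoring.** Zero consumption of a group over the 7-day recall is
   handled by the two-step probit-corrected system: a participation probit
   per group on all exogenous regressors and instruments yields
   $\Phi_{ij}, \phi_{ij}$, and the corrected share equation is
   $w_{ij} = \Phi_{ij}\, x_i'\beta_j + \theta_j \phi_{ij} + e_{ij}$. This
   is one concrete member of the latent-demand (Tobit-family) estimators;
   full simulated-likelihood multivariate Tobit is out of scope. Groups
   with fewer than 30 zeros or under 1% censoring are treated as
   uncensored — with almost no zeros the probit density column is nearly
   constant and collinear with the intercept, which destabilises small
   samples while adding nothing.
5. **Weighting.** The stacked system is weighted by the inverse residual
   covariance across equations (feasible GLS / 3SLS flavour), updated each
   iteration; with a singular residual covariance (noiseless data) the
   identity weighting is used.
6. **Iteration.** $y$ depends on $(A, D)$; the estimator alternates
   computing $y$ from observed shares and re-solving the restricted
   system, with damping 0.5 on the $(A, D)$ values used in $y$, declaring
   convergence when the full-step parameter change falls below `1e-8`
   (default cap 100 iterations, with automatic relaxation if the map
   oscillates). The polynomial is centred at the sample mean of $y$
   internally — a pure reparameterisation undone on exit — because raw
   powers of $y \approx 4$ are severely collinear.
7. **Inference.** The covariance of the free parameters is a
   heteroskedasticity-robust sandwich with scores summed within household
   (household-clustered), on the weighted moments.

Degree selection (`select_degree()`) fits each candidate Engel-curve degree
and minimises the BIC computed on the stacked system residuals; all
criterion values are recorded.

**Identification caveat.** Price *levels* are only identified up to
group-specific constants once unit values are re-based by the Fisher index:
re-basing is absorbed by the intercepts (exactly, thanks to homogeneity)
but perturbs the utility construction at order $c \times$ (share
variation). Machine-precision recovery of the generating coefficients is
therefore only a well-posed question when the estimator sees the exact
generating prices, which is what `prepare_from_truth()` provides for the
oracle tests; through the realistic survey path the tests assert recovery
at the tolerances statistical noise permits.

## A worked residual-distribution refinement

Policy counterfactuals need not only mean demand but the *distribution* of
intake around it (sufficiency is a threshold event). Interior residuals
understate the latent error dispersion when censoring is material, so after
the system converges the package refits, per group, a location and scale of
the latent error by censored (Tobit) maximum likelihood — interior
residuals enter through the normal density, censored observations through
the normal mass below the truncation point — keeping the interior
correlation structure across groups. These calibrated distributions are
used only by the policy module's sufficiency probabilities.

# Survey preparation

* **Unit values.** Purchases are valued at `value/quantity`; non-purchased
  and non-consuming household-items receive the median purchaser unit value
  at the smallest geography with at least 5 purchase observations
  (cluster, then stratum, then national), with the level flagged. Medians
  resist outlying unit values.
* **Fisher group indices.** Within each group, a Fisher Ideal index
  (geometric mean of Laspeyres and Paasche) of the household's item unit
  values against a wave-1 base (sample-mean purchaser prices and
  sample-mean quantities). An empty current basket degrades the Paasche
  leg to Laspeyres. The base is fixed across waves so indices are
  comparable over time.
* **Aggregates.** Total weekly expenditures = food from all sources valued
  at unit values + non-food. Adult equivalents use a configurable age
  scale (default: under-15 count 0.5, 15–59 count 1.0, 60+ count 0.8).
  Expenditure groups Q1–Q4 are assigned at the international poverty lines
  1.90 / 3.20 / 5.50 US\$ PPP per AE per day, half-open and
  lower-inclusive.
* **Instruments and CRE.** Leave-one-out cluster-wave mean log prices
  (stratum fall-back for singletons, flagged); the average-share Stone
  index; cluster means of prices, log expenditures and shifters, dropping
  cluster-constant columns (an urban flag's cluster mean *is* the column).

# The synthetic data generator

`generate_preferences()` + `generate_panel()` produce an LSMS-style panel
from a known EASI process so that every downstream stage can be validated
against ground truth. Default conditions: 2,000 households over 3 waves in
100 clusters, 6 food groups of 3 items plus the numeraire, quadratic Engel
curves, log expenditures per AE per day $\sim N(\log 2.4, 0.7^2)$ — which
places roughly a third of households under the extreme poverty line —
cluster-by-wave log price dispersion 0.15, and item prices carrying a
quality premium (loading 0.1 on the expenditure z-score) and a price-search
premium (loading 0.1 on the standardised preference error), so that the
two instruments are genuinely needed. Base price levels around
2 US\$ PPP/kg put dietary energy sufficiency on a steep gradient across the
expenditure distribution rather than saturating it. Preference draws are
rejection-sampled until latent shares at the median household lie in
(0.01, 0.6), own-price coefficients are negative, and shares stay
near-admissible over the realised utility range.

Censoring arises by *truncation*: latent shares below zero are recorded as
zero with the released budget assigned to the numeraire (renormalised if
the numeraire floor 0.01 binds). The error scale default (0.05, flat
across groups with small-share groups drawn from a long-tailed weight
distribution) yields roughly 15% zero household-group records, with zeros
concentrated in small-share groups as in survey data. All random draws are
made up-front in a fixed order: an intervention hook (`x_add_weekly`,
`lnp_shift`) reuses bit-identical draws, which is what makes brute-force
ground-truth re-simulation of a policy possible, and item prices are formed
from *baseline* expenditures so a transfer changes demand, not the price
process.

What the generator does **not** emulate: seasonality, attrition, recall
measurement error, food away from home, intra-household allocation, and
any general-equilibrium price response. Passing tests on this process
therefore validate the estimator and the accounting, not robustness to
those real-data features.

# Elasticities

Expenditure and price elasticities are evaluated analytically at every
observation by total differentiation through the utility fixed point; a
central finite-difference oracle confirms them to relative error `1e-4`.
By default they describe the *latent* (preference-consistent) demand
system; `demand = "adjusted"` scales derivatives by the participation
probabilities for accounting on the censored demand, at the cost of exact
Slutsky symmetry (with heterogeneous $\Phi_j$ the symmetric part is scaled
asymmetrically). Numeraire rows/columns come from adding-up and
homogeneity. Cells with a predicted share under `1e-4` are flagged and
excluded from medians. Reporting follows the median-by-expenditure-quartile
convention; standard errors come from multivariate-normal parameter draws
around the estimate (restrictions hold per draw by construction of the
free parameterisation), re-evaluating the median tables per draw on a
quartile-stratified subsample (default 400 observations, 200 draws in the
pipeline) and taking the across-draw standard deviation.

Nutrient-intake elasticities are composition-weighted sums: with source
shares $s_{nj}$ (share of nutrient $n$ from group $j$),
$e_{nx} = \sum_j s_{nj}\eta_j$ and $e_{np,k} = \sum_j s_{nj}
\epsilon_{jk}$, and the staple-price decomposition splits $e_{np,k}$ into
an own-price part $s_{nk}\epsilon_{kk}$ and the cross-price remainder —
the quantity that shows why staple prices move intake of nutrients not
concentrated in the staple.

# Diet quality

Three measures per household-wave, all computable from group quantities,
the composition table and the roster:

* **Adequacy.** 7-day intake of dietary energy, carbohydrate, protein,
  fat, iron, zinc, vitamin A and folate versus household requirements
  (sum of members' daily EER/EAR over 14 age-sex classes, times 7);
  sufficiency is boundary-inclusive. The shipped requirement and
  composition tables are documented synthetic defaults patterned on
  standard references, and both are replaceable arguments.
* **Balance.** Energy shares of protein/fat/carbohydrate by Atwater
  factors 4/9/4, over macronutrient-derived energy (so shares add to one
  by construction), classified against the recommended 10–15%, 15–30% and
  55–75% ranges, boundary-inclusive.
* **NRFI.** An NRF9.3-style density score on a 2,000 kcal basis: nine
  qualifying components capped at 100% of their reference amounts minus
  three uncapped moderation components. Density normalisation makes the
  score invariant to proportional quantity misreporting, which the tests
  assert exactly.

# Policy simulation

The cash transfer adds 20% of median Q1 monthly household expenditures
(flat, not size-adjusted; spend fraction $\kappa$, default 1) to total
expenditures and re-solves demand at unchanged prices; the price discount
multiplies the prices of one category (SG, SS, PN, FFV, ASF — mapped from
composition archetypes or a user category map) by $1-\delta$, default
$\delta = 0.25$, at unchanged expenditures, for all consumption regardless
of source (imputed unit values are opportunity costs; a purchases-only
switch is out of scope). Monthly values convert at $365.25/12/7$ weeks per
month. The government cost of a discount is its redeemed value,
$\sum_{j \in \text{cat}} \delta\, p^0_j q^{\text{post}}_j$, reported as
quartile medians; the transfer's cost is its amount. Producer prices and
wages are held fixed by assumption.

Sufficiency outcomes are reported as *predicted probabilities*: intake is
linear in the budget shares, so the calibrated latent error distribution is
simulated (48 draws, keyed to household order for permutation invariance)
with the same truncation-at-zero mechanism that generates censoring, and
the sufficiency indicator averaged. On synthetic ground truth this makes
model-simulated post-intervention quartile sufficiency shares agree with
brute-force re-simulation from the generating preferences to within two
percentage points at the exemplified study condition; across other seeds
the worst nutrient-by-quartile cell differs by up to about four points,
which is the footprint of parameter estimation noise at 2,000 households
rather than of the simulation machinery.

# Numerical choices and limitations

* Fixed points: prediction tolerance `1e-10` (cap 100 iterations),
  estimation tolerance `1e-8` on the full-step parameter change, both
  damped; non-convergence is an error (prediction) or warning (fit).
* Degenerate inputs: never-consumed groups, never-purchased items,
  nonpositive expenditures or prices, empty rosters and unmapped members
  raise named errors; groups consumed by everyone short-circuit the
  censoring stage.
* Ties and boundaries: all interval rules (quartiles, balance classes,
  sufficiency) are lower-inclusive and documented.
* Problem sizes in the tests were chosen to exercise the estimator at the
  default study conditions (2,000 x 3) where the scientific claims live,
  and at small sizes (300-600 households) elsewhere; the oracle suite
  covers 100 random parameter draws.
* Known limitations: the two-step censoring correction is not a full
  multivariate Tobit and breaks exact adding-up of fitted shares (the
  predicted numeraire share absorbs the gap, floored at 0.005 with the
  renormalisation counted); elasticity standard errors ignore first-stage
  probit estimation noise; the adjusted-demand elasticity option violates
  exact Slutsky symmetry, which is why the latent demand is the default.
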