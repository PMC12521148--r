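---
title: "A three-state decision-tree cost-utility model for pediatric asthma inhaler regimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state decision-tree cost-utility model for pediatric asthma inhaler regimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qalytree)
library(dplyr)
```

## The model

qalytree evaluates the pharmacoeconomics of inhaled corticosteroid (ICS)
and ICS-LABA maintenance strategies in pediatric asthma. The clinical
course is reduced to three mutually exclusive health states a medical
visit can fall into:

* `symptom_free` — a maintenance visit with no exacerbation,
* `outpatient_exacerbation` — an acute exacerbation managed in outpatient
  care,
* `hospitalization` — an acute exacerbation requiring admission.

Each treatment strategy is a single chance node with these three branches.
A branch carries a cost $c_i$ (CNY), a probability $p_i$ and a utility
$u_i$ (QALYs), and the strategy's value is the pair of expectations

$$E[C] = \sum_i p_i c_i, \qquad E[U] = \sum_i p_i u_i.$$

This is deliberately a *single-decision tree*, not a Markov cohort model:
a patient's whole horizon is attributed to the state mix observed in their
visits. There are no cycles, no transitions and no half-cycle correction,
and the reserved discount-rate field defaults to zero because the
utilities the model reproduces are undiscounted products (see below).

### Utilities

Branch utilities come from a base annual utility for a well-controlled
year, $u_{\text{base}} = 0.867$, with annual decrements $d_i$ of $-0.1$
(outpatient exacerbation) and $-0.22$ (hospitalization), accumulated over
a horizon $H = 18$ years:

$$u_i = (u_{\text{base}} + d_i)\, H.$$

With the defaults this gives 15.6060, 13.8060 and 11.6460 QALYs. The
values are literature-derived weights for pediatric asthma; the package
treats them as inputs, exposes them through `utility_model()`, and errors
if a decrement drives a lifetime utility below zero. `state_utilities()`
is linear in the horizon, which the test-suite checks as a property.

### Probabilities

The branch probabilities are *per-visit shares*: the fraction of all
recorded visits, per strategy, that fell in each state,
$p_i = n_i / \sum_j n_j$ (`visit_share_probabilities()`). The study behind
the packaged tables never states how its printed branch probabilities
were obtained, but the visit-share reconstruction reproduces all 18
printed cells to four decimals from the printed visit counts, so the
package adopts it — flagged here as an inference, not a documented
derivation. The synthetic-cohort aggregation mirrors the same convention
(probabilities are shares of visits, not of patients).

### Two cost bases

Costs are tracked on two explicit bases — `"ics"` (ICS drug costs only)
and `"medication"` (total medication: ICS + traditional Chinese medicine +
other agents). The basis travels with every parameter table and result as
an attribute, and comparisons across bases are refused
(`cost basis mismatch`), because a ratio of an ICS-cost difference to a
utility difference means something different from its total-medication
counterpart.

## Cost-effectiveness analysis

The CEA side uses a clinical effect measure instead of utilities: the
percentage of patients whose *longest symptom-free duration* reached 3, 6,
12 and 24 months ($E_3, E_6, E_{12}, E_{24}$, from
`effectiveness_rates()`). Ratios are

$$C/E = \frac{\text{cost}}{\text{effect}}, \qquad
  \text{ICER} = \frac{\Delta C}{\Delta E},$$

with the effect kept in *percentage points* (a cost of 3824.02 CNY at 75%
effectiveness gives $C/E_3 = 50.99$ CNY per percentage point). Storing the
percentage rather than the fraction matches how such tables are printed
and read in this literature; the unit is documented on every output.

Two conventions are fixed once:

* **Reference arm.** Each ICER pair is oriented so the lower-cost
  strategy is the reference (`cea_table(orient_by_cost = TRUE)`). This
  reproduces the printed tables, where the single-inhaler A subgroups
  orient by whichever of A1/A2 is cheaper on the basis at hand.
* **Dominance.** Every incremental ratio is paired with its quadrant
  label (`alt_dominates` / `ref_dominates` / `tradeoff` / `equivalent`,
  `classify_dominance()`). A bare negative ratio is never interpreted on
  its own: it arises both when the alternative is dominated and when it
  dominates, so the verdict always comes from the quadrant, and when the
  effect difference is zero the ratio is left `NA` while the quadrant is
  still reported.

## Cost-utility analysis and the WTP verdict

`icur()` computes $\Delta C / \Delta U$ in CNY/QALY and compares tradeoff
pairs against a willingness-to-pay threshold, default
$\lambda = 287{,}100$ CNY/QALY (three times China's 2024 per-capita GDP).
`nmb()` provides the equivalent net-monetary-benefit view,
$\text{NMB} = \lambda E[U] - E[C]$; for any pair gaining utility,
$\text{NMB}_{\text{alt}} > \text{NMB}_{\text{ref}}
\iff \text{ICUR} < \lambda$, an identity the suite verifies over random
pairs, including the flip exactly at $\lambda = \text{ICUR}$.

One discrepancy in the source tables is worth recording: the narrative
text quotes the triple-vs-dual comparison's ICS-basis ICUR as the same
20,632.18 CNY/QALY as the medication basis, while the printed ICS block
gives 7,444.57 — and only the latter is consistent with the parameter
table's arithmetic. The packaged fixture and the tests therefore assert
7,444.57 on the ICS basis.

The printed strategy rows themselves were evidently computed from the
4-decimal probability dialect of the parameter table; the package carries
full precision internally and its published checks use a 0.5% relative
band for table comparisons (costs/ratios print at 2 decimals,
probabilities/utilities at 4).

## Probabilistic sensitivity analysis

`run_psa()` propagates parameter uncertainty by Monte Carlo (default
1,000 iterations):

* **Costs** get Gamma priors matched by moments,
  $\text{shape} = (\mu/\sigma)^2$, $\text{scale} = \sigma^2/\mu$
  (`fit_gamma_from_moments()`; the fit preserves both moments exactly and
  the round trip is tested as an identity). Where the packaged tables
  print a per-state sd it is used; otherwise a configurable coefficient
  of variation (default 0.3) applies, and an sd of zero keeps the
  parameter fixed.
* **Probabilities** get a joint Dirichlet prior with the visit counts as
  concentration (`dirichlet_from_counts()`). Each marginal is then
  Beta(count, total − count) — the natural three-state generalisation of
  putting a Beta on each probability — while every draw still sums to 1.
  The marginal-moment agreement with the Beta closed form is tested at
  $10^5$ draws.
* **Utilities** stay fixed in the base configuration, since the source
  analysis lists distributions only for costs and probabilities; an
  optional Beta-on-base-utility mode (`vary_utilities = TRUE`) exists but
  is off by default.

Because the source study never published the dispersions behind its own
simulation, its scatter plots are not numerically reproducible;
validation of this module is therefore *property-based* (degenerate PSA
equals the base case, CEAC endpoints equal the cost-saving and
utility-gaining draw fractions, $O(1/\sqrt n)$ shrinkage of the Monte
Carlo error, bit-reproducibility under a seed) rather than
figure-matching.

**Seeding.** Each parameter owns a substream whose seed is a byte-rolling
hash of its identifier (e.g. `ref:A/cost/symptom_free`) folded into the
root seed modulo $2^{31}-1$. Adding or removing one parameter therefore
never reshuffles the draws of the others, and a (seed, spec) pair pins
the entire draw table bit-for-bit.

**The plane and the ellipse.** `ce_plane_summary()` summarises the
incremental cloud with a bivariate normal-theory confidence ellipse
(Mahalanobis radius $\sqrt{\chi^2_{2,\alpha}}$). "Most simulations within
the 95% confidence interval" is not a defined construct for a scatter
plot, so the package makes this concrete, documented choice; its nominal
coverage is verified on synthetic bivariate-normal clouds. `ceac()`
reports, per $\lambda$ on a grid, the fraction of draws with positive
incremental net benefit. `autoplot()` methods draw both figures.

## The synthetic cohort

`generate_cohort()` exists so the full pipeline — records to visit shares
to expected values to ICURs — can be exercised and tested without the
study's raw charts, which were never deposited. Its defaults
(`asthma_cohort_config()`) are the study conditions as printed: subgroup
sizes 8/22/21/8, visit-count means and sds per subgroup, visit-share
state vectors, per-category cost moments per state, and symptom-free
exceedance targets at 3/6/12/24 months.

Distributional choices, each made once:

* **Visit counts** — negative binomial matched by moments (the printed
  sds exceed the means, ruling out Poisson), with zero draws resampled so
  every patient has at least one visit. The resampling biases the visit
  mean up slightly; no calibration target depends on the visit mean.
* **Per-visit costs** — independent Gammas per category (ICS, TCM, other
  medication, non-medication): non-negative and right-skewed like the
  printed summaries. The source reports no covariances, so none are
  modelled; consequently the generator will not reproduce any real
  correlation between, say, ICS and non-medication spending.
* **Longest symptom-free duration** — piecewise-exponential between the
  calibration thresholds, passing exactly through the target exceedance
  probabilities, with the last segment's hazard carried into the tail.
  Non-monotone targets are rejected (`infeasible exceedance targets`).
* **States i.i.d. per visit** — no within-patient serial correlation.
  This matches the information the decision model actually uses (visit
  shares), but it means the cohort understates the clustering of
  exacerbations real records would show; recovery tests validate the
  *model inputs*, not patient-level realism.

`aggregate_cohort()` reduces a cohort exactly the way the study reduced
its records: visit-state counts to probabilities, per-visit state means
to branch costs on both bases (medication = ICS + TCM + other), durations
to effectiveness rates. A state with no visits gets probability 0 and a
zero placeholder cost in the strategy table (it carries no weight there);
the cost summary reports it as absent. Round-trip recovery is tested at
$10^4$ patients per subgroup: state shares within ±0.01 absolute, state
cost means within ±5%, exceedance rates within ±2 percentage points —
tolerances chosen from the binomial/Gamma standard errors at that size.

## Numerical conventions and edge cases

* Probability sums are accepted within `5e-4` when a table arrives in the
  printed 4-decimal dialect (one packaged column sums to 0.9999), and
  within `1e-9` for freshly derived shares.
* All internal arithmetic is full double precision; rounding happens only
  in print methods (2 decimals for money and ratios, 4 for probabilities
  and utilities).
* Degenerate inputs have defined behaviour rather than NaNs: all-zero
  visit counts, empty cohorts, zero effects, zero-variance PSA clouds and
  missing states all raise typed errors or warnings tested by name.
* Problem sizes in the shipped checks — $10^4$ patients per subgroup for
  recovery, $10^5$ Dirichlet draws for moment checks, 1,000 PSA
  iterations — were chosen as the sizes at which the relevant standard
  errors sit comfortably inside the stated tolerances.

## Worked example

```{r example}
params <- asthma_strategies("ics")
res <- evaluate_strategy(params)
res

icur(res, ref = "A", alt = "B", wtp = wtp_threshold())

psa <- run_psa(asthma_psa_spec("A", "ics"), asthma_psa_spec("B", "ics"),
               n = 1000, seed = 1)
glance(psa)
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(psa)
autoplot(ceac(psa), wtp = wtp_threshold())
```

## Limitations

The model inherits every limitation of its single-tree structure: no
time-dependence within the horizon, utilities attached to whole-horizon
state mixes, and per-visit shares standing in for patient-level
transition behaviour. The packaged aggregates come from a small (59
patients), single-center, retrospective cohort with unbalanced subgroups;
the package reproduces that analysis faithfully but cannot make its
evidence stronger. And because the PSA priors' dispersions are partly
reconstructed (printed sds where available, a CV fallback elsewhere),
PSA output should be read as a robustness probe of this model, not as an
estimate of real-world parameter uncertainty.
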