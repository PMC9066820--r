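---
title: "Disproportionality analysis of spontaneous reports with the Information Component"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous reports with the Information Component}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icsignal)
```

## The problem

Spontaneous-report databases collect individual case safety reports
(ICSRs): one report describes one patient, the drugs they took and the
suspected adverse reactions, coded with MedDRA Preferred Terms (PTs).
Because there is no denominator of exposed patients, safety signals are
sought by *disproportionality*: is an event reported with a drug more
often than the database as a whole would predict?

`icsignal` implements this case/non-case machinery end to end for the
motivating use case of vasospastic events (Raynaud's phenomenon) with
CGRP-targeting migraine drugs (ATC class N02CD), including the
comparator-restricted variant used to control for confounding by
indication, the descriptive layer a case series is reported with, and a
simulator of spontaneous-report stores for validating the whole pipeline.

## The Information Component

All counting is **report-level**: a report contributes at most once to any
cell however many of its drug or reaction entries match. For a drug query
$D$ and event query $E$ over $N$ reports in scope, with $n_D$ reports
involving the drug, $n_E$ involving the event and $O$ involving both, the
expected count under independence is

$$E = \frac{n_D\, n_E}{N},$$

and the Information Component is the shrunk log ratio

$$\mathrm{IC} = \log_2 \frac{O + 1/2}{E + 1/2}.$$

The additive $1/2$ is the standard shrinkage of the observed-to-expected
ratio: it pulls small-count pairs towards zero so that a single co-report
cannot generate an extreme statistic. The observed count is modelled as
Poisson with a gamma prior on the rate, giving the posterior
$\Gamma(\text{shape} = O + 1/2,\ \text{rate} = E + 1/2)$ on $2^{\mathrm{IC}}$.

Two 95% credible intervals are provided:

* `gamma_quantile` (default): $\mathrm{IC}_{025}$ and $\mathrm{IC}_{975}$
  are the $\log_2$ of the 2.5% and 97.5% gamma posterior quantiles. This
  is exact under the stated posterior.
* `noren_approx`: the published closed-form asymptotic approximation
  $\mathrm{IC} - 3.3\,(O+0.5)^{-1/2} - 2.0\,(O+0.5)^{-3/2}$ for the lower
  bound (and the analogous upper form). The two variants agree within
  0.15 bits for $O \ge 10$ over the operating range (tested); the
  approximation degrades for very small $O$.

`is_signal` applies the conventional threshold $\mathrm{IC}_{025} > 0$ per
pair. No multiplicity adjustment is made across screened pairs: the
per-pair threshold is the operating convention of this field, and the
type-I behaviour under the null is instead characterised by simulation
(below). Published interval bounds from production systems can differ from
both variants by up to ~0.1 bits since the exact interval routine in use
is generally uncited; agreement should only be expected to one-decimal
display precision. Displayed values are rounded half-up to one decimal
(`round_half_up()`); machine outputs always carry full precision.

```{r}
tab <- contingency_table(O = 99, n_drug = 55605, n_event = 142, N = 103065)
information_component(tab)
```

## Comparator-restricted (comparative) disproportionality

Whole-database disproportionality confounds drug and indication: migraine
patients are prone to Raynaud's phenomenon whatever they take. The
comparative analysis restricts the scope to reports involving either the
class of interest or an active-comparator class used in the same
population (triptans, migraine beta-blockers) and recomputes the IC within
that scope. Reports co-exposed to both classes are assigned to the
interest row (`overlap = "keep"`, default), so the four cells are disjoint
and sum to $N$; `overlap = "exclude"` drops them instead. The two classes
must be disjoint at ingredient level; `comparative_ic()` enforces this.

## Terminologies and queries

The PT→HLT→SOC and ingredient→ATC dictionaries are deliberately minimal:
only the levels the analysis touches are modelled (no LLT/HLGT, no
multi-axiality — each PT sits under exactly one HLT, the single-path
assumption for HLT-level sensitivity queries). Label matching is
case-insensitive after whitespace normalisation and typographic
apostrophes are folded to ASCII, because spontaneous-report sources vary
in both. ATC queries match by code prefix at any level (`N`, `N02`,
`N02CD`, `N02CD01`); a full-length prefix is equivalent to the exact code.
Drug queries carry a role filter defaulting to suspected + interacting:
purely concomitant drugs do not count as exposure.

Dates may be partial (`YYYY-MM`); they resolve to the 15th of the month
and are flagged imputed. Time to onset is the earliest dated matching
reaction minus the earliest start among matching drug entries; negative
values are kept but flagged implausible and excluded from summaries by
default, so the plausibility filtering is visible rather than silent.

## Descriptive layer

Every `summary_table` carries its denominator and the rule that produced
it. This is not cosmetic: in published case-series tables the denominator
legitimately differs by row group (all cases for drug shares, known-age
cases for age bands, known-outcome cases for outcomes, evaluable cases
for withdrawal), multi-valued fields can sum past 100%, and percentages
are irreproducible when the denominator is left implicit. Percentages are
`100 * count / denominator` rounded half-up to one decimal; quartiles use
linear interpolation between order statistics (`stats::quantile` type 7),
fixed so interquartile ranges reproduce exactly in tests.

## The simulator

`synthetic_config()` + `generate_store()` produce report stores with the
structure the IC's expected-count model assumes: each report draws
suspected drugs and reaction PTs independently from configured marginal
reporting frequencies; an injected association multiplies the event's
draw probability by $\rho \ge 0$ (capped below 1) when any associated
drug is present; demographics, dates, doses, seriousness, outcomes and
per-field missingness follow the config.

Two design points deserve note:

* **Marginal calibration.** Every report must list at least one drug and
  one reaction (zero rows are redrawn so `n_reports` is exact). That
  conditioning inflates raw Bernoulli marginals, so the generator solves
  the fixed point $q_i = m_i\,(1 - \prod_j (1 - q_j))$ and draws with
  $q$; the *realised* marginals then equal the configured $m$ (tested to
  3 binomial standard errors at $n = 10{,}000$). This requires the
  configured marginals to sum above 1 — i.e. to describe a population
  averaging more than one drug and one reaction per report, as real
  spontaneous-report databases do. Configurations violating this are
  rejected at validation.
* **Ground truth.** `implied_ic()` returns the large-sample IC implied by
  a configured association in closed form, including the redraw
  conditioning on both the drug and the event side (the renormalisation
  differs slightly between exposed and unexposed reports because a
  boosted event makes an empty reaction draw rarer). Cross-association
  interactions are neglected. Recovery of this implied IC from generated
  data is tested at $n$ up to 200,000.

Randomness flows from one `set.seed(config$seed)` call and a fixed,
fully vectorised draw order, which makes generation deterministic given
the seed without per-report generator state.

Default parameters are the study conditions of the motivating case
series: drug and event marginals sized for a migraine-pharmacovigilance
population; sex ratio 92.5% female; ages normal (mean 46, sd 13) clamped
to 18–75; time to onset log-normal with median 84 days and $\sigma =
2.27$ log-days (matching an IQR of roughly 18–383 days), capped at ten
years to keep onsets inside a plausible reporting window; outcome mix
27.7 / 6.4 / 65.9% among known; seriousness 15.2%; missingness per field
at the rates implied by the published denominators (e.g. 41% of ages, 52%
of outcomes unknown). The single default association links the CGRP class
to Raynaud's phenomenon with $\rho = 26$, whose implied class-level IC is
$\approx 3.3$ bits — the magnitude of the published whole-database
signal — so that signal injection and recovery are exercised at a
realistic effect size.

What the simulator does **not** emulate: co-reporting correlation between
events, duplicate reports, masking by competing signals, and
time-dynamics of reporting rates (Weber effect, notoriety bias). Passing
tests on synthetic data therefore validate the counting and estimation
machinery, not robustness to those real-data phenomena.

## Deterministic fixtures

Two constructed (not sampled) stores reproduce the published study
exactly where its inputs are printed:

* `study_fixture()`: a 99-case Raynaud's series plus 400 background
  reports whose descriptive layer reproduces the published counts and
  percentages (drug shares, sex, age bands and quartiles, seriousness,
  outcomes, withdrawal, co-reported terms, co-suspect drugs, onset and
  dose medians). Where a published table implies multiple values per
  report (reporter qualification sums past 100%), the single-valued
  schema holds one reporter per report and the consumer count absorbs
  the difference; reporter shares are therefore illustrative only.
* `comparative_fixture()`: a count-faithful skeleton store realising the
  printed comparative 2×2 cells (99/55,506 with the CGRP class, 43/47,417
  with triptans, 142/129,222 with beta-blockers), one suspected drug and
  one reaction per report. Whole-database margins are not printed in the
  source study, so the full-database IC is validated property-wise on
  simulated stores instead of numerically.

## Numerical and edge-case conventions

* $O = E$ gives IC exactly 0; $O = 0, E = 0$ gives IC 0 with a wide
  interval (the statistic is defined for every valid table).
* Contingency tables validate $0 \le O \le \min(n_D, n_E)$,
  $n_D, n_E \le N$ before any statistic is computed.
* Screens order by $\mathrm{IC}_{025}$ descending, ties by $O$
  descending then label; zero-count pairs are retained.
* Unknown PTs or ingredients never silently drop reports: they are
  collected in the store's `rejects` and surfaced in logs and the study
  report, since missingness and coding heterogeneity are the dominant
  caveats of this data type.
* `run_study()` recomputes every emitted percentage and IC from the
  emitted counts before the report is declared valid, and leaves a
  `FAILED` marker file when any stage errors.

## Problem sizes used in the test suite

The suite exercises the estimator at the scales where its guarantees are
stated: counting-oracle equivalence on 100–200-report stores against a
brute-force raw-row scan; marginal calibration at $n = 10{,}000$;
injected-signal ranking and ±0.3-bit recovery at $n = 50{,}000$;
convergence of the recovered IC to the implied IC over
$n \in \{2, 20, 200\} \times 10^3$ averaged over three replicate seeds;
and null type-I behaviour over 400 replicates of $n = 2{,}000$, where the
empirical $\mathrm{IC}_{025} > 0$ rate must stay below 7.5% (nominal
2.5% one-sided plus simulation slack).

## Known limitations

The IC's expected-count model assumes independence between drugs and
between non-associated events; real co-prescription and syndromic
co-reporting violate this and can mask or inflate signals. The package
performs no deduplication, no E2B XML ingestion, no causality assessment,
and offers no ROR/PRR/EBGM alternatives. Disproportionality quantifies
reporting, not risk: a positive $\mathrm{IC}_{025}$ is a hypothesis for
pharmacological and clinical assessment, never a measure of incidence.
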