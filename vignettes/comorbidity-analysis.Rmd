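---
title: "Replicated case-control comorbidity analysis and patient stratification"
author: "ComorbidEHR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicated case-control comorbidity analysis and patient stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ComorbidEHR)
```

## The problem

Electronic health records make it possible to ask, phenome-wide, which
diagnoses co-occur with an index disease more often than expected. Doing this
credibly requires three guards that this package wires together:

1. **Replicated matched controls.** Any single matched control group is one
   draw from a large pool; an association that only holds for one draw is
   fragile. We therefore select, for each case, thirty controls by propensity
   score matching and analyse them as thirty replicate 1:1 control groups,
   summarising each condition by the distribution of its odds ratios and
   p-values across replicates.
2. **Conservative aggregation.** Within each replicate, enrichment of each
   condition is scored with the hypergeometric test and
   Bonferroni-corrected by the number of conditions tested in that
   iteration. Across replicates we report the mean odds ratio and an
   aggregated p-value defined as twice the mean corrected p-value, capped at
   1 — a combination rule valid under arbitrary dependence between
   replicates, at the cost of (further) conservatism.
3. **A utilization filter.** Patients with the index disease interact more
   with the healthcare system, so *any* frequently coded condition tends to
   look enriched. A second control arm is matched additionally on the number
   of recorded visits and the record duration; a condition is significant in
   the final analysis only if it is significant against both arms.

On top of the case-control analysis, cases are stratified by Leiden
community detection on a nearest-neighbour graph of their PCA-reduced binary
diagnosis matrix, clusters are characterised by enriched and
cluster-exclusive conditions, and two data sources are compared by
significant-set overlap, log-odds-ratio correlation, and greatest-overlap
cluster matching with Jaccard similarity.

## Data model

Cohorts are built from OMOP-style flat tables (persons, dated condition
occurrences, per-person utilization summaries). Cases are the patients with
at least one occurrence of a concept-set closure: a root condition concept
plus all its descendants under the vocabulary's ancestor edge list
(`closeConceptSet()`). The background population is everyone with at least
one condition of any kind and no concept-set occurrence; patients with no
coded conditions at all carry no information for a diagnosis-based analysis
and are excluded from the pool.

Two analysis modes are supported. In the *full* mode every condition in a
patient's record counts. In the *pre-index* mode each case keeps only
conditions dated strictly before their first concept-set diagnosis (the
index date), while controls keep their full records. Two choices here are
deliberate:

- **Strict inequality.** Conditions coded on the index date itself are
  excluded. Within-day ordering of diagnoses is not recorded, so counting
  same-day codes as "prior" would let diagnostic work-up of the index
  disease leak into its own risk-factor profile; strictness is the
  conservative reading. Cases left with no pre-index condition are dropped.
- **The case-defining concepts are never tested.** Cases have a concept-set
  occurrence by construction, so testing those concepts is circular; they
  are removed from the condition universe in both modes. Closely related
  (but distinct) concepts — e.g. conditions that share diagnostic coding
  pathways with the index disease — remain in the universe; interpreting
  their (often extreme) odds ratios is left to the analyst.

The tested condition universe for an analysis is every concept occurring in
at least one analysed patient (cases or matched controls), with an optional
minimum-prevalence floor (default: none). Within each replicate iteration,
the Bonferroni multiplier is the size of *that iteration's* universe —
concepts present in at least one case or one control of that replicate;
concepts absent from an iteration contribute a corrected p of 1 (not a
missing value) so that aggregation across replicates is always defined.

## Matching

Propensity scores come from a main-effects logistic regression of case
status on age, gender, race, ethnicity (and site, when more than one is
present); the utilization variant adds the visit count and record duration,
both entered linearly. Categorical covariates are one-hot expanded with a
dropped reference; constant covariates are dropped (they carry no
information and break the design matrix). If the fit separates or fails to
converge, a ridge-stabilised fit (small L2 penalty) is substituted with a
warning. Gender is a matching covariate, not an eligibility filter: real
cohorts retain a small number of male/unknown records for an
overwhelmingly female condition, and excluding them is a reporting
decision, not a statistical one.

Matching is greedy nearest-neighbour without replacement on the raw
propensity score: cases are processed in descending score order (the
hardest-to-match, highest-score cases pick first, a standard greedy
heuristic that avoids poor late matches), and each case takes its 30
nearest unused controls by absolute score difference, with distance ties
broken by the smaller control id so the procedure is fully deterministic.
Replicate group *g* collects every case's *g*-th nearest control, so the 30
groups partition the matched controls, the whole match is
without-replacement, and each group is itself a valid 1:1 matched sample
whose quality degrades gracefully with *g*. No caliper is applied by
default (one can be supplied). An alternative reading of "thirty control
groups" — thirty independent 1:1 matches — would reuse controls across
groups and make the replicates less informative about control-sampling
variability; the single 1:30 match is the implemented interpretation.

Balance is reported as standardized mean differences per expanded
covariate, before (cases vs the whole pool) and after (cases vs matched
controls) matching; zero-variance covariates are flagged and reported as 0.

## Statistics

For a 2x2 table with `a` cases and `c` controls carrying the condition, the
odds ratio is `(a d)/(b c)`; if any cell is zero the Haldane–Anscombe
correction adds 0.5 to all four cells so replicate means stay finite. The
enrichment p-value is the hypergeometric upper tail `P[X >= a]` with
population `a+b+c+d`, `a+c` successes and `a+b` draws; no continuity
correction is needed there. Protective (depleting) associations are
reported from the analogous lower tail in a separate column, with the same
per-iteration Bonferroni and aggregation applied within that tail —
depletion is a real phenomenon (comparing against controls matched to have
comparable healthcare contact makes "protective" codes interpretable), but
enrichment and depletion are distinct hypotheses and are never mixed in one
two-sided p.

The default significance level is 0.05 on the aggregated p, in each arm;
`significant_final` requires both arms.

## Clustering

Only cases are clustered. The binary case-by-condition matrix is centred
and reduced by PCA to at most 1,000 components (capped at
`min(rows, cols) - 1`; with condition vocabularies below 1,000 the cap
binds and the embedding is lossless — the retained variance fraction is
reported either way). Component signs are fixed by making each component's
largest-magnitude loading positive, so results do not flip across BLAS
builds. A k-nearest-neighbour graph (default k = 15, a conventional
neighbourhood size for cohorts of hundreds to tens of thousands; logged in
the result) is symmetrised by union and weighted with a locally scaled
Gaussian kernel, `exp(-d^2/(sigma_i sigma_j))` with `sigma_i` the distance
to the k-th neighbour — local scaling keeps dense and sparse regions
comparably connected. Leiden community detection under the modularity
objective (the flavour used by the standard scanpy/leidenalg stack) runs at
resolution 1.0 by default; a sweep helper reports pairwise adjusted Rand
indices across a resolution grid (e.g. 0.5–1.0) to check that subgroupings
are not a resolution artefact.

Cluster characterisation reuses the identical enrichment core — the same
odds-ratio, hypergeometric and Bonferroni code paths — with the "cases"
being the cluster under consideration and the "controls" all other
clusters. This contrast has no control-sampling step, so there is nothing
to replicate thirty times: a single corrected test per condition per
cluster is the appropriate specialisation. A condition is *exclusive* to a
cluster when it is enriched (corrected p < alpha, OR > 1) there and nowhere
else; exclusive sets are therefore pairwise disjoint by construction.
UMAP provides 2-D coordinates for reporting only; clustering never sees
them.

## Comparing data sources

Association tables from two sources are compared on the intersection of
their final significant sets: Pearson correlation of natural-log mean odds
ratios (the base cancels in r), reported only when at least 3 conditions
are shared, with zero-variance degeneracies returned as structured
"undefined" results. Cluster structures are compared directionally: each
discovery-side cluster is matched to the replication-side cluster sharing
the most enriched conditions (ties: larger Jaccard, then smaller id — an
arbitrary but deterministic rule), unmatched clusters are reported, and
matched pairs are scored by Jaccard similarity of their enriched sets. A
`mutual` flag identifies reciprocal-best pairs. The bipartite structure is
exported as GraphML (nodes: cluster, side, size, exclusively enriched
count; edges: coverage fraction and Jaccard) rather than as a rendered
figure. Membership changes between two labelings of the same patients
(e.g. pre-index vs full-record) are reported as a long-format crosstab
whose marginals equal the per-cluster sizes — a structural identity checked
on every call.

## The synthetic cohort generator

Real multi-site EHR data of this kind are access-restricted, so the
package ships a generator that emulates the *structure* the analysis
assumes, with known ground truth:

- demographics drawn independently of case status from configurable
  margins (defaults resemble a largely female, demographically mixed
  tertiary-care population: 97% female; age ~ N(38, 12) truncated to
  18–90);
- over-dispersed utilization: visits ~ negative binomial (mean 20,
  size 2 — coded-visit counts are strongly over-dispersed, and no
  particular dispersion is canonical, so a moderate value is fixed as the
  default), with the case mean scaled by a configurable shift (default
  1.5);
- condition occurrence from a per-person logistic model:
  baseline intercept (default U(-5, -2.5), i.e. background prevalences of
  roughly 0.7–8%, the sparse regime of coded diagnoses), a per-condition
  planted case effect (log odds ratio), a utilization effect on
  `log(1 + visits)` (multiplicative coding-intensity bias, kept bounded by
  the log), and an additive subgroup signature boost;
- latent subgroups over cases only (the analysis clusters cases only):
  by default 4 subgroups with 8 disjoint signature conditions each and a
  +5 logit boost, giving within-subgroup signature prevalence around
  0.6–0.75 against a few percent outside;
- dated records: each person has a record span (1–10 years) and each
  present condition an independent uniform date in it; each case gets a
  concept-set occurrence at the 0.6 quantile of their span (so pre-index
  analyses retain most of the history), which is also the planted index
  date. The emitted ground truth includes the *realized marginal log odds
  ratio* per condition — the case-vs-background contrast implied by the
  drawn visit counts and subgroup memberships — which is the estimand a
  demographically matched contrast targets, and differs from the planted
  conditional effect whenever utilization or subgroup pathways are active.
- Background size defaults to 31x the case count so a full 1:30 match
  remains feasible after background persons with no coded conditions drop
  out of the eligible pool. That minimum is enough when matching only needs
  to mirror the case demographics, but a 1:30 match from a 31x pool uses
  nearly every eligible control, so it cannot be *selective*: studies that
  exercise the utilization-matched arm use a 100x pool (real EHR
  case:background ratios are in the hundreds), which restores the headroom
  the matcher needs to find visit-comparable controls.

What the generator does *not* emulate — and what green tests therefore do
not establish about real data: correlated comorbidity structure beyond the
planted subgroups (real diagnoses co-occur in rich dependency networks),
demographic-condition confounding (conditions here are independent of age,
gender, race and ethnicity, so demographic matching is exercised as
machinery, not stress-tested), coding-system drift across sites and time,
informative missingness, and visit-level temporal dynamics. Conclusions
about the *statistical procedure* (calibration, power, filter behaviour,
recovery of planted structure) transfer; conclusions about clinical
findings do not.

## Validation design and problem sizes

The test suite validates each stage against independent oracles:
concept-set closure against breadth-first reachability; hypergeometric
p-values against exhaustive enumeration over all 2x2 tables with total
up to 30; matching against brute-force optimal assignment on small
instances (greedy is required to be within 1.5x of optimal total
distance); and the full pipeline against the generator's ground truth.
The statistical acceptance checks run at the scale where their targets are
meaningful while staying desk-sized: 50 null cohorts of 500 cases for
family-wise error; 20 cohorts of 2,000 cases for effect recovery (planted
OR = 4; the mean replicate odds ratio is required to land in [3.0, 5.0]
with primary-arm power at least 0.95) and for the confound filter
(utilization-only conditions must be flagged by the naive contrast in at
least half the runs and survive the final filter in at most 10%; these
cohorts use the 100x background pool discussed above); 10
cohorts of 2,000 cases for subgroup recovery (ARI at least 0.8, signature
conditions recovered as cluster-exclusive, resolution-sweep stability at
least 0.7); and a two-site run of 2,000 cases per site for concordance.
Where a check is evaluated across seeds, per-seed statistics are
averaged rather than requiring every seed to clear the bar individually;
the thresholds themselves are stated above.

Numerical and degenerate-input policies, gathered in one place: dates are
ISO-8601 calendar dates and index-date ties across concepts resolve by
date alone; all identifiers are opaque strings; score-distance and
cluster-matching ties resolve by smaller id; zero cells in odds ratios use
the Haldane–Anscombe correction; aggregated p-values cap at 1; empty
condition universes, all-zero matrices, empty graphs, cyclic concept
hierarchies and insufficient control pools are errors with diagnostics;
an empty case selection, probability saturation in the generator, and
propensity separation produce warnings (the latter with a ridge
fallback); zero-variance covariates and correlations yield flagged zeros
or structured "undefined" results rather than NaNs.

## Known limitations

The twice-the-mean aggregation is conservative and, combined with
per-iteration Bonferroni, makes the familywise error rate far below
nominal in the null simulations; that is the intended trade-off, not a
bug. Greedy matching is not optimal matching; the 1.5x-of-optimal bound
is checked only at small scale. The in-cluster-vs-rest enrichment treats
clusters as fixed after Leiden, ignoring selection effects (enrichment
p-values within discovered clusters are descriptive, not inferential).
Cross-site comparison assumes a shared condition vocabulary; no concept
mapping is attempted.
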