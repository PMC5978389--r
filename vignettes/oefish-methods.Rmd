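---
title: "Methods: an observed/expected fish index from boosted regression trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an observed/expected fish index from boosted regression trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Snapshot physicochemical monitoring of rivers misses what biota integrate:
species persist or vacate in response to the whole regime of conditions they
experience. An observed/expected (O/E) index compares the species assemblage
predicted at a river reach under *current* conditions with the assemblage
predicted under a defined *reference* condition — a near-natural covariate
state, not necessarily pristine. A ratio near 1 means the present-day
assemblage resembles what the environment could support without
anthropogenic pressure; low ratios flag reaches where species have been
lost, and are candidates for restoration.

`oefish` implements this index end to end for presence/absence fish survey
data: survey filtering, per-species boosted regression tree (BRT) occurrence
models, Cohen's-Kappa-optimal presence thresholds, a counterfactual
reference-condition covariate transform, per-reach O/E, attribution of O/E
to pressures, and an NMDS ordination of species by their influential
environmental variables. Because national survey databases cannot be
bundled, the package ships a synthetic river-network generator with known
ground truth, so every stage is testable without any download.

## The modelling procedure

### Survey filtering

Records are retained when sampled in or after 2000, during the austral
summer window (December–March inclusive), by electric fishing, over at
least 150 m of reach; every boundary is read inclusively. Where a site has
several retained records exactly one is kept, drawn uniformly with a seed
derived from the global seed and the site identifier — so the choice is
reproducible and invariant to input row order. One documented ambiguity:
a summer window of December–March and an exclusion window of May–October
disagree about April and November; the package retains only months
{12, 1, 2, 3} and does not silently switch.

Species enter the models only if present at ≥ 150 distinct sites, counted
*after* deduplication and the record filters (the self-consistent choice,
since the analysis set is what the models see). River classes enter only
with ≥ 1,000 survey sites, and **all** downstream prediction is restricted
to retained classes to limit extrapolation. A pairwise Pearson collinearity
screen (r and two-sided p per covariate pair) is reported but removes
nothing — no removal rule is part of the procedure.

### Occurrence models

Each species is modelled independently by stagewise gradient boosting on
Bernoulli deviance: interaction depth ("tree complexity") 5, per-tree row
subsampling ("bag fraction") 0.15, 10-fold cross-validation, and an
ensemble size chosen by cross-validated deviance. The learning rate starts
at 0.01 and is halved — at most six times — until the CV-optimal tree count
reaches 1,000; a species that still cannot support 1,000 trees raises a
convergence error naming the final rate. Folds are stratified by outcome
and seeded. The backend is xgboost; relative influence is each covariate's
share of total split gain, normalised to 100%, computed from the tree dump.

Reported AUC is the Mann–Whitney probability that a random presence
outscores a random absence (ties half), computed on *pooled* out-of-fold
predictions; the fold-averaged AUC is reported alongside since either
convention is defensible.

### Presence thresholds

Because prevalence is rarely 50%, a fixed 0.5 threshold misrepresents most
species. For each species, Cohen's Kappa of presence calls against observed
presence is evaluated at every threshold on the inclusive grid
{0, 0.005, …, 1} (201 values), and the maximising threshold is kept. Calls
use `probability >= threshold` (inclusive), the same convention inside the
search and in prediction. Ties are broken toward the smallest threshold
(favours sensitivity; deterministic). Thresholds are selected on in-sample
predictions of the fitted ensemble, the convention of standard O/E
practice; an out-of-fold mode exists (`select_threshold_for(...,
out_of_fold = TRUE)`) but is off by default. Degenerate tables where
expected agreement is 1 return Kappa 0 by convention.

### Reference condition and O/E

The reference condition is *configuration*, not constants, with defaults:
upstream native cover set to 1, upstream pasture to 0, riparian native
percent to 100, riparian shade replaced by the estimated pre-human shade
companion column, and nitrate-N and DRP *capped where exceeded* at
0.11 and 0.006 mg/L — the upper range of nutrient enrichment consistent
with high ecological health. `cap_at` never raises a value; `set_to`
overwrites regardless (so riparian percentages slightly above 100, which
occur in real covariate layers, need no special case). The transform is
idempotent and never mutates its input.

Per reach, E is the set of native species called present under the
reference scenario; O is the set called present under current conditions
**and** expected under reference. Restricting O to expected species is what
guarantees 0 ≤ O/E ≤ 1; species present today but not expected are
diagnostic information, not credit. "Observed" is model-predicted
present-day presence, not raw field detections — the index compares two
model states on an equal footing. Reaches with E = 0 get a reason-coded
undefined ratio (not 0, not 1) and never enter attribution. Exotic species
never enter E or O.

### Attribution and ordination

The per-reach O/E is then modelled from pressure covariates (downstream
dams, nutrients, predicted exotic presence, and any further pressure
columns supplied) with the same boosted-tree procedure on squared-error
loss — O/E is continuous, so Bernoulli deviance is not applicable. The
"cross-validated correlation" is Pearson r between pooled out-of-fold
predictions and O/E. A noise-dominated target may never support 1,000
boosting rounds; the attribution fit therefore accepts the CV-optimal
ensemble with a warning instead of failing, the one place the minimum-tree
rule is relaxed.

For the ordination, each species is represented by its five largest
relative influences (others zeroed), species-to-species Euclidean distances
are embedded in two dimensions by non-metric MDS minimising Kruskal
stress-1 (vegan's engine), best of 20 seeded random starts. Coordinates are
identifiable only up to rotation/reflection/translation; comparisons should
be at the stress or distance level.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not any particular geography:

* a lowland–upland gradient drives temperature, slope and distance to
  coast, and a development gradient rides on it: pasture and native cover
  are strongly negatively correlated, nutrient concentrations rise with
  pasture (lognormal noise), dams are more frequent in developed reaches;
* riparian shade is a fraction of its pre-human companion value, reaching
  it only under full native riparian cover;
* each species' occurrence probability is a logistic function with a
  quadratic temperature optimum, one or two additional natural-covariate
  terms, one pairwise interaction, and signed anthropogenic /
  native-cover terms — natives are suppressed by pressure, exotics favour
  it. Coefficient scales are chosen so the steepest species exceed a
  generating (Bayes) AUC of 0.95 at survey scale: that is the regime in
  which an occurrence model can meaningfully be asked to reach high
  cross-validated AUC;
* every coefficient on a covariate the reference transform can touch is
  multiplied by `impact_strength`, so `impact_strength = 0` is a
  calibrated world in which reference and current probabilities coincide
  and true O/E is exactly 1 wherever E > 0;
* detection is one multiplicative probability per record — survey-level
  nuisance (operator skill, conductivity) is not modelled because such
  covariates are unavailable in real survey databases anyway;
* a configurable fraction of records violates each ingest filter so the
  filtering stage has real work;
* reaches are exchangeable rows: no network topology, flow routing, or
  migration dynamics. Consequently passing recovery tests says the
  *procedure* recovers known structure from tabular covariates; it says
  nothing about spatial autocorrelation, detection heterogeneity, or
  diadromy in real data.

The fixed demonstration world (`oe_demo(seed = 42)`) uses 2,000 reaches,
1,500 survey sites, 8 native and 2 exotic species, `impact_strength = 1`,
detection 1, a 5% violation fraction per filter rule, and two river classes
(0.7/0.3). At this scale the class rule is desk-scaled to 300 sites per
class — the package default of 1,000 reflects national survey volumes and
would empty a 1,500-site simulation; all other defaults are the standard
regime. These sizes keep a full demonstration run in single-digit minutes
on one CPU while leaving every stage non-trivial.

## Numerical choices and degenerate inputs

* Seeds: one global seed is fanned out to per-stage and per-site seeds by a
  stable polynomial string hash (exact in doubles, below 2^31), so stages
  are independently reproducible and row order never matters.
* Kappa grid: both endpoints included; `t = 0` calls everything present,
  `t = 1` only certainties.
* Single-class outcomes are unfittable (error, audited), as is an AUC or a
  threshold on one-class labels.
* Zero-variance covariates in the collinearity screen are flagged, not
  errored; constant pressure columns get zero influence.
* An ensemble with no splits at all would have undefined influence; it is
  reported as uniform with a warning (never observed under the default
  regime).
* Unparseable dates drop the record with its own audited reason code
  rather than aborting a run.

## Known limitations

* The reference state covers land use, riparian condition and nutrients;
  geomorphological change is not represented — a limitation shared with
  the real-data setting, where no reference geomorphology layer exists.
* O/E on presence/absence is insensitive to abundance change; impacts that
  thin populations without extirpating them are invisible.
* The index inherits the occurrence models' blind spots: where the
  training gradient confounds natural and anthropogenic variation (e.g.
  lowland reaches are almost all developed), the counterfactual leans on
  extrapolation.
* The attribution model describes association between pressures and O/E,
  not causation.
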