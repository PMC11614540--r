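---
title: "Methods: phylogenetically corrected cross-cultural locomotor traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetically corrected cross-cultural locomotor traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locomotr)
```

## The problem

Cross-cultural claims of the form "X% of hunter-gatherer societies swim"
face two obstacles. First, the evidence is ethnographic text: scattered
passages ("quotes"), each describing one behaviour in one society, coded by
hand into controlled vocabularies. Second, societies are not independent
observations — closely related societies share traits by descent and
diffusion (Galton's problem), and comparative samples are usually heavily
biased towards one world region, so a naive proportion over societies
over-counts whatever that region happens to do.

`locomotr` implements the full path from coded quotes to corrected
proportions for four locomotor modalities — running (terrestrial), climbing
(arboreal), swimming and diving (aquatic) — together with proficiency
levels, functional domains (subsistence, leisure, ritual, conflict, ...),
three special subsistence activities (persistence hunting, honey climbing,
underwater hunting), and gender engagement codes.

## From quotes to society codes

Each quote carries: a modality; proficiency evidence (`none`, `basic`,
`higher`, with `basic` the default when engagement is documented without
meeting the predefined higher-proficiency criteria); a set of functional
domains; optionally a special activity and gender evidence; and an
exclusion flag for passages from myths/legends, non-traditional lifeways,
or ambiguous wording (e.g. "bathing" for swimming). Quotes with no
engagement evidence carry no further variables.

Aggregation to one record per society and modality is deterministic:

* **presence** — `present` iff at least one non-excluded quote documents
  basic or higher engagement;
* **proficiency** — the maximum over quotes (`higher` beats `basic`);
* **functional domains / special activities** — unions over quotes;
* **gender** — via `resolve_gender()`: a lone exclusivity code stands; an
  exclusivity contradicted by documented engagement of the other gender
  (a bias statement or an explicit both-genders code implies both engage)
  degrades to the corresponding bias; evidence pointing in both directions
  resolves to egalitarian engagement with a logged warning. Quotes about
  children's play contribute no gender evidence.

These rules are the weakest ones consistent with the coding behaviour the
source material describes (for instance, a female-exclusive aquatic code
must survive anecdotes that merely *mention* men in the water, but not
documented male engagement). They make aggregation order-invariant,
monotone under added evidence, and idempotent — properties the test suite
checks directly, including an exhaustive comparison of the gender rules
against an independent truth-functional interpreter over all evidence
multisets of size up to three.

Two domains are structurally restricted: `observation` applies only to
climbing, and `travel` only to running and swimming (and, at quote level,
travel is coded only when no other domain applies). Masked table cells are
reported as not-applicable, never zero.

### Sample eligibility

A society enters the analysis sample when its cumulative dependence on
gathering, hunting and fishing strictly exceeds 56% and at least two
non-excluded locomotion-relevant quotes exist for it. Excluded quotes do
not count towards the threshold: a passage about a mythical swimmer is not
locomotor information. Both thresholds are parameters of
`eligible_societies()` and `run_pipeline()`.

## Phylogenetic correction

The correction targets the sample's phylogenetic clustering. On a rooted
time-calibrated society tree, the patristic distance between two societies
is the sum of branch lengths on the path connecting them. We use patristic
path distance rather than twice the age of the common ancestor: the two
coincide on an ultrametric tree, and path distance stays well-defined if
the supertree is not perfectly ultrametric (a >1% spread in root-to-tip
depths triggers a diagnostic warning, nothing more).

A society's *isolation* in a sample S is its mean distance to every other
society in S; resampling weights are isolations normalized to sum to one:

$$m_i = \frac{1}{|S|-1}\sum_{j \in S,\, j \neq i} d_{ij}, \qquad
  w_i = \frac{m_i}{\sum_{k \in S} m_k}.$$

The corrected proportion of a binary trait is estimated by drawing
societies i.i.d. with replacement, `n_resamples` times (default
1,000,000), with probabilities $w_i$, and taking the fraction of draws
carrying the trait. Its expectation is available in closed form,
$\sum_i w_i x_i$ (`analytic_weighted_value()`), which pins the estimator's
semantics and serves as the oracle in every test; the Monte-Carlo standard
error uses the plug-in binomial formula. We draw single societies rather
than whole-sample bootstrap replicates because only point proportions are
reported and the expectation is identical. Categorical distributions
(e.g. the versatility histogram) are resampled as one draw vector, so
category shares partition exactly.

Two properties make the weighting interpretable. On a star tree with equal
pendant edges all weights are uniform and the correction is a no-op. When
a sample over-represents one shallow clade, its members sit close together,
have low isolation, and are down-weighted — so a trait confined outside the
clade is corrected upward, and conversely.

Weights are **re-derived for every denominator**: the corrected share of
higher-proficiency climbers uses weights computed among climbing societies
only, and special-activity shares use weights among the societies with
subsistence functionality in that modality. Renormalizing full-sample
weights is not equivalent (restricting a three-society sample with weights
3/11, 3/11, 5/11 to two societies gives 1/2, 1/2, not 3/8, 5/8), and the
test suite asserts the distinction.

Which statistics are corrected follows the reporting conventions of this
literature: modality presence, the versatility histogram, modality-overlap
(Venn) masses, higher-proficiency shares and special-activity shares are
corrected; ecological breakdowns, functional-domain proportions, gender
proportions and the coastal/inland split are raw. The `estimates.tsv`
output lists raw and corrected values side by side.

### Determinism

Every random choice flows from one integer seed. Stage- and
statistic-level seeds are derived from it with a label hash, so individual
statistics are independently reproducible and reruns are byte-identical;
package functions save and restore the caller's RNG state. The default
seed, 20242553, is an arbitrary constant recorded in all outputs.

## Ecology

Societies carry a WWF Major Habitat Type name, mean annual temperature
(deg C, may well be negative) and distance to coast (km). Habitat types are
simplified to six biomes (boreal forest/taiga, temperate forest, tropical
forest, desert, grassland, tundra) through an editable mapping file
(`inst/extdata/biome_map.tsv`) covering the 14 canonical terrestrial
habitat-type names; archives with variant spellings or extra categories
can supply their own file. The coastal split uses a strict inequality:
"inland" means strictly more than 50 km (a parameter) from the coast.

## The synthetic-data generator

The generator exists so every stage of the pipeline — including failure
modes — can be exercised without any external data, and so the correction
can be validated against known ground truth. Its defaults are the study
conditions, fixed once:

* **53 societies**, the size of the hunter-gatherer comparative sample the
  pipeline targets;
* a **time tree with half the tips inside one shallow clade**
  (`clustered_clade_fraction = 0.5`, clade depth 10% of tree depth),
  emulating the strong over-representation of one world region in
  cross-cultural samples; built by joining two coalescent subtrees under a
  common root so the result is exactly ultrametric with a controlled
  isolation contrast;
* **biome frequencies and biome-conditional temperatures** spanning tundra
  (-11 ± 4 deg C) to tropical forest (25 ± 2 deg C), with coast distances
  exponential (mean 120 km) and dependence percentages summing to 60–95%;
* a **trait model** in which running is universal, climbing and swimming
  are common (base probability 0.88) but shut off below -10 and -3 deg C
  respectively, and diving (base 0.5) requires at least 5 deg C and forces
  swimming presence — the qualitative ecological constraints the real
  data display;
* a **documentation model**: each true society-modality trait is
  documented with probability `p_document` as 1 + Poisson(1) quotes that
  jointly carry the truth (the first quote carries the gender evidence and
  never the child-play domain); myth-flagged excluded quotes are added at
  rate 0.05, and quotes documenting nothing at rate 0.05;
* a **gender model** with modality-specific code frequencies (a male bias
  concentrated in climbing) and a `female_dropout` dial that deletes
  evidence revealing female engagement, the direction of documentation
  bias this literature worries about.

The faithful-observer defaults (`p_document = 1`, `female_dropout = 0`)
make aggregation an exact inverse of generation: the aggregated codes are
*identical* to the ground truth. This identity is the pipeline's central
parameter-recovery test. `degrade_quotes()` then drops each
society-modality cell's quotes all-or-none with probability 1 − p to trace
how presence counts decay under under-documentation.

What the generator does *not* emulate: correlated documentation effort
across modalities within a society, ethnographer-specific vocabularies,
quote-level coding mistakes, or any attempt to mimic the real sample's
covariate values. Passing tests therefore demonstrate that the pipeline's
arithmetic and precedence rules are right and that the correction moves
proportions in the right direction by the right amount — not that any
particular empirical dataset is unbiased.

## Numerical and design choices

* Proportions are kept at full double precision internally; outputs are
  not rounded.
* `sample.int(..., prob = w)` performs the weighted draws; with the
  default 1,000,000 draws the Monte-Carlo standard error of a proportion
  is at most 0.0005.
* Ties and degenerate inputs: a subsample of two societies always gets
  weights (1/2, 1/2); weights are undefined (an error) for fewer than two
  societies or an all-zero distance matrix; a trait constant across
  societies is corrected to itself exactly.
* Missing societies on the tree are a hard error naming them — silently
  dropping a society would quietly change the estimand.
* Tests and examples run the resampler at 10^3–10^5 draws, and the
  generator at 12–500 societies; these sizes keep the suite quick while
  leaving every statistical tolerance at 4 Monte-Carlo standard errors.

## Limitations

The correction addresses phylogenetic non-independence only; spatial
diffusion between unrelated neighbours is untouched. Isolation weighting
re-weights the observed sample — it cannot recover traits of societies
that were never sampled, and with documentation gaps the corrected
proportion inherits the raw data's lower-bound character. Gender codes are
especially sensitive to reporting bias; the generator's dropout dial
quantifies the direction of that distortion but not its real magnitude.
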