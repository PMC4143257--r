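---
title: "Measuring egocentric social networks from roster surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring egocentric social networks from roster surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(egoroster)
```

## The measurement problem

Egocentric (personal) network instruments embedded in health surveys ask a
respondent — the *ego* — to nominate up to a fixed number of close social
relations (*alters*), in order of closeness, and then characterise each
nominated *tie* with follow-up items: the alter's sex, relationship to the
ego, residence, tobacco use, perceived bodyweight relative to the ego, and a
14-day recall of shared activities (communication, snacks, meals, exercise,
walking and small tasks, meal preparation or shopping, tobacco co-use).
Three further items ask the ego to choose one alter as the emergency
contact, the primary contact for a health problem, and the contact when
feeling overwhelmed.

`egoroster` implements the complete measurement pipeline for such data: a
validated relational data model (ego table, tie table, network-level
nomination table), the standard per-ego network measures, sample-level
summary tables with between-group tests, and a seeded synthetic-data
generator so the pipeline can be exercised and tested end to end when the
underlying microdata are restricted, as is typical for health surveys.

The package's reference point is an instrument fielded among 208 adults in
New Delhi, India, with a nomination cap of 5; the published marginal tables
from that sample (network-size frequencies, per-position tie-type
composition, dyadic-feature counts) ship as `delhi_reference()` and anchor
the generator's defaults and the package's worked examples.

## Measures

For an ego with ties $a_1, \dots, a_k$ (so *network size* $k \le 5$):

* **Network exposure** to a binary alter attribute $X$ is
  $\frac{\#\{i : X(a_i) = 1\}}{\#\{i : X(a_i)\ \text{known}\}}$ — the
  proportion of network members exhibiting the attribute among those with a
  known value. Unknown values leave both numerator and denominator; the
  measure is *undefined* (`NA`), never imputed, when no value is known.
  One published usage convention deserves note: although exposure is
  sometimes defined only for egos who lack the attribute themselves, sample
  means are in practice computed over all egos; `network_exposure()` is
  therefore unconditional, and callers who want the restricted version can
  filter egos first.
* **Network homogeneity** is the proportion of alters sharing the ego's own
  value of an attribute. Three attributes have instrument-defined
  semantics: same sex; same city (residence coded `same household` or
  `same city` rather than `other`); and bodyweight, where the item is
  already self-referent so a match is simply `similar`.
* **Tie diversity** is summarised two ways: the share of ties that are
  relatives (`pct_family`), and the number of distinct tie types present
  (`n_tie_types`). Tie types follow the kin-vs-non-kin framing of
  diversity: all kin codes pool into a single *kin* type while each non-kin
  code (friend, workmate, neighbor, other) counts separately, so a roster
  of husband, son, friend, neighbor spans 3 types. (An alternative would
  count the four-way relative classes; the kin-pooled space matches how
  diversity contrasts kin against friendship and other non-kin ties.)
* **Tie strength** combines three operationalizations: closeness rank (the
  nomination position, 1 = closest), intimacy (being chosen for any of the
  three network-level items), and 14-day contact frequency (shared snack
  and meal days plus the binary activity indicators).
* **Tie multiplexity** counts the distinct activity domains a dyad spanned
  in the recall window — eight by default (communication; snacks > 0 days;
  meals > 0 days; exercise; walking or small tasks; meal preparation or
  shopping; tobacco co-use; health talk above the scale's lowest level).
  Unknown responses count as not engaged, so multiplexity is a lower bound
  under item nonresponse.

```{r measures-example}
ds <- generate_dataset(generator_config(n_egos = 100, seed = 7))
head(all_ego_measures(ds), 3)
```

## Classification policy

Relationship codes carry a three-way class (male relative, female relative,
non-relative) plus a catch-all `other`. For the relative/non-relative
dichotomy used by `pct_family` and the dyadic tables, the default policy
pools `other` with relatives: in the reference sample the published split of
637 relative against 143 non-relative ties (out of 780) is arithmetically
consistent with the composition table only when `other` ties (1.9% of ties)
count as relatives. The policy is a codebook field
(`default_codebook(other_is_relative = )`), so adaptations can invert it.

Two further conventions are configurable because published practice varies:

* the "primary contact for a health concern" defaults to the
  health-problem nomination rather than the emergency item
  (`health_contact_item` argument);
* the most frequent snack partner is the tie with the highest shared-snack
  day count, ties broken by closeness rank (lower position wins) — a
  deterministic, closeness-respecting rule for a tie-break the instrument
  itself does not specify.

## Sample-level tables and denominators

`summarize_measures()` follows the denominator conventions of published
sample-description tables: mean network size is computed over **all** egos,
including those who nominated nobody (in the reference sample, the
printed 3.8 overall / 3.9 women / 3.6 men reproduce only with denominators
208/105/103), while the composition measures — undefined on an empty
roster — average over egos with at least one alter. Because whether a table
averages only egos with defined values or scores undefined egos zero is
usually unstated, both modes are provided (`undefined = "drop"`, the
default, or `"zero"`), and every output row carries its denominator
explicitly.

Group comparisons use the classical tests for this table style: one-way
ANOVA for continuous measures and Pearson chi-square (no continuity
correction) for categorical distributions, with p-values formatted to two
decimals and floored at `<0.01`. Percentages are rounded half-up at
presentation time only (`round_half_up()`); raw values are always retained.

```{r expansion}
ref <- delhi_reference()$size_frequencies
freq <- rbind(data.frame(size = ref$size, n = ref$women, sex = "female"),
              data.frame(size = ref$size, n = ref$men, sex = "male"))
summarize_measures(expand_size_frequencies(freq), group_by = "sex")
```

## The synthetic generator

`generator_config()` fixes the study conditions the generator emulates.
Everything the published tables constrain is taken from them, once:

| parameter | default | source |
|---|---|---|
| `n_egos` | 208 | reference sample size |
| `p_female` | 105/208 | reference sex split |
| `size_pmf` | ∝ (7, 8, 12, 56, 45, 80) | size-frequency column |
| `tie_type_pmf_by_position` | ∝ per-position composition | composition table |
| `p_exercise_given_relative` / `..._nonrelative` | 0.08 / 0.17 | dyadic table |
| `p_alter_tobacco_by_sex` | 0.39 men / 0.03 women | sample's own tobacco prevalence |
| `p_same_city` | 0.9 | homogeneity summary |

Laws the tables do not constrain are explicit config fields, chosen once to
be realistic for an urban Indian roster survey and never tuned afterwards:
day counts are binomial over the 14-day window with per-domain rates
(relatives share meals and snacks more often than non-relatives); the
health-talk scale is a 4-level ordered placeholder (the instrument's exact
scale is not published); the three network-level nominations are drawn with
weights proportional to $2^{-\text{position}}$, times a kin-preference
factor of 2.5 calibrated so that about 91% of health contacts are
relatives, as published; each item is left unanswered with probability
0.015, matching the reference table's 198-of-201 health-contact
denominator. The two snack-day rates (0.25 relative, 0.18 non-relative)
were likewise calibrated once against the published 91% share of relatives
among most-frequent snack partners. Spouse codes are drawn consistently
with ego sex, and sexed kin codes imply alter sex; friend, workmate,
neighbor and other draw sex as a fair coin.

Reproducibility: the master seed yields one pseudo-random substream per ego
(per-ego seeds drawn under the master seed), so a dataset is byte-identical
across runs and could be generated in parallel without changing results.

What the generator does **not** emulate — so what passing tests do and do
not show about real data: within-household correlation of the two
respondents sampled per household; any joint law between alter tobacco use
and relationship type beyond alter sex; interviewer and social-desirability
effects; item nonresponse outside the three network-level nominations.
Parameter recovery on generated data demonstrates that the measurement
pipeline is correct and internally consistent, not that the generator's
unconstrained laws match Delhi.

`recover_parameters()` closes the loop: it re-estimates the recoverable
configuration subset (size pmf, sex split, tie-type shares, conditional
exercise probabilities, tobacco prevalence by alter sex) from a generated
dataset using only the package's measurement functions. At 20,000 egos the
estimates sit within three Monte-Carlo standard errors of the configured
values, and the error shrinks as the sample grows (checked at 500 / 5,000 /
50,000 egos); those sizes keep the whole check to a couple of minutes on
one CPU while leaving the binomial standard errors small enough to be
informative.

## Numerical and degenerate-input choices

* Proportions are undefined (`NA`) exactly when their denominator is zero:
  empty rosters, all-unknown attributes, no snack sharing, no nomination.
  Undefined is a value, never an error, and is excluded — not zero-filled —
  from sample means by default.
* Positions must be contiguous from 1; a filled roster slot after an empty
  one (wide layout) and duplicate or gapped positions (long layout) are
  hard errors at read time, naming the ego. Unknown codes are reported by
  the validator but the rows are kept, so the report is complete rather
  than truncated at the first problem.
* Sample SD uses the $n-1$ convention; at one printed decimal this agrees
  with the population SD for the reference table.
* The chi-square helper refuses tables with a zero margin rather than
  returning `NaN`; the sample-summary wrapper treats an untestable row as
  `NA` rather than failing the whole table.

## Known limitations

* Sociometric statistics (centrality, density, components) are out of
  scope: roster data name alters but do not link them to each other.
* Published exposure/homogeneity sample means cannot be recomputed from the
  published marginals alone (they need respondent-level microdata), so the
  package's checks of those measures are property-based rather than
  value-based.
* The wide layout requires the codebook's nomination cap to bound the
  number of per-alter column blocks; instruments with unbounded rosters
  need the long layout.
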