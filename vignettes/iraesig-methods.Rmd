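---
title: "Detecting and filtering immune-related adverse event signals: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and filtering immune-related adverse event signals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iraesig)
```

## The problem

Immune checkpoint inhibitors (anti-CTLA-4 and anti-PD-1/PD-L1 antibodies)
cause a distinctive family of inflammatory toxicities — colitis, hepatitis,
pneumonitis, hypophysitis and others — collectively called immune-related
adverse events (irAEs). Spontaneous reporting systems such as FAERS are the
standard post-marketing source for detecting drug–event associations, but a
disproportionality scan over such a database mostly rediscovers toxicities
that are already on the drug label or described in the literature. The
interesting output is the *residual*: statistically disproportionate
associations that current knowledge does not explain.

`iraesig` implements that workflow at desk scale, in four stages:

1. **Case store (ETL).** FAERS-dialect report tables are deduplicated to
   the latest version of each case, verbatim drug names are mapped to
   standard ingredient concepts through a surface-form lexicon, and
   reaction codes are normalized to MedDRA preferred terms (PTs).
2. **Signal detection.** Reporting odds ratios (ROR) with Woolf 95%
   confidence intervals, at PT and system-organ-class (SOC) level, with the
   standard positivity rule.
3. **Text mining.** Dictionary lookup of MedDRA surface forms in drug-label
   sections and literature abstracts, producing PT-level term sets.
4. **Filtration.** Positive signals are partitioned into *labeled*,
   *unlabeled published* and *new* by comparing their codes against the
   mined term sets.

A synthetic-data module generates every input dialect with known ground
truth, so the full pipeline runs and is tested without licensed
vocabularies or real report data.

## The disproportionality model

For an exposure set $E$ (one drug, or a pooled class of ingredient concept
ids) and an event $e$, reports are cross-classified as

|            | with event | without event |
|------------|-----------:|--------------:|
| exposed    | $a$        | $b$           |
| unexposed  | $c$        | $d$           |

and the reporting odds ratio is
$\mathrm{ROR} = \dfrac{a\,d}{b\,c}$, with the Woolf (log-normal) interval
$$\exp\!\Big(\ln \mathrm{ROR} \pm z \sqrt{\tfrac1a + \tfrac1b + \tfrac1c +
\tfrac1d}\Big), \qquad z = 1.959964 .$$

A signal is **positive** when $a \ge 3$ and the CI lower bound exceeds 1.
This is a one-sided screen: the $a \ge 3$ floor suppresses single-report
noise, and the lower-bound rule corresponds to a two-sided 5% test used in
a one-directional way.

Counting conventions that matter:

* Each report falls in exactly one cell, however many matching drug rows
  or event rows it has; the cells always sum to the store size.
* At SOC level a report "has" the event if *any* of its PTs links to that
  SOC, through the primary or a secondary link. Using secondary links is a
  deliberate choice: multi-axial MedDRA places one PT under several SOCs,
  and SOC-level screening should see all of them. Primary-only counting
  remains reachable through `socs_for_pt(..., primary_only = TRUE)`.
* The event universe is the set of events observed in at least one exposed
  report: an event with $a = 0$ can never be positive and would only bloat
  the output.
* A zero cell leaves the ROR and interval undefined, flagged as such —
  never silently corrected. The `continuity` flag of `detect_signals()`
  opts in to the Haldane-style +0.5 on all cells of zero-cell tables; such
  rows are marked `corrected`, and the positivity rule always evaluates
  the *uncorrected* $a$.

## The ETL and its conservation law

FAERS cases are revised over time, so the same `caseid` appears under
several `caseversion`s. Deduplication keeps, per case, only the rows of
the maximum version; residual ties are broken by the lexicographically
greatest `primaryid`. The tie-break is arbitrary but fixed — deterministic
rebuilds matter more than which of two equal-version rows survives.

Reaction codes may arrive at LLT or PT level; both are accepted and
normalized to PT at load (each LLT links to exactly one PT). Codes unknown
to the hierarchy, or at HLT/SOC level, are counted as unmappable and
excluded; reports left with zero mappable events are dropped and counted.
Every load therefore satisfies

```
n_total = demo rows read − malformed − duplicates removed − zero-event dropped
```

and the load report exposes all four counts. Drug-name matching trims,
collapses internal whitespace and case-folds; ingredient, brand and
development-code synonyms all resolve to the ingredient concept. This is
why a concept-id query always retrieves a superset of a verbatim-string
search: reports that name only a development code (`MK-3475` for
pembrolizumab) are found by concept, not by name.

## The dictionary matcher

The text-mining stage stands in for a full clinical NER engine with a
deterministic primitive: case-insensitive exact-phrase matching on token
boundaries (tokens are maximal runs of letters and digits), greedy
left-to-right longest match, non-overlapping, with hyphens inside
dictionary terms treated as spaces. Every hit is normalized to PT level.
Two tie rules make the matcher deterministic: a PT surface beats an
identical LLT surface, and within a level the smallest code wins.

What is deliberately *not* done: no stemming, no abbreviation expansion,
no negation or hedge detection, no sentence segmentation. Laboratory-test
names are the canonical failure mode of dictionary matching in this domain
(matching *Alanine aminotransferase* where only *Alanine aminotransferase
increased* is an adverse event); keeping the matcher austere keeps its
false positives analyzable, and the evaluation operations quantify the gap
against a gold term set rather than hiding it.

SPL label documents are parsed with `xml2`; the WARNINGS AND PRECAUTIONS
and ADVERSE REACTIONS sections are selected by their LOINC section codes
(43685-7, 34084-4) with a case-insensitive title fallback, and all
descendant text is concatenated with single-space joins.

## Filtration and evaluation

Classification applies a fixed precedence: a positive signal found in the
label term set is `labeled`; otherwise, if found in the literature term
set, `unlabeled_published`; otherwise `new`. Because mined term sets
legitimately contain SOC-level terms, a PT signal whose own code is absent
falls back to any SOC linked to it; such assignments are flagged
(`matched_via = "soc"`) so reviewers can see which matches used the
relaxation. Classification summaries round to integer percentages;
evaluation metrics (precision, recall, F-measure as percentages) display
at one decimal. Zero denominators leave a metric absent, never zero.

Reviewer agreement uses the unweighted two-rater, two-category Cohen's
kappa, $\kappa = (p_o - p_e)/(1 - p_e)$, flagged undefined when both
raters are constant ($p_e = 1$).

## The synthetic-data generator

The generator emulates the study's input formats with controllable ground
truth:

* `make_meddra_fixture()` writes a `$`-delimited dictionary (SOC/PT/LLT
  term files, primary links in the PT file, secondary links in a separate
  file) with pronounceable unique synthetic names.
* `simulate_reports()` draws, per report, exposure to each drug
  independently, then each PT event with probability $p_1$ when an
  injecting drug is present and $p_0$ otherwise, where $p_1$ solves
  $p_1/(1-p_1) = \omega\, p_0/(1-p_0)$ for the design odds ratio
  $\omega$. Events are independent across PTs. Reports with an empty event
  draw get one redraw and are then dropped, because spontaneous reports
  always list at least one reaction. A configurable fraction of cases is
  emitted twice with incremented version to exercise deduplication, a
  fraction of reaction rows is recoded to a random LLT of its PT to
  exercise normalization, and verbatim drug names are sampled uniformly
  over each concept's surface forms to exercise the lexicon.
* `make_label_corpus()` / `make_abstract_corpus()` embed each planted
  term's surface exactly once in filler sentences built from
  non-dictionary words (each candidate sentence is itself checked against
  the matcher and resampled if it accidentally contains a surface), plus
  distractor sentences with no dictionary content.

One property of the zero-event drop deserves note. Conditional on a report
being kept, the per-PT event probability inflates from $p$ to
$p/(1-z)$, where $z$ is the per-draw probability of an all-zero event
vector. The conditional odds become $p \,/\, [(1-p)(1-B)]$ with $B$ the
keep-failure factor contributed by the *other* PTs. When a single pair is
injected, $B$ is identical in the exposed and unexposed arms, so the
truncation cancels exactly in the odds ratio: the design $\omega$ remains
the estimand of the ROR. When several events of the same drug are injected
at once, the arms' $B$ factors differ and the realized odds ratio is
attenuated — a masking-like distortion that real spontaneous data also
exhibits. The recovery tests therefore inject one pair per design when
checking CI coverage; multi-injection designs are still used where only
detection (not calibration) is asserted.

## Test conditions and what they show

The statistical recovery suite uses one drug at 30% exposure, six PTs with
a 1% background rate, 5000 drawn reports per replicate, and 100 replicates
per condition: all-null designs ($\omega = 1$) for the false-positive
rate of the positivity rule, and single injections at $\omega = 5$ and
$\omega = 20$ for power and CI coverage. At these sizes the $\omega = 20$
injection is detected in every replicate, nominal-truth coverage of the
95% interval sits in the low-to-mid 90s, and null pairs are flagged at a
few percent, consistent with the one-sided rule plus the $a \ge 3$ floor.
Oracle-equivalence tests compare every cell of `detect_signals()` against
a brute-force enumeration over reports on random stores of up to 200
reports, at both levels.

The generator emulates the *structure* of spontaneous-report data, not its
pathologies: no reporting-delay dynamics, no drug–drug confounding, no
correlated event clusters, no masking by competing signals (beyond the
truncation effect above), and synthetic rather than clinical vocabulary.
Passing tests therefore demonstrate the correctness of the counting,
normalization and interval machinery and the internal consistency of the
pipeline — not field performance of dictionary NER on real labels, which
the evaluation operations are designed to measure against a human gold
standard.

## Numerical and degenerate-input choices

* $z = 1.959964$ (the conventional 6-decimal 97.5% normal quantile) rather
  than `qnorm(0.975)`; the difference is far below reporting precision,
  and the fixed constant makes printed intervals reproducible by hand.
* Ranking ties in signal output break by ascending event code; category
  precedence in classification is label > literature > new.
* Sex codes outside F/M map to UNK; malformed rows are counted, never
  silently dropped; empty signal sets and empty gold sets are usage
  errors, while an empty *predicted* set is a legitimate input that leaves
  precision absent and recall zero.
* All generator randomness flows through a single seed per design, and
  every generator is byte-deterministic given its seed.

## Known limitations

* The matcher has no lexical-variant generation, so recall against a human
  gold standard on real labels is bounded by surface coverage of the
  dictionary.
* HLT support is limited to term identity (no PT→HLT links), which is all
  the filtration stage needs.
* SOC-level contingency counting counts *reports*, not events; a report
  with several PTs under one SOC contributes once. The alternative
  (event-level counting) is not implemented.
* The kappa reconstruction from marginal review counts is a 2×2 table
  consistent with those margins, not a published table; it is reported as
  such by the acceptance script.
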