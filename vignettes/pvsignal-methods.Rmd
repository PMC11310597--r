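---
title: "Disproportionality analysis of spontaneous reports with pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous reports with pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(data.table)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA's FAERS
collect reports in which a clinician or consumer names one or more
suspect drugs and one or more adverse reactions (coded as MedDRA
preferred terms, PTs). Such data have no denominator — nobody knows how
many patients took the drug without an event — so incidence cannot be
estimated. What *can* be estimated is disproportionality: whether a
drug–event pair is reported more often than the database background
would predict under independence. `pvsignal` implements this analysis
for the muscle-toxicity question around colchicine, statins, and their
combination: both drug classes cause myopathy and rhabdomyolysis on
their own, they share CYP3A4 metabolism and P-glycoprotein transport,
and their co-prescription is rising, so an interaction signal is a
live clinical concern.

## The statistics

Every statistic in the package is computed from a 2×2 contingency table
of report counts:

|              | target event | other events |
|--------------|--------------|--------------|
| index group  | $a$          | $b$          |
| comparator   | $c$          | $d$          |

The **reporting odds ratio** is $\mathrm{ROR} = ad/bc$ with the Wald
interval $\exp(\ln \mathrm{ROR} \pm z\sqrt{1/a + 1/b + 1/c + 1/d})$,
$z = 1.96$ for 95%. When a cell is zero the estimate is undefined and
the Haldane–Anscombe correction (0.5 added to each cell) is applied;
`ror()` applies it exactly when needed and reports whether it did.

The **information component** of the BCPNN family shrinks the observed
count toward its expectation $E = (a+b)(a+c)/N$ under independence:

$$\mathrm{IC} = \log_2 \frac{a + 0.5}{E + 0.5}.$$

The default interval is the credible-interval approximation of Norén
and colleagues,

$$\mathrm{IC}_{025} = \mathrm{IC} - \frac{3.3}{\sqrt{a+0.5}} -
\frac{2}{(a+0.5)^{3/2}}, \qquad
\mathrm{IC}_{975} = \mathrm{IC} + \frac{2.4}{\sqrt{a+0.5}} -
\frac{0.5}{(a+0.5)^{3/2}},$$

with a normal interval from the closed-form BCPNN posterior variance
(Bate's priors) selectable via `ic(method = "bate_variance")`. These
are the two standard IC variants; the choice is surfaced in the output
metadata rather than hidden. The shrinkage constant 0.5 means the IC is
biased toward 0 when $E$ is small — at $E \approx 10$ and a true
five-fold excess the IC's effect scale $2^{\mathrm{IC}}$ sits roughly
10–20% below the ROR, which is why the parameter-recovery checks allow
a wider band for $2^{\mathrm{IC}}$ than the sampling noise alone would
need.

A pair is flagged as a **signal** when all three hold: $a \ge 3$,
$\mathrm{ROR}_{025} > 1$, and $\mathrm{IC}_{025} > 0$. The case-count
floor and the IC condition both guard against the ROR's false positives
at small counts; the joint rule is deliberately conservative, and the
null-calibration tests measure (rather than assume) how conservative.

## From raw files to the table

FAERS quarters arrive as `$`-delimited ASCII tables (the post-2012
layout; older layouts are out of scope). The pipeline is:

1. **Ingest** (`read_quarter()`): verbatim rows; malformed lines are
   skipped and counted, never guessed at; orphan rows (no demographic
   row) are dropped only at assembly, with a count.
2. **Assembly** (`assemble_reports()`): one row per report. Ages convert
   to years by unit code (`MON`/12, `WK`/52.18, `DY`/365.25, `HR`/8766;
   a missing unit is accepted as years when the value is ≤ 120,
   otherwise unknown — a pragmatic guard against day-coded ages; `DEC`
   values are taken as already in years). Reporter occupation codes map
   to health-professional / non / unknown; the reporting country maps to
   a continent-level region through a packaged, editable table, because
   the region grouping is an analysis choice, not a FAERS field. Reports
   with no reaction row are uninterpretable as adverse-event reports and
   are dropped (counted).
3. **Deduplication** (`deduplicate()`): cases on a published deleted
   list are removed; among versions of one case the keeper is chosen by
   highest `caseversion`, then latest receipt date, then highest
   `primaryid`. The published analyses state only that duplicates were
   removed by case id; this keep rule is the conventional one and —
   what actually matters for reproducibility — deterministic and
   order-insensitive, which the test suite checks by permutation.
   `latest_receipt_only` is available as a switch.
4. **Exclusion** (`exclude_preexisting()`): reports whose drug
   *indication* is itself a myopathy term describe pre-existing disease,
   not a drug-induced event, and are removed. Indications are the proxy
   used because spontaneous reports carry no reliable medical history.
5. **Exposure** (`assign_groups()`): verbatim drug names are cleaned
   (uppercase, punctuation and dose/formulation tokens stripped) and
   looked up exactly in an editable dictionary of generics and trade
   names; no fuzzy matching, misses are `unknown` and logged. Exposure
   is defined on **primary-suspect (PS) drugs only**, because "the
   primary suspected drug" is the inclusion criterion this analysis
   mirrors; a `roles` switch widens to SS/C/I for sensitivity analyses.
   The label set — each single statin, `>=2 statins`, colchicine, each
   colchicine+statin pair, `colchicine+>=2 statins`, `other` — is
   mutually exclusive and exhaustive, and depends only on the ingredient
   set, never on row order.
6. **Case definition** (`classify_reports()`): a report is a myopathy
   case iff at least one reaction PT is in the term set. MedDRA is
   licensed, so the packaged set is an approximation of the narrow
   rhabdomyolysis/myopathy SMQ seeded with the PTs the field uses
   (including UK/US spelling variants); holders of a MedDRA license can
   drop in the full narrow SMQ as a CSV.

The counting unit is the **report** for term-set events and the
**(report, PT) pair** for single-PT events; this reproduces both the
per-drug count tables and per-PT signal tables of the conventional
study layout. `build_table()` uses the rest of the store as comparator
by default; an explicit `(c, d)` background is supported for running a
retrieved subset against full-database totals that are known only as
counts.

Percentages in the per-drug count table use the combined myopathy-case
denominator (all drug groups including the combination): that is the
only denominator under which per-drug shares of the case load add to
100, and it is the convention the published tables follow. Seriousness
outcomes allow multi-membership (FAERS permits several outcome codes
per report); outcome percentages are therefore shares of outcome
entries, which keeps each block summing to 100.

## The synthetic generator

`synthetic_truth()` + `simulate_reports()`/`generate_faers()` produce a
complete FAERS-dialect quarter with known ground truth, so every stage
— parser, dedup, name normalization, grouping, classification,
statistics — is testable without downloading anything. The generative
model: each report draws an exposure label from a configured mix; given
the label, each PT occurs as an independent Bernoulli with probability
$\min(1, r \cdot p_0)$, where $p_0$ is the PT's background probability
and $r$ the planted relative reporting rate. This is the simplest model
under which the ROR estimates $r$ (exactly, up to the odds-vs-risk gap,
which is below 5% at the default $p_0 \le 0.06$) and was chosen for
that reason — the tests' tolerances are statements about *this* model.
Reports that draw no event receive one filler background PT so that
every report has a reaction; this perturbs only the non-case cells.

Defaults sketch the structure (not the scale) of the real database:
74% unrelated reports, single-statin and colchicine groups at a few
percent, combination groups below 1%, planted myotoxicity excesses
strongest for the combination; a 5% duplicate rate exercising the
keep rule (duplicates are exact copies except `caseversion` and receipt
date, by design — they test the dedup path specifically); 0.5% of
reports carry a myopathy indication to exercise the exclusion.
Demographic marginals (age ~ N(62, 18²) truncated to [1, 100] with 15%
unknown; sex 45/45/10; reporters 55/35/10; regions weighted toward
North America and Europe) are checked against realized frequencies at
3 standard errors. All randomness comes from one seeded stream in a
fixed draw order, so a seed reproduces files byte for byte.

What the generator does **not** emulate: stimulated reporting,
masking/competition bias, notoriety effects, drug-name misspellings
beyond dose/formulation noise, report-level missingness correlation.
Passing tests on synthetic data therefore show the machinery is
correct under the stated model, not that real-FAERS estimates are
unbiased — disproportionality never measures incidence.

## Problem sizes and numerical choices

The test suite exercises stores of 10³–10⁴ reports for exactness
properties, one 10⁵-report store for parameter recovery, 1,000
simulated tables for interval coverage, and 100 seeded 2,000-report
stores (null) plus 100 seeded 20,000-report stores (power at an
expected case count of 50) for calibration — sizes at which binomial
noise is small enough for the stated tolerances (e.g. 25% relative
error at an expected $a \approx 50$ spans ±3 SD of sampling noise plus
the IC's shrinkage bias).

Degenerate inputs are defined, not fatal: an all-zero event column
yields $a = 0$ tables and no signals; a zero cell triggers the Haldane
correction (or an instructive error if the correction is disabled); an
empty index group is an error naming the problem; unparseable
demographics degrade to unknown and are counted in the store log.
Ties in deduplication are broken deterministically (receipt date, then
`primaryid`). Dates are compared as `yyyymmdd` integers; missing dates
sort last.

## Limitations

- The packaged SMQ term set is an approximation; results shift with the
  term set, which is exactly why it is a visible, editable input.
- The published analyses' own ROR/IC values are not reproducible from
  printed numbers alone (the full-database comparator counts behind
  them are not published); the package therefore validates its
  statistics against closed-form oracles and planted-truth recovery
  instead, and supports an explicit-background comparator for users who
  have such totals.
- Exposure defined on same-report PS co-listing is the operational
  stand-in for true concomitant use; FAERS has no dosing timeline
  robust enough for more.
- No multiplicity adjustment is applied across PTs or groups, matching
  standard practice for hypothesis-generating signal screens; the
  joint rule is the only false-positive control.
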