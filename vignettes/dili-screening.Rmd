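---
title: "Screening for drug-induced liver injury when baselines are abnormal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for drug-induced liver injury when baselines are abnormal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dishtools)
library(dplyr)
```

## The problem

Clinical-trial liver safety review has long relied on the eDISH scatterplot:
each subject's peak on-treatment aminotransferase (AT, i.e. ALT or AST) is
plotted against peak total bilirubin (TB), both in multiples of the upper
limit of normal (xULN). A vertical cut at AT 3xULN and a horizontal cut at
TB 2xULN define four quadrants — normal/near-normal (NNN), Temple's
Corollary (AT elevated without jaundice), Cholestasis (jaundice without
substantial AT elevation) and the potential Hy's Law quadrant (both
elevated), the last of which marks possible hepatocellular drug-induced
liver injury (DILI) with a fatality risk of roughly 10% or more. eDISH
serves three screening functions at once: visualizing between-arm shift,
categorizing subjects by severity, and identifying individual subjects for
in-depth review.

All three functions presuppose normal or near-normal baselines. In trials
that enroll subjects with pre-existing liver disease — increasingly common
as drugs target liver disorders, and as the background prevalence of MASLD
forces liver-abnormal subjects into non-liver trials — a subject may sit in
the Hy's Law quadrant before the first dose, or may have *improved* into
it from even higher values. eDISH cannot show that. `dishtools` implements
the screening toolkit for these abnormal-baseline (ABN-BL) trials:
baseline-anchored categorization, category-shift Sankey diagrams with
cross-tables, composite per-destination mDISH plots, and a modified
waterfall plot, plus an advisor that says which toolset applies and a
synthetic-trial simulator that makes the whole pipeline testable without
patient data.

## Categories, bands and the shift lattice

`banding_scheme()` partitions the (AT, TB) xULN plane. The classical
scheme uses AT >= 3xULN (the boundary is inclusive on the elevated side)
and TB > 2xULN (strict, so the boundary point (3, 2) lands in Temple's
quadrant). We follow the figure-caption convention for the boundary
inclusivity; the alternative reading with a strict AT cut differs only on a
measure-zero set and on values reported exactly at the cut.

Two refinements are available. `extra_tb_band = TRUE` inserts an
intermediate bilirubin band at (1.5, 2] xULN, which yields six categories
and finer resolution for liver-disease populations whose TB hovers below
the jaundice cut. `split_nnn = TRUE` splits NNN at ALT 1xULN into Normal
and NearNormal. Both keep the plane partitioned with no gaps or overlaps —
a property the test suite checks on a boundary-including grid.

Each category carries a pair of band ranks, ordered componentwise:
a shift is **upward** (potential DILI, rendered pink/red) when the
destination is strictly above the origin in both coordinates' weak order,
**downward** (potential improvement/efficacy, green) when strictly below,
**none** on the diagonal, and **lateral** when the categories are
incomparable. Temple vs Cholestasis is the canonical lateral pair: a move
between them trades enzyme elevation for jaundice and is treated as
neutral (yellow in the cross-tables) rather than as worsening or
improvement, since the lattice gives it no direction. When NNN is split,
the two merged Cholestasis cells take the minimum band rank as their
representative, so NearNormal to Cholestasis is lateral, not downward.

For display, categories are ordered by severity with TB dominant: HyLaw,
then Cholestasis, then Temple, then NNN. The lattice leaves Cholestasis
and Temple unordered; the jaundiced category is placed higher because
jaundice drives the fatality risk behind Hy's Law.

## From records to profiles

`read_lab_csv()` ingests long-format subject-level laboratory data (an
SDTM LB-style preset is included). Numerical conventions, chosen once:

* **Baseline** is the value at the largest `study_day <= 0`, so a day-0
  pre-dose draw counts as baseline — the standard trial convention.
* **Duplicates** on (subject, analyte, day) keep the maximum value. For a
  safety screen, the conservative resolution is the one that cannot hide
  an elevation; collisions are counted in the ingest report.
* **On-treatment window** is `(0, treatment_end_day + followup_lag_days]`
  with a default follow-up lag of 30 days, a common safety-window
  convention; there is no field standard, so the lag is a parameter.
* **AT policy**: mDISH, Sankey and waterfall analyses use ALT. Classical
  eDISH may use `max_alt_ast`, taking each day's larger of the two
  enzymes' xULN before maximizing over days; AT then has no meaningful
  absolute unit, and the profile stores xULN directly with ULN fixed at 1.
* **Zero or missing baseline** leaves xBL undefined. Such subjects stay in
  all xULN analyses and are excluded, with a logged reason, from xBL plots
  — division by a zero baseline is not patched with an epsilon.
* Units are not converted. xULN normalization makes them moot for
  categorization; the absolute-value waterfall assumes ALT in U/L, which
  is documented rather than enforced.

Peaks are independent maxima per analyte: the AT peak day need not be the
TB peak day. This follows standard eDISH practice and can overstate
simultaneity for subjects whose two peaks are far apart; the per-day
pairing is deliberately not offered because no published variant defines
it.

## The three artifacts

**Sankey + cross-tables.** Baseline categories for *all* subjects form a
center column ordered by severity; each arm's flows leave toward its own
side (comparator left, active right), pink for upward, green for downward.
Ribbon thickness defaults to within-arm proportions rather than counts, so
a 1:3 randomization stays visually comparable — the tests assert that two
arms with identical shift distributions but 3-fold different sizes produce
identical ribbon fractions. Diagonal (no-shift) subjects are drawn as flat
grey ribbons; without them the flow conservation that the tests verify
(per-category outflow equals the category's arm count) would not be
visually true. Cross-tables print counts only, origin rows by destination
columns, colored red/green/grey/yellow by shift class.

**Composite plots.** One mDISH (xBL) panel per destination category,
restricted to its arrivals, each point marked by origin with a fixed
legend (NNN green square, Temple blue plus, Cholestasis orange triangle,
HyLaw red star). Over all destinations the panels partition the
mDISH-eligible subjects — the union property the suite checks. No severity
boundaries are drawn in xBL space: because every subject is re-anchored to
its own baseline, a 3xBL/2xBL cross would separate nothing meaningful, and
subjects with identical relative changes coincide regardless of absolute
severity (the package reproduces this pathology as a test: equal-xBL
subjects coincide on mDISH while differing 5-fold on eDISH).

**Modified waterfall.** Subjects ordered by baseline ALT — comparator
ascending, then active descending, ties broken by subject id — so the
black baseline profile peaks mid-figure. Bars show ALT change from
baseline in U/L with two modes. `max_magnitude` takes the signed change of
largest absolute size (a magnitude tie keeps the increase,
safety-conservative); it captures efficacy but can mask a DILI rise
smaller than the subject's largest decline. `max_increase` always reports
peak minus baseline, focusing on DILI risk; the suite demonstrates the
difference on a subject whose +100 U/L rise hides behind a -150 U/L fall.
New-onset jaundice (peak TB above the 2xULN cut from a baseline at or
below it — the "new onset" baseline criterion is ours, since none is
standard) turns bars green. Horizontal severity lines default to 300, 600
and 900 U/L. Box-whisker panels at the far left and right summarize the
*bar values* per arm with Tukey whiskers (1.5 IQR); summarizing bars
rather than absolute peaks was an open choice, made because the bar is the
quantity the plot ranks subjects by.

The waterfall is only offered when baseline TB is essentially restricted:
`check_applicability()` requires the baseline-jaundiced fraction to be at
most 2% (configurable); one jaundiced subject among a thousand passes.

## The advisor

`recommend_tools()` maps the baseline pattern — the fraction with ALT at
or above the elevated cut, and the three baseline TB band fractions — to
tool applicability. Sankey + cross-tables + composite plotting applies
across all abnormal-baseline patterns; the modified waterfall applies only
when no substantial fraction has baseline TB above 2xULN. "Substantial" is
quantified at 5% by default; the underlying guidance is deliberately
qualitative, so the threshold is exposed. When nothing is substantial the
advisor notes that the trial is effectively NNN-baseline and classical
eDISH applies. Raising the baseline-jaundice fraction can only switch the
waterfall off, never back on — a monotonicity the tests check.

## The synthetic data

`simulate_trial()` draws two-arm trials from a `synthetic_spec()`:
baseline categories per arm from a multinomial mix, values log-uniform
*within* the assigned band (so the baseline category is exact by
construction; bands are capped at 10xULN ALT and 6xULN TB for realism),
visits at day -14, -1 and then every 28 days to day 336 by default, with
lognormal visit-to-visit noise (sdlog 0.15, roughly the within-subject
variability of serial ALT). Three injectable on-treatment signals emulate
the patterns a reviewer must distinguish: a hepatocellular DILI surge (ALT
to a multiple of baseline with optional absolute floor, with TB rise), a
multiplicative efficacy decline, and a hemolysis-type isolated TB rise
with no ALT elevation. Default signal rates (active arm: DILI 2%,
efficacy 30%, hemolysis 1%) sketch a modestly hepatotoxic but effective
drug in a chronic-liver-disease population.

The simulator emulates the *categorical* structure of real trials. It does
not model dose interruptions, visit nonadherence, assay batch effects,
correlated ALT/AST/TB dynamics, or disease-specific fluctuation (e.g. the
wide swings of alcohol-related liver disease). Passing tests therefore
show that the aggregation machinery is correct under the stated generative
model, not that the toolkit's operating characteristics on any real
disease population are known.

Two deterministic fixtures, `study1_fixture()` and `study2_fixture()`,
are *constructed*, not sampled: published summaries of this kind pin only
marginal counts (arm sizes, baseline category counts, upward-path counts
and totals, destination-category origins, a single baseline-jaundiced
subject), and the fixtures place exactly those counts while putting all
remaining mass on the diagonal. Within each cell, baseline values are
log-spaced across the band so orderings are non-degenerate. These are
stand-ins for trials whose subject-level data are not public; the tests on
them validate the categorization and aggregation machinery against known
tallies, and nothing else.

## Reporting conventions and numerics

* Whole-number percentages are rounded half-up (`report_proportion()`),
  the convention that reproduces printed tallies like 13/46 = 28%.
* Log-scaled scatter axes floor displayed multiples at 0.01 — display
  only, never categorization.
* Figures are written through the cairo SVG/PNG devices; for a fixed
  input and style the SVG output is byte-stable, and the suite asserts
  byte-identical re-renders and byte-identical full screening bundles.
* The priority list orders upward-shifted subjects by destination
  severity, then peak TB xULN, then peak AT xULN, all descending — TB
  before AT because jaundice carries the fatality signal. Both arms are
  listed by default (placebo upward shifts contextualize background
  disease progression); `active_only` restricts to the active arm.

## Problem sizes used by the checks

The property suites run 100 simulated trials of 30 subjects per arm with a
five-visit schedule for conservation, 50 seeds of 60 subjects for baseline
marginal fidelity (99% binomial bounds), and a 21 x 25 boundary-including
grid for the categorization oracle; the fixtures are full size (92 and
1019 subjects). These sizes make every structural property exercised at
realistic scale while keeping the default check fast.

## Known limitations

Causality adjudication, fatality-rate estimation for chronic liver
disease, ALP-based cholestatic analogues and interactive drill-down are
out of scope. No validated fatality rates exist for any ABN-BL grouping,
so upward shifts flag subjects for review; they do not carry Hy's-Law-like
risk quantification. Subjects who stay in the Hy's Law or Temple category
throughout can still worsen greatly without an upward *category* shift;
they appear on the composite plot for their category but not in the pink
flows, and reviewers should examine them there. Multi-arm trials,
unit auto-conversion and per-visit trajectory plots are non-goals.
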