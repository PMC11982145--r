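# dishtools

Liver safety screening graphics for clinical trials whose subjects may have
**abnormal baseline liver tests**.

The classical eDISH scatterplot — each subject's peak on-treatment
aminotransferase (AT) versus peak total bilirubin (TB), both in multiples of
the upper limit of normal (xULN), cut at AT ≥ 3×ULN and TB > 2×ULN into the
NNN, Temple's Corollary, Cholestasis and potential Hy's Law quadrants —
screens for drug-induced liver injury (DILI) by visualizing between-arm
shift, categorizing subjects by severity, and identifying individual cases
for review. Those three functions break down when subjects start the trial
with abnormal values: a subject may occupy the Hy's Law quadrant at
baseline, or may have *improved* into it.

`dishtools` re-anchors the analysis to baseline. It assigns each subject a
quadrant category **at baseline** and **at on-treatment peak** (both in
xULN), classifies the shift on the category lattice (upward = potential
DILI, downward = potential efficacy, lateral = neutral, e.g. Temple ↔
Cholestasis), and builds the screening artifacts for abnormal-baseline
trials:

- **Sankey diagrams** with pooled baseline categories center-anchored
  (most severe on top), placebo flows left / active flows right, upward
  shifts pink, downward green; ribbon widths are within-arm proportions so
  unequal randomization (e.g. 1:3) stays comparable;
- **cross-tables** of origin × destination counts with red/green/grey/yellow
  cell classes;
- **composite mDISH plots** (peaks in multiples of each subject's own
  baseline, ×BL) per destination category, each arrival marked by its
  category of origin;
- **modified waterfall plots**: subjects ordered by baseline ALT, bars for
  maximum on-treatment ALT change (max-magnitude or increase-only mode),
  green bars for new-onset jaundice, severity lines at 300/600/900 U/L,
  Tukey box-whisker summaries per arm;
- classical **eDISH** and **mDISH** scatter data for comparison, an
  **advisor** that recommends Sankey+composite vs waterfall from the
  baseline ALT/TB pattern, and a deterministic **synthetic-trial
  simulator** plus two constructed study-like fixtures so the whole
  pipeline is testable without patient data.

Everything is tidyverse-native: functions take data frames and return
tibbles, result objects have `tidy()`/`glance()` methods and ggplot2
`autoplot()` methods, and `run_screen()` drives the pipeline end-to-end
from a YAML config.

## Worked example

Screen a 1019-subject, 1:3 randomized trial (a built-in constructed
fixture emulating a chronic-liver-disease trial with mostly normal
baselines):

```r
library(dishtools)

trial    <- study2_fixture()
profiles <- derive_profiles(trial$records, trial$manifest)
shifts   <- shift_records(profiles)

classify_trial_baseline(profiles)
#> <trial_baseline_class> ABN-BL (abnormal-baseline fraction 10.6% over 1019 subjects)
#> # A tibble: 8 × 5
#>   arm     category        n arm_n percent
#>   <chr>   <fct>       <int> <int>   <int>
#> 1 Active  NNN           684   765      89
#> 2 Active  Temple         81   765      11
#> 3 Active  Cholestasis     0   765       0
#> ...
```

11% of active-arm subjects (81 of 765) start in Temple's quadrant, so the
trial is abnormal-baseline and classical eDISH alone would mislead. The
cross-table counts every baseline→peak shift; red cells (upward) flag
potential DILI:

```r
build_cross_table(shifts, "Active")
#> <dili_crosstab> arm: Active | total: 765
#>              destination
#> origin        HyLaw Cholestasis Temple NNN
#>   HyLaw           0           0      0   0
#>   Cholestasis     0           0      0   0
#>   Temple          1           0     40  40
#>   NNN             4           3      0 677

upward_shift_summary(list(build_cross_table(shifts, "Placebo"),
                          build_cross_table(shifts, "Active")))
#> # A tibble: 2 × 3
#>   arm     upward_total upward_paths
#>   <chr>          <int>        <int>
#> 1 Placebo            4            1
#> 2 Active             8            3
```

The active arm shows 8 upward shifts along 3 paths (4 NNN→HyLaw, 1
Temple→HyLaw, 3 NNN→Cholestasis — the last a hemolysis-type jaundice
without ALT rise), none of which occur in placebo. The composite plot data
identify the five Hy's Law arrivals individually, with their origin:

```r
composite_points(profiles, "HyLaw")
#> # A tibble: 5 × 5
#>   subject_id arm        x     y origin
#> 1 S2A0678    Active  6.67  4.80 NNN
#> 2 S2A0679    Active  5.56  4.19 NNN
#> 3 S2A0680    Active  4.63  3.65 NNN
#> 4 S2A0681    Active  3.86  3.18 NNN
#> 5 S2A0725    Active  1.05  3.91 Temple
```

(`x`, `y` are peak ALT and TB in ×BL.) Because only one subject has
baseline jaundice, the advisor also clears the single-figure waterfall:

```r
recommend_tools(baseline_pattern(profiles))
#> <tool_recommendation>
#>   sankey_crosstab_composite  recommended
#>   modified_waterfall         recommended
```

`run_screen(run_config(input = "study2", out_dir = "out"))` writes the
whole bundle: `sankey.svg` (with per-arm cross-tables), per-category
composite CSVs, `waterfall.svg`, a priority list headed by the five Hy's
Law arrivals, and a JSON summary. A thin CLI over the same functions lives
at `inst/scripts/dili-screen.R` (subcommands `screen`, `simulate`,
`fixtures`, `advise`).

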