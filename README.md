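# crcdisrupt

Person-level microsimulation of colorectal cancer (CRC) screening
disruptions. The package is for modellers and screening-programme
analysts who want to ask: *if a cohort's screening is delayed, switched
to another modality, paused for years, or abandoned — as happened at the
onset of the COVID-19 pandemic — how much of the lifetime benefit of
screening is lost?*

It simulates the adenoma–carcinoma natural history of CRC (Poisson
adenoma initiation with lognormal person-level risk, von-Bertalanffy
growth, size-proportional malignant transformation, lognormal preclinical
sojourn, stage-specific survival, life-table other-cause mortality),
applies colonoscopy and FIT screening with polypectomy, stage shift and
post-polypectomy surveillance, and evaluates disruption scenarios as
**paired counterfactuals on common random numbers**: every person is
replayed under three arms — disrupted, no-disruption, and no-screening —
with identical natural-history and detection draws, keyed by
`(seed, person, purpose, counter)` rather than by call order.

## The outcome calculus

With LY the cohort's life-years under the disrupted scenario, LYND under
the no-disruption counterfactual, and LYNS under no screening (per 1,000
persons, counted from the cohort's age at the pandemic onset):

```
LYL        = LYND − LY          life-years lost to the disruption
LYG        = LYND − LYNS        life-years gained by undisrupted screening
% LY lost  = 100 · LYL / LYG    share of the screening benefit lost
```

Scenarios cover eight cohorts (unscreened, colonoscopy-adherent,
FIT-adherent and FIT-semi-adherent 50/60/70-year-olds) crossed with
short-term delays of 3/9/18 months, long-term delays (colonoscopy only at
age 65/75 or 75), a permanent switch from colonoscopy to annual FIT, and
complete discontinuation — 49 scenarios, labelled
`"<cohort> | <code>"` (`C60 | F18m`, `U50 | C@65`, `F70 | U`, …).

## Worked example

```r
library(crcdisrupt)
cfg <- default_config()   # two parameter sets, high/low test sensitivity
rec <- run_all(cfg, n = 20000, master_seed = 42, param_sets = "model_a",
               sensitivities = "high_sensitivity", scenario_filter = "C60*")
rec[, c("scenario_label", "LYL", "LYG_nd", "pct_ly_lost", "se_LYL")]
```

```
  scenario_label     LYL LYG_nd pct_ly_lost se_LYL
1      C60 | C3m  0.1925    183       0.105   1.03
2      C60 | C9m -0.0383    183      -0.021   1.73
3     C60 | C18m  2.5222    183       1.379   2.49
4      C60 | F3m  0.6604    183       0.361   3.65
5      C60 | F9m  3.7088    183       2.028   3.73
6     C60 | F18m  3.2986    183       1.804   3.81
7     C60 | C@65  1.3817    183       0.756   3.88
8        C60 | U  69.2811   183      37.882   6.54
```

Reading: for 60-year-olds who had a colonoscopy at 50, undisrupted
screening is worth 183 life-years per 1,000 persons (`LYG_nd`). Short
delays cost at most a few LY per 1,000 — indistinguishable from zero at
this cohort size (`se_LYL` is the paired Monte Carlo standard error) —
while discontinuing screening (`C60 | U`) forfeits 69 LY per 1,000,
about 38% of the entire benefit. Negative point estimates on small
losses are Monte Carlo noise, within one standard error of zero.

`run_disruption_analysis()` runs the full grid and writes `outcomes.csv`
(one row per scenario × sensitivity × parameter set; columns are the
quantities above plus `LY`, `LYNS`, `LYND`, `ly_days_per_person` and
`se_LYG`), `summary.csv` (ranked cross-model ranges) and `scenarios.csv`
(the scenario audit table). A thin command-line wrapper is included:

```sh
exec/crcdisrupt list-scenarios
exec/crcdisrupt run --n 200000 --seed 1 --out results/
exec/crcdisrupt report --outcomes results/outcomes.csv
```

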