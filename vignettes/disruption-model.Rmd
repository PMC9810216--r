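---
title: "The crcdisrupt model: natural history, screening, and the disruption calculus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The crcdisrupt model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`crcdisrupt` is a person-level microsimulation of colorectal cancer (CRC)
natural history and screening, built to quantify how pandemic-style
disruptions to screening — delays, regimen switching, long pauses, and
outright discontinuation — erode the lifetime benefit of a screening
programme. This vignette is the package's own account of the model: its
assumptions, its tunable parameters, the common-random-number design that
makes the counterfactual comparisons tight, and its known limitations.

## The natural-history model

Each simulated person carries an untreated disease trajectory built on the
adenoma–carcinoma sequence:

* **Risk heterogeneity.** A person-level deviate $\psi_i \sim
  \mathcal N(\mu_\psi, \sigma_\psi^2)$ is added to the log adenoma
  intensity. With the default $\sigma_\psi$ of 1.1–1.3 most persons never
  develop an adenoma while a small tail develops several, which is what
  gives screening its concentrated benefit.
* **Adenoma initiation.** Adenomas arise from a non-homogeneous Poisson
  process with log-intensity $\psi_i + g(a)$, where $g$ is piecewise
  linear in age $a$ with knots at ages 20/50/60/70 (flat outside), zero
  before age 20. Counts and times are drawn by inversion of the
  integrated intensity, so they are exact functions of keyed uniforms.
* **Growth.** Each adenoma follows von-Bertalanffy growth
  $d(t) = d_\infty - (d_\infty - d_0)e^{-\lambda t}$ from $d_0 = 1$ mm
  towards $d_\infty = 50$ mm. The lesion-specific rate $\lambda$ is set
  by drawing the time to reach 10 mm from a Fréchet distribution
  (scale 10–12 yr, shape 1.8–2) and inverting the growth curve; most
  adenomas grow slowly, a minority quickly.
* **Malignant transformation.** A size-proportional hazard
  $h(t) = \beta\, d(t)$ (per yr per mm) governs progression to
  preclinical invasive cancer; the transformation age solves the
  closed-form cumulative hazard by bisection.
* **Sojourn and presentation.** Preclinical cancer dwells a lognormal
  sojourn time (mean 3–3.5 yr in the defaults) before clinical
  (symptomatic) diagnosis, during which it is screen-detectable.
* **Stage and survival.** Clinical diagnoses draw a stage I–IV from a
  multinomial; screen-detected cancers draw their stage from a
  row-stochastic *stage-shift* matrix applied to the would-be clinical
  stage. The shift rows place all mass at or below the clinical stage,
  so screen detection never worsens the stage. Post-diagnosis survival
  is exponential with a stage-specific rate (roughly 95/86/64/11%
  five-year survival).
* **Other-cause death.** A Gompertz–Makeham life table supplies all-cause
  (non-CRC) mortality on a 1-year grid from 0 to 110; the hazard beyond
  110 is treated as infinite, so everyone has a finite death age at or
  below 110. One consequence worth noting: with a constant hazard of
  0.01/yr the *capped* life expectancy is $(1-e^{-1.1})/0.01 \approx
  66.7$ yr, not the uncapped exponential mean of 100 yr; the tests
  assert the capped value because that is what the model samples from.

Two parameter sets ship in `inst/extdata/default_params.yaml`
(`model_a`, `model_b`). Their values are *sanity-targeted*, not
calibrated to any registry: both give a lifetime clinical CRC risk
without screening of about 4–6% (4.3% and 5.5% at $n = 5\times10^4$),
mean sojourn of 3.5 and 3.0 yr, and a life expectancy at birth of about
77 yr. Runs report the min–max across the two sets, emulating the
cross-model range one gets from structurally different models. Exact
reproduction of any published calibrated model is out of scope.

## Screening tests and surveillance

Colonoscopy and FIT are modelled with per-lesion sensitivities by size
class (small < 6 mm, medium 6–9 mm, large ≥ 10 mm), a sensitivity for
preclinical cancer, and a specificity. The shipped high-sensitivity
colonoscopy is 0.75/0.85/0.95 with 0.95 for preclinical cancer; the
low-sensitivity scenario lowers these to 0.65/0.75/0.85/0.90. FIT is
0.05/0.10/0.22 with 0.74 for cancer and specificity 0.96; a positive FIT
(true or false) triggers an immediate diagnostic colonoscopy. Whether
FIT sensitivity should act per lesion or per person-exam is genuinely
open; per lesion was chosen because it makes multi-lesion persons more
detectable, which is the behaviour reported for hemoglobin-based tests.

Detected adenomas are removed (polypectomy) and their transformation is
cancelled — removal is permanent. Findings assign surveillance per
standard post-polypectomy practice: three or more adenomas or any large
one → colonoscopy in 3 yr; one to two smaller ones → 5 yr; a clear
colonoscopy returns the person to their routine regimen with no exam
within 10 yr; surveillance stops after age 80.

## Common random numbers and the keying of draws

Every random quantity is a pure function of a key
`(master seed, person, attempt, purpose, counter)` hashed through a
splitmix64 finalizer. This gives three properties the analysis depends
on: bit-for-bit reproducibility; order independence (simulating persons
in any order, or a prefix sub-cohort, yields identical histories); and
paired counterfactual arms, because the same person re-played under a
different screening schedule consumes exactly the same natural-history
draws.

Detection draws are keyed by *(person, lesion, modality, exam ordinal)*.
The ordinal — the exam's position in the person's sequence of exams of
that modality — rather than the calendar date means an exam that is
merely delayed re-uses the same draw in both arms, so the paired
difference isolates the timing effect. Keying by lesion alone (one
permanent draw per lesion and modality, reused at every exam) was tried
first and rejected: it is not variance-neutral. Under a single reused
draw a delayed exam sees a larger lesion and the same latent uniform
systematically crosses the size-class sensitivity threshold, making
delays *beneficial* in expectation, and annual FIT loses all cumulative
multi-round sensitivity, roughly tripling the apparent cost of switching
from colonoscopy to FIT. Ordinal keying preserves the pairing rationale
while keeping successive exams independent, as they are in reality.

Survival after a screen-detected diagnosis is anchored at the lesion's
*would-be clinical diagnosis age*, with a survival quantile shared across
arms and a (weakly) lower stage: this removes lead-time bias and makes
earlier detection deterministically no worse for a fixed person. With
anchoring at the detection age instead, the same person could die
earlier in the screened arm purely by lead time.

The false-positive draw of a FIT is keyed by the FIT ordinal; since
pre-pandemic exams are common to both post-onset arms, false-positive
histories stay aligned until the arms genuinely diverge.

## Cohorts, scenarios and disruption rules

Cohorts are defined by age at the pandemic onset (April 2020, the
reference age) and their pre-pandemic screening, which is actually
simulated: members are conditioned — by deterministic rejection with a
per-person attempt counter — on being alive and free of any CRC
diagnosis at the reference age given that history. Life-years are
counted from the reference age; differences (LYL, LYG) are invariant to
this origin and per-1,000 numbers are comparable across cohorts.

The disrupted schedule rules are: short-term delays of 3/9/18 months
shift every post-onset exam by $d/12$ yr, carried forward — including
past the regimen stop age when the undelayed exam was within it (an
18-month delay must not silently drop the final exam); long-term delays
replace the schedule with colonoscopies at the stated resume ages (for
the 60-year-old cohorts, at 65 *and* 75, the second exam following from
the decennial interval); switching yields annual FIT to 75 with the
first FIT delayed by $d$ months; discontinuation removes every
post-onset exam, surveillance included. Surveillance colonoscopies owed
from pre-pandemic findings are delayed by the same $d$ (clinics were
closed for screening and surveillance alike), and under long-term delay
they cannot occur before the first resume age. Diagnostic colonoscopy
after a positive FIT is never delayed: it is triage of a positive test,
not screening. The semi-adherent f60 cohort resumes *annual* FIT at 60
(the study design's table form; the config makes this switchable by
editing the counterfactual regimen). One regimen switch at most is
modelled.

## Outcomes

With LY the cohort's life-years under the disrupted scenario, LYND under
the no-disruption counterfactual and LYNS under no screening at all
(all per 1,000 persons from the reference age):

$$\mathrm{LYL} = \mathrm{LYND} - \mathrm{LY}, \qquad
  \mathrm{LYG} = \mathrm{LYND} - \mathrm{LYNS}, \qquad
  \%\,\mathrm{LY\ lost} = 100\,\mathrm{LYL}/\mathrm{LYG},$$

with the percentage undefined (reported missing) when LYG ≤ 0, and the
loss also reported as life-days per person
($\mathrm{LYL}/1000 \times 365.25$). The Monte Carlo standard error of
LYL comes from the paired per-person differences, typically an order of
magnitude smaller than the unpaired error. Ranked summaries order
scenarios by mid-range LYL (ties by label) and flag losses below two
life-days per person.

## Numerical choices and degenerate inputs

Ages are continuous doubles; the life table is piecewise-constant on
1-yr bins and inverted exactly. Exam-time ties: an exam scheduled at the
exact moment of death or clinical presentation does not happen (strict
inequality); a surveillance exam coinciding with a routine exam takes
its place. The clear-colonoscopy skip uses a $10^{-9}$-yr tolerance so
an exam exactly 10 yr later still occurs. Adenoma counts per person are
capped at 500 (far beyond any realistic draw); transformation times
beyond $10^6$ yr are treated as never. Degenerate parameters are legal
where they are useful for testing: zero intensity (no adenomas), zero
sojourn variance, a fixed-age life table, and a fully deterministic toy
mode (`fixed_history` plus fixed survival years) in which every person
has the same single-adenoma timeline — the basis of the hand-computed
oracle (`make_toy_fixture()`), where discontinuation loses exactly 20
life-years per person.

## What the tests do and do not show

The test suite checks the machinery against independent oracles
(Poisson counts by chi-square, binomial detection, false-positive rates,
life-table quadrature, a hand-computed deterministic timeline, and an
R reference replay that must agree with the compiled engine exactly),
and checks the *orderings* the epidemiology implies: discontinuation
dominates every other disruption; losses grow with delay length;
70-year-olds lose less than 60-year-olds; high-sensitivity tests gain
more benefit but lose similar amounts to a given disruption. Ordering
checks run at $n = 2\times10^5$ persons per cohort with two pooled
standard errors of slack; the acceptance script uses $n = 10^5$ per
cohort across both parameter sets and both sensitivity scenarios. These
sizes keep a full grid under a minute of compute while leaving paired
standard errors around 1–3 LY per 1,000.

Passing them shows the simulator is internally coherent and reproduces
the qualitative structure of screening-disruption analyses. It does not
show calibration to any population: the generator emulates realistic
magnitudes (lifetime risk, sojourn, life expectancy, stage-specific
survival), but real data have sex and site structure, adherence
behaviour, test-specific hemoglobin thresholds, colonoscopy complications
and registry-calibrated dwell times that this model deliberately omits.
Absolute LY numbers should be read as model-scale quantities; the
comparisons between scenarios are the deliverable.

## Known limitations

No population-level projections (the cohorts are conditional scenarios,
not a weighted population); no cancer-incidence, mortality or
utilization outcome tables; no cost-effectiveness; no parameter or
sampling uncertainty beyond the paired Monte Carlo errors and the
two-parameter-set range; no treatment disruption; no colonoscopy harms,
so screening is never net-negative by construction and LYL ≤ LYG holds
in expectation.
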