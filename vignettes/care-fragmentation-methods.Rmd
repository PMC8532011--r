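---
title: "Methods: phenotyping, the PCP + distance constraint, and care-fragmentation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping, the PCP + distance constraint, and care-fragmentation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carefrag)
```

## The problem

American patients commonly obtain care from several unaffiliated health
care systems, so no single system holds a complete record — *care
fragmentation*. Cost-prediction models that drive care-management programs
for chronic disease assume complete history, which makes them unusable on
fragmented data. A pragmatic workaround is to restrict modelling to the
patients whose care is mostly in-system. carefrag implements that
selection rule and the machinery to evaluate it: the patient must (a) hold
an in-system primary care physician (PCP) and (b) reside within $d$ km
(geodesic) of at least one in-system hospital. Performance is the share of
the selected patients' *hospital* visits (ED + inpatient, from an
all-payer registry) occurring in-system during a follow-up window:

$$\text{fulfilling %} = \frac{n_0}{m_0} \times 100, \qquad
  \text{in-system %} = \frac{n_1}{m_1} \times 100 \;(6\text{mo}),\;
  \frac{n_2}{m_2} \times 100 \;(12\text{mo}),$$

with per-hospital variants $n_3/m_1$ and $n_4/m_2$. Hospital visits are
used because an average hospital visit costs far more than any other
encounter type, so this share proxies the share of total care.

## Cohort and subgroups

The cohort is every patient with at least one in-system visit of any type
in the cohort year, aged $\ge 18$, and not recorded dead in the cohort
year or earlier (a death predating the cohort year is read as "not alive
at index"; the source material only addresses deaths during the year).
Age is computed at the index date — January 1 following the cohort year —
because the index date is stated explicitly while the age-reference
convention is not; it is configurable.

Five chronic-disease subgroups are computed with published rule-based
phenotypes over the look-back span (2011–2018 analog):

* **Asthma** — $\ge 1$ asthma diagnosis code (ICD-9 493.0x/.1x/.8x/.9x;
  ICD-10 J45.x) dated in the cohort year.
* **CKD** — two CKD-range measurements $\ge 3$ calendar months apart,
  each either an MDRD eGFR $< 60$ mL/min/1.73m² computed from a serum
  creatinine row ($175 \cdot \text{age}^{-0.203} \cdot
  \text{SCr}^{-1.154} \cdot 0.742_{[\text{female}]} \cdot
  1.212_{[\text{Black}]}$) or a urine-protein dipstick $\ge 1+$.
* **COPD** — age $\ge 40$ at index and any of: (1) outpatient COPD dx
  followed by a long-acting muscarinic antagonist within 6 months; (2)
  $\ge 1$ ED dx **or** $\ge 2$ outpatient dx; (3) inpatient principal dx;
  (4) inpatient principal respiratory-failure dx with a secondary
  acute-exacerbation dx on the same stay.
* **Diabetes** (Nichols-style) — $\ge 1$ inpatient diabetes dx, or any two
  of {HbA1c $\ge 6.5$%, random glucose $\ge 200$, fasting glucose
  $\ge 126$, outpatient diabetes dx, antihyperglycemic prescription}
  within 2 years, one event per (type, day), events during pregnancy
  excluded, and a metformin/thiazolidinedione-only prescription pair never
  qualifying on its own.
* **Type 1 vs type 2** (Klompas-style) — type 1 if (T1D code count >
  T2D count and glucagon prescribed), or (T1D count > T2D count and no
  oral hypoglycemic beyond metformin), or a negative C-peptide, or a
  positive diabetes autoantibody; otherwise type 2. Counts use all rows of
  the full span.

### Interpretation choices the rules leave open

These are decided once, documented here, and (where sensible) exposed as
configuration:

* **CKD window** — the narrative mentions the cohort year, but chronicity
  needs a 3-month separation that a 1-year window needlessly constrains;
  default is the full span, `ckd_window = "cohort_year"` restores the
  narrow reading.
* **CKD mixed pairs** — the defining sentence reads as a disjunction over
  measurement type, so one low eGFR plus one dipstick $\ge 3$ months apart
  qualifies by default (`ckd_mixed_pairs = FALSE` for strict same-type).
* **Klompas counting** — diagnosis *rows* are counted (literal reading of
  "number of codes"); `klompas_counting = "days"` counts distinct dates.
  Ties fail the "greater than" conditions, strictly.
* **COPD condition 2** — read as ($\ge 1$ ED dx) OR ($\ge 2$ outpatient
  dx), each from the COPD set.
* **"Followed by within 6 months"** — prescription date in
  $[\text{dx}, \text{dx} + 6\text{mo}]$, boundaries inclusive.
* **Oral hypoglycemics other than metformin** — {sulfonylurea,
  meglitinide, DPP-4 inhibitor, alpha-glucosidase inhibitor,
  thiazolidinedione}, configurable.
* **Pregnancy exclusion** applies to the five event types only, not to the
  inpatient-dx route (the exclusion sentence is attached to the event
  list).
* All "within *k* months/years" arithmetic is calendar-based: same
  day-of-month, clamped to month end, boundaries inclusive.
* Diagnosis rows without a visit link are treated as outpatient
  (ambulatory default).

## ICD code patterns

Rule code lists use two wildcard notations. A trailing `x` or `*`
(`J45.x`, `J44.*` — the two spellings are synonymous) denotes the stem
itself plus any extension; whether the bare stem (`J45`) was meant to be
included is not decidable from the source lists, so it is included and
documented. An interior `x` in five-character ICD-9 patterns (`250.x2`)
denotes exactly one arbitrary character. Matching is dot- and
case-insensitive (source systems disagree on dot presence); a pattern
only ever matches codes of its own code system. The full vocabulary ships
as `inst/extdata/code_sets.csv` and is editable without code changes.

## Geodesic distance

Distance is the geodesic on the WGS-84 ellipsoid
($a = 6378137$ m, $f = 1/298.257223563$), computed by Vincenty's inverse
iteration (tolerance $10^{-12}$ on the longitude term, 200-iteration cap),
matching the behaviour of the distance routine the original analysis used.
Arguments are canonically ordered first so $d(a,b)$ is bit-identical to
$d(b,a)$. Vincenty's known near-antipodal failure falls back to damped
Gauss–Newton shooting through the series direct solver (several start
azimuths; shortest converged solution kept) and is flagged
`converged = FALSE` — it must not crash cohort selection, though no
realistic home–hospital pair comes near that regime. Threshold comparison
is at full precision with an **inclusive** boundary ("within $d$ km" means
$\le d$); $d$ is exactly the configured kilometre value (the quoted
"8 km (5 miles)" is treated as 8 km). Missing home coordinates or a
missing PCP row make the constraint evaluate `FALSE`, with counts surfaced
in the run manifest rather than silently biasing $n_0$.

The test suite checks the solver against an independent oracle that
integrates the geodesic ODEs with RK4 and Newton-shoots on (azimuth, arc
length); both are cross-checked against values frozen from a
high-precision Karney-algorithm implementation during development.

## Fragmentation metrics

Registry rows are deduplicated exactly (same patient, date, type,
facility); a same-day ED + inpatient pair remains two visits, as both
visit types are counted. Windows are closed date intervals (an endpoint
visit counts); defaults are index → index + 6 months − 1 day and
index → index + 12 months − 1 day. Report percentages are rounded half-up
to 2 decimals — matching how the published table is formatted — with raw
fractions retained alongside; a zero denominator yields a flagged
undefined cell, never a silent 0. The $d$-sweep grid defaults to 0–30 km
by 1 km merged with 0–10 km by 0.5 km (coarse plus fine views); the
fulfilling percentage is nondecreasing in $d$ by construction and this is
asserted at run time. No scalar objective for an "optimal" $d$ exists in
the source analysis (it balances two competing goals qualitatively), so
the package exposes the curves and defaults to $d = 8$ km.

## The synthetic generator: what a green test establishes

No real warehouse or all-payer feed is available, so the generator is a
first-class module producing the *structure* the analysis assumes:

* disease prevalences default to the published population's rates
  (asthma 4.26%, CKD 7.38%, COPD 2.21%, T2D 16.45%, T1D 0.84%); the
  type-1 draw is deflated slightly by the t1d/t2d exclusivity rule, and
  the COPD draw is confined to the $\ge 40$ stratum and upweighted so the
  overall rate is preserved;
* each drawn disease is implanted as minimal rule-satisfying rows via a
  randomly chosen rule branch — the same `implant()` machinery produces
  the branch-coverage fixtures (every clause × {positive, near-miss});
* homes: distance from a mixture of a near-urban log-normal
  (meanlog $\log 6$, sdlog 0.9, weight 0.75) and a far tail (meanlog
  $\log 40$, sdlog 0.6), uniform bearing, coordinates by a direct-geodesic
  step from a random hospital — chosen so that, with
  `pcp_probability = 0.35`, roughly 15–22% of the cohort fulfills the
  constraint at $d = 8$, the published range;
* registry visits: Poisson counts (0.25/patient-year baseline, 1.0 for
  disease-positive patients — matching the ~1 visit/patient-year implied
  by the published subgroup counts), ED:inpatient 60:40, each visit
  in-system with probability
  $\operatorname{logit}^{-1}(0.2 + 1.0 \cdot \text{PCP} - 0.06 \cdot
  \text{km})$. The logistic form is the generator's own invention; only
  its coefficient *signs* are motivated by the source observation that
  in-system share falls with distance and rises with an in-system PCP.
  The defaults put the fulfilling subset at $d = 8$ around 65–75%
  in-system.

The generator does **not** model seasonality, student migration, coding
noise, real geography beyond three configurable hospital coordinates, or
correlated comorbidity. A green acceptance suite therefore establishes
that the pipeline's *counting, selection, geometry and rule logic* are
correct and that the measured metrics recover the generative model's
parameters — not that any real-world percentage is reproduced. Real
headline values live only in the bundled printed-ratio table, which the
arithmetic-parity check recomputes; one cell of that table is internally
inconsistent at source (3194/14,640 printed as 21.81, which recomputes to
21.82; the abstract's 3194/14,644 verifies), and the verifier reports it
as the single expected failure rather than papering over it.

## Numerical notes

* Percentages: half-up rounding (not IEEE round-half-even) at 2 decimals.
* Determinism: one seed drives generation; identical config + seed gives
  byte-identical CSV output; the caller's RNG state is restored.
* Degenerate inputs: empty candidate sets and zero-denominator fractions
  are flagged undefined; an empty hospital set is an error (the constraint
  is meaningless without one).
* Test budgets: simulation sizes in the acceptance suite (5,000-patient
  sweep; 40 × 1,200-patient recovery replicates; 1,000 oracle pairs
  restricted to regional, ≤ ~1,000 km separations — the study's spatial
  domain) were chosen to keep the suite inside a few minutes on one CPU;
  the properties checked are scale-free.

## Known limitations

* Phenotype rules are implemented as published, not validated against
  chart review; no severity staging.
* The registry stand-in has complete facility attribution; real all-payer
  feeds have mapping noise.
* `classify_diabetes_type()` inherits Nichols-rule diabetes as its
  precondition; gestational diabetes is handled only via the event
  exclusion.
* Drive-time or network distance — arguably more clinically relevant than
  geodesic distance — is out of scope, as in the source analysis.
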