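# carefrag

Care-fragmentation analysis of chronic-disease cohorts under a
distance-parameterized primary-care constraint.

## The problem

A patient's health care is typically split across several unaffiliated
health care systems, so no single system holds a complete record. That
*care fragmentation* blocks the cost-prediction models that drive care
management for chronic disease, because those models assume complete
history. A practical way out: restrict modelling to patients who are apt
to obtain care mostly in-system. carefrag implements, end to end on
EHR-style relational tables, the selection rule

> the patient has an in-system primary care physician (PCP) **and**
> resides within *d* km (WGS-84 geodesic) of at least one in-system
> hospital,

and evaluates it on five rule-based chronic-disease subgroups — asthma,
chronic kidney disease (via the MDRD eGFR equation
`175 · age^-0.203 · SCr^-1.154 · 0.742[female] · 1.212[Black]`), COPD,
and type 1 / type 2 diabetes (Nichols + Klompas rules) — by measuring,
from an all-payer hospital-visit registry,

```
fulfilling % = n0/m0 · 100        (subgroup patients fulfilling the constraint)
in-system %  = n1/m1 · 100 (6 mo),  n2/m2 · 100 (12 mo)
```

the share of the selected patients' hospital visits (ED + inpatient) that
occur in-system, over 6- and 12-month follow-up windows and a sweep of
*d*. A synthetic EHR + registry generator (log-normal home-distance
mixture; in-system visit probability `logistic(b0 + b_pcp·PCP +
b_dist·km)`) makes every stage reproducible with no data access.

## Worked example

```r
library(carefrag)
res <- run_study(study_config(n_patients = 5000, seed = 7),
                 output_dir = "demo_run")
res$report[, .(subgroup, n0, m0, fulfilling_pct, pct_all_12m, pct_ful_12m)]
#>    subgroup    n0    m0 fulfilling_pct pct_all_12m pct_ful_12m
#> 1:   asthma    39   199          19.60       41.29       71.43
#> 2:      ckd    72   401          17.96       43.89       71.64
#> 3:     copd    23    96          23.96       40.43       64.00
#> 4:      t1d     8    36          22.22       50.00       71.43
#> 5:      t2d   151   812          18.60       43.76       70.27
```

Reading the asthma row: 199 cohort patients carry the asthma phenotype;
39 of them (19.60%) have an in-system PCP and live within the default
d = 8 km of an in-system hospital. Over the 12-month follow-up, 41.29% of
*all* asthma patients' hospital visits were in-system, but 71.43% for the
selected subset — the constraint roughly doubles in-system share, the
pattern the method is designed to produce. The sweep shows the trade-off
in d:

```r
res$sweep[d_km %in% c(1, 4, 8, 16, 30),
          .(d_km, fulfilling_pct, pct_6m, pct_12m)]
#>     d_km fulfilling_pct   pct_6m  pct_12m
#> 1:     1       0.945335 71.42857 72.41379
#> 2:     4      11.344020 70.63492 72.04724
#> 3:     8      19.153309 72.76995 70.84282
#> 4:    16      25.195232 67.71930 67.82609
#> 5:    30      29.901356 63.71951 63.97608
```

The fulfilling percentage rises steeply then flattens; the in-system
percentage drifts down as farther-living patients enter. There is no
scalar optimum — `d = 8` km is the conventional balance point and the
default. `run_study()` also writes `labels.csv`, `sweep_curves.csv`,
`per_hospital.csv` and a JSON run manifest (config hash, warning counts,
output checksums) to the output directory, and is byte-reproducible under
a fixed seed.

Lower-level entry points: `generate_ehr()` / `load_dataset()` /
`write_dataset()`, `filter_cohort()`, `label_all()` and the per-disease
`detect_*()` functions, `vincenty_inverse()` / `vincenty_direct()`,
`select_subcohort()`, `fragmentation()`, `sweep_constraint()`,
`per_hospital_report()`, `fixture_suite()` and `verify_paper_arithmetic()`.
See the methods vignette (`vignettes/care-fragmentation-methods.Rmd`) for
the model, its assumptions, and every interpretation choice.

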