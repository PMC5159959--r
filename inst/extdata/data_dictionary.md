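# Data dictionary

## risk_registry.yaml

The 14 dietary risk factors of the GBD 2013 comparative risk assessment
(eight food types, five nutrients, and fibre), as a loadable registry.
Fields per risk:

- `name` — unique risk identifier.
- `direction` — `harmful_low` ("diet low in X": risk rises as intake falls
  below the optimum) or `harmful_high` ("diet high in X").
- `exposure_unit` — unit of the exposure scale (g/day, % of daily energy,
  g/day urinary sodium equivalent).
- `mediator` — `none` for directly quantified diet-disease effects; `sbp`
  (systolic blood pressure) for sodium and `bmi` (body mass index) for
  sugar-sweetened beverages, whose effects are composed through a two-stage
  chain.
- `category` — food / nutrient / fibre grouping.

## ethiopia_reported_burden.tsv

Published diet-attributable burden figures for Ethiopia from the GBD 2013
comparative risk assessment, used as inputs to the report-arithmetic
operations (percentage change between 1990 and 2013, shares of all-cause,
NCD and CVD burden). Columns:

- `series` — what the value is: `count` (attributable persons or
  person-years), `rate` (per 100,000), `proportion_all` (% of all-cause
  burden), `rate_fruit_dalys` (DALY rate attributable to low fruit intake),
  `count_cvd_total` (all CVD deaths), `count_cvd_diet` (diet-attributable
  CVD deaths), `count_diet_total` (all diet-attributable deaths).
- `metric` — deaths, dalys, ylls or ylds.
- `year` — 1990 or 2013.
- `value` — the published value, unrounded exactly as printed.

## World bundle files (written by `write_world()`)

- `hierarchy.tsv` — `name`, `level` (global/super_region/region/country),
  `parent` edge list; exactly one global root.
- `surveys.tsv` — one row per survey stratum: `risk`, `location`, `level`,
  `sex`, `age_group`, `age_lower`, `age_upper`, `year`, `reported_mean`,
  `standard_error`, `sample_size`, `mean_energy` (kcal/day).
- `relative_risks.tsv` — per diet-disease pair: `log_rr_per_unit`, `rr_se`
  (direct risks) or `slope`, `slope_se`, `mediator_log_rr_per_unit`,
  `mediator_se` (mediated risks).
- `tmrel.yaml` — optimal intake per risk; the uncertainty interval is
  uniform on [0.8, 1.2] x optimal by construction.
- `envelopes.tsv` — cause-specific burden envelopes: `outcome`, `group`
  (`specific`, `all_ncd`, `all_cause`), `metric`, stratum columns, `count`,
  `population`.
- `truth_exposure.tsv`, `truth_paf.tsv` — generator ground truth (true
  stratum means/sds; exact quadrature PAFs from the true parameters).
- `config.yaml`, `risk_params.tsv`, `manifest.tsv` — world configuration,
  risk parameters, and per-file MD5 checksums.
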