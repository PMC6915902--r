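# Bundled data files

## Synthetic clock stand-ins

`horvath2013_synthetic_coefficients.csv` and
`hannum2013_synthetic_coefficients.csv` are **synthetic stand-in**
coefficient tables, not the published clock coefficients (those are
third-party supplementary data and are not redistributed here). They
reproduce the documented *structure* of the two clocks so that every code
path behaves as it would with the real tables:

- 353 and 71 probe coefficients respectively, plus an `(Intercept)` row;
- a probe-set intersection of exactly 6 ids, including cg22736354 and
  cg06493994;
- absolute multi-tissue coefficients spanning 5.9e-6 to 3.07;
- the named high-influence probe ids (cg12830694, cg24580001, cg02580606
  with positive weights; cg08090772, cg03019000, cg04268405) present.

All other ids and coefficient values are random draws from a seeded
generator (`scratch/make_clock_assets.R` in the source tree). For real
analyses, pass the published coefficient CSVs to
`read_clock_definition()` instead.

## Toy fixtures

`toy_clock.csv`, `toy_betas.csv`, `toy_metadata.csv`: a 2-probe clock and
a 3-sample cohort for quick command-line smoke runs.
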