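# Demo pipeline configuration: two synthetic lakes (one seasonally salty
# "gradient" lake, one freshwater "stable" lake), monthly sampling at two
# depths and two size fractions. Null-model and bootstrap replicate counts are
# kept small so the demo finishes in minutes; raise n_null to 999 and the
# bootstrap counts to 1000 for production-scale inference.
seed: 42
simulate:
  n_taxa: 150
  reads_per_sample: 1500
  turnover: 0.2
  salinity_amplitude: 8
  months: 10
  start_date: 2021-05-01
  depths_m: [2, 15]
  fractions: [PA, FL]
  lakes:
    - name: gradientlake
      regime: gradient
    - name: stablelake
      regime: stable
ncm:
  n_bootstrap: 200
nullmodels:
  n_null: 199
  group_by: [lake, fraction]
stability:
  method: bray
plspm:
  n_bootstrap: 199
  per_lake: true
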