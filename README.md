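# reefheat

Phenotyping pipeline for standardized coral heat-stress (bleaching) assays.

Reef corals vary enormously in how well they tolerate marine heat waves, and
mapping that variation is the first step of any conservation or assisted-gene-
flow program. A practical field protocol tags colonies across many reefs,
subjects nubbins of each colony to a short standardized heat ramp (ambient
30 °C to 34–35 °C targets over two days), and quantifies bleaching as the loss
of algal endosymbionts, counted by flow cytometry. `reefheat` implements the
full analysis chain for that protocol, for coral ecophysiologists and anyone
re-analysing such assays:

* **cytometry gating** — classify events into symbiont-containing cells
  (chlorophyll fluorescence above threshold), symbiont-free coral cells
  (large forward scatter), and debris; estimate per-sample **symbiont load**
  `s/(s+c)` and aggregate measurement triplicates;
* **retention scoring** — a colony's bleaching resistance is
  `mean(heated-nubbin loads) / mean(control-nubbin loads)`, with the top
  quartile classified resistant (linear-interpolation percentile);
* **thermal exposure** — per-reef counts of 10-minute logger intervals
  strictly above 31–35 °C thresholds, averaged over loggers;
* **growth** — annual linear extension and percent growth from repeat
  diameter surveys, with decreases exceeding 10 % excluded as damage;
* **statistics** — Spearman rank correlation via the S statistic, OLS with
  R², one-way ANOVA, within/between-reef variance decomposition, and a
  from-scratch implementation of **Hartigan's dip test** of unimodality with
  a seeded Monte-Carlo null (`p = (1 + #{D_b ≥ D}) / (B + 1)` over uniform
  null samples);
* **simulators** — seeded generators for cytometry event clouds, colony
  phenotype populations (bimodal Beta-mixture loads, weak negative
  load→retention and positive load→growth couplings), and spiked
  temperature-logger series, all returning ground truth for recovery tests.

The central quantities, in the field's notation: load
`L = n_symb/(n_symb + n_coral)`; retention `R = L̄_heated / L̄_control`;
dip statistic `D = min_G sup_x |F_n(x) − G(x)|` over unimodal CDFs `G`;
exceedance `E_T = #{t : temp(t) > T}`.

## Worked example

Simulate a default survey (221 colonies on 37 reefs, triplicate cytometry at
1,000 events per replicate, spiked logger series) and run the pipeline
(about half a minute):

```r
library(reefheat)
ds  <- simulate_dataset(cyto = cytometry_sim_params(n_events = 1000),
                        spikes = spike_params(n_spikes = 10), seed = 42)
res <- run_pipeline(pipeline_config(dataset = ds, dip_B = 1999, seed = 42))

res$stats$dip
#> Dip test: D = 0.04132, p = 0.007 (n = 221, B = 1999 Monte-Carlo nulls)
res$stats$load_retention_ols
#> OLS fit: n = 221, R^2 = 0.0912, F = 21.965, p = 4.878e-06
#>             estimate      se        t p
#> (Intercept)  0.97277 0.08108 11.99738 0
#> load        -3.25150 0.69378 -4.68668 0
res$contrast
#> Quartile contrast (groups of 55):
#>          control_load heated_load retention depth_m above_31 above_32
#> top25          0.0831      0.1171    1.4307  1.0856  58.5818  58.5818
#> bottom25       0.1210      0.0003    0.0024  1.0944  56.8364  56.8364
```

Reading this: control loads are bimodal (dip test rejects unimodality,
p = 0.007); colonies that started with *lower* symbiont loads retained more
of them under heat (negative load coefficient, R² ≈ 0.09 — the generator's
calibrated weak-coupling regime); the most resistant quartile held
essentially all its symbionts (mean retention 1.43) while the most
susceptible quartile bleached to nearly zero (0.002). In this run 31 of 37
reefs harboured at least one resistant colony, and the recovered retentions
correlate > 0.98 with the simulator's latent truth.

A shell interface wraps the same pipeline:

```sh
exec/reefheat simulate --config cfg.yaml --out data/   # write a dataset bundle
exec/reefheat run --input data/ --out results/         # gate → thermal → score → stats
exec/reefheat simulate --show-defaults                 # print every simulator default
```

`run` writes `colony_scores.csv`, `reef_thermal.csv`, `quartile_contrast.csv`,
`stats.json`, a GeoJSON `reefs.geojson` of per-reef resistance fractions, and
a `run_manifest.json` carrying the seed and config hash (reruns with the same
seed are bit-identical).

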