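# isletca

Analysis of pancreatic-islet Ca²⁺ imaging at single-cell resolution: from
per-ROI fluorescence traces to global islet dynamics and functional
beta-cell subpopulations.

Islets expressing a genetically encoded Ca²⁺ indicator (e.g. GCaMP6f in
beta-cells) respond to a glucose ramp (3 → 11 → 25 mM, then KCl) in two
phases: a large initial Ca²⁺ peak, then steady-state Ca²⁺ waves. `isletca`
quantifies both and classifies the cells that orchestrate them. It is aimed
at islet physiologists who already extract traces with ImageJ's
"Multi Measure" and want a reproducible, scriptable replacement for the
usual ad-hoc spreadsheet/MATLAB steps.

**Global metrics** (on the islet trace, fold change `(F − F_min)/F_min`
over the 3 mM baseline):

* AUC of each phase, both the "apparent" sum `Σ F_i` and the trapezoid rule
  `Σ (F_i + F_{i+1})/2 · Δt`;
* first-phase amplitude, activation time FP-T₂₀ (first 20% rise after the
  11 mM step) and width;
* second-phase wave frequency, mean amplitude and mean width, from a double
  threshold (fold change > 0.2 sustained ≥ 2 s) applied after detrending
  with a piecewise-linear **adaptive baseline** through filtered signal
  valleys.

**Subpopulations** (KCl-unresponsive cells excluded first):

* **first-responders** — the 10% of cells with the fastest normalized
  first-phase activation (FR-T₂₀);
* **hubs** — from binarized activity, pairwise coactivity
  `C_ij = T_ij/√(T_i·T_j)` with a circular-shift shuffle null
  (significant if observed > null mean + 2 SD); hubs by the strong-connection
  criterion (≥80% of significant partners with C ≥ 0.8) and/or the top-10%
  best-connected rule. Also the islet connectivity score `C_islet`
  (mean off-diagonal coactivity) and its low/medium/high class;
* **leaders** — cells whose mean per-wave activation latency (SCSP-T₂₀ per
  wave window, rescaled per wave) is at or below the 10th percentile.

A seeded synthetic-islet generator with planted ground truth
(`simulate_islet()`, presets `clean`, `noisy`, `drifting`,
`no_heterogeneity`) makes every stage testable without imaging data.

## Worked example

```r
library(isletca)

sim <- simulate_islet(islet_preset("clean", rng_seed = 1))
res <- run_islet_analysis(sim, config = run_config(n_shuffles = 1000,
                                                   rng_seed = 1))
res
#> <islet_analysis> 50 cells (50 KCl-responsive), 53 second-phase waves
#>   first phase : T20 160.0 s, amplitude 3.01, width 466.0 s
#>   second phase: 2.41 waves/min, mean amplitude 0.79, mean width 14.7 s
#>   connectivity: c_islet 0.753 (high)
#>   labels: 5 first-responders, 5 leaders, 10 criterion hubs, 5 top-10% hubs
```

Reading the output: the islet activated 160 s after the 11 mM glucose step
and the first-phase peak reached a 3.0-fold change; during the 25 mM phase
it fired 53 waves (2.41 waves/min) of mean amplitude 0.79 over the local
baseline; the mean pairwise coactivity of 0.753 classifies the islet as
highly connected. The per-cell table is a tibble:

```r
head(tidy(res), 5)
#> # A tibble: 5 × 12
#>   cell_id  included fr_t20_s mean_scsp_t20_s is_first_responder is_leader ...
#> 1 cell_001 TRUE         158             6.18 TRUE               FALSE
#> 2 cell_002 TRUE         239             5.69 FALSE              FALSE
#> 3 cell_003 TRUE         262.            6.11 FALSE              FALSE
#> 4 cell_004 TRUE         172.            5.47 TRUE               FALSE
#> 5 cell_005 TRUE         237             6.09 FALSE              FALSE
```

and the labels recover the simulation's planted truth exactly
(`sim$truth$first_responders` is `cell_001, cell_004, cell_023, cell_034,
cell_039` — the five cells flagged `is_first_responder`). `glance(res)`
returns the one-row global summary, `autoplot(res, type = "trace")`,
`"raster"`, `"coactivity"`, `"network"` and `"latency"` draw the standard
figures, and `write_results(res, "outdir")` writes the diffable CSV/JSON
file set.

For recordings on disk:

```r
run_full_analysis("traces.csv", "timeline.json", "centroids.csv",
                  outdir = "results", islet_roi_first = TRUE)
```

or from a shell via the bundled CLI
(`Rscript inst/cli/isletca.R analyze --traces traces.csv
--timeline timeline.json --centroids centroids.csv --outdir results`;
`simulate` and `report` subcommands included).

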