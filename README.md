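# dnbtip

Dynamic network biomarker (DNB) detection of critical transitions in
replicated time-course expression data.

Biological systems often switch states abruptly — a tumour becoming
metastatic, a cell committing to a fate. Just before such a transition, a
small group of genes (the DNB) shows a characteristic signature: its
within-group fluctuation and correlation rise sharply while its
correlation with everything else falls. dnbtip finds that group and the
timepoint at which the system sits at the tipping point, and runs the
surrounding analysis a time-course study needs: differential expression
across timepoint contrasts, fuzzy clustering of temporal patterns,
permutation significance for the detected module, and correlation-network
analysis linking the module to its protein–protein interaction (PPI)
neighbors and to user-supplied gene sets.

It is aimed at analysts with replicated expression time courses (a few
timepoints, few replicates, e.g. 4–5 × n = 3) who want an auditable,
deterministic implementation of the DNB workflow plus a simulator with
planted ground truth for benchmarking it.

## The statistic

For a candidate module at timepoint *t*, with that timepoint's replicates
as the sample space:

- **SD_in(t)** — mean per-gene replicate standard deviation inside the module
- **PCC_in(t)** — mean |Pearson r| over within-module gene pairs
- **PCC_out(t)** — mean |Pearson r| over module × background pairs

combined into the criticality index

    CI(t) = size · PCC_in(t) · SD_in(t) / (PCC_out(t) + ε)

whose peak across timepoints locates the tipping point. `dnb_detect()`
searches candidate modules (correlation clustering over pooled samples),
scores every candidate at every timepoint, refines the winner, and
returns a classed model object with `print`, `summary`, `plot`, and
`coef` methods plus an optional permutation p-value.

## Worked example

```r
library(dnbtip)

sim <- simulate_critical_transition(simulation_config(mean_shift = 2, seed = 42))
fit <- dnb_detect(sim$series, n_permutations = 1000, seed = 42)
summary(fit)
```

```
DNB fit: 19-gene module, tipping point at T3 (CI = 51.497)
criteria met: sd_in_increased, pcc_in_increased
permutation p = 0.000999

per-timepoint statistics:
 timepoint  sd_in pcc_in pcc_out size     ci
        T1 0.5115 0.6259  0.6421   19  9.474
        T2 0.5705 0.6419  0.6383   19 10.900
        T3 1.9445 0.9568  0.6864   19 51.497
        T4 0.5564 0.6243  0.6316   19 10.449
        T5 0.4199 0.7022  0.6123   19  9.151
```

The simulation planted a 20-gene module whose latent-factor SD jumps from
0.2 to 2.0 at the third of five timepoints. The fit recovers 19 of the 20
planted genes and places the tipping point at T3: SD_in quadruples and
PCC_in jumps from the n = 3 correlation noise floor (≈ 2/π ≈ 0.64) to
0.96 exactly there, so CI peaks at 51.5 against ≈ 10 elsewhere, and none
of 1000 random same-size modules score as high (p ≈ 0.001).
`plot(fit)` draws the CI profile with the tipping point marked.

The full pipeline — DEG tables, temporal clusters, DNB search,
PPI-neighbor/metastasis intersections, correlation networks, and a ranked
module-gene table, all written to a results directory with a run log —
runs from one config:

```r
paths <- make_demo("demo_inputs")            # simulated inputs + truth manifest
cfg <- pipeline_config(
  expression = paths[["expression"]], metadata = paths[["metadata"]],
  ppi_edges = paths[["ppi_edges"]], metastasis_gmt = paths[["metastasis_gmt"]],
  pathway_gmt = paths[["pathway_gmt"]], out_dir = "demo_results", seed = 1)
run_pipeline(cfg)
```

A thin command-line wrapper lives at `inst/scripts/dnbtip.R`
(`simulate`, `run`, `print-config` subcommands).

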