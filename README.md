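# seqreg — sequential transcriptional activity from time-series RNA-seq

When a transcription factor (TF) switches on, its target genes respond
some time later. `seqreg` takes a short RNA-seq time course (genes ×
sampling hours, raw counts) together with a curated table of
regulator→target relations — for *E. coli*, typically a RegulonDB-style
network file — and estimates, for every regulatory pair, the lag between
regulator and target expression and the pair of activation times: the
hour `t_a` at which the regulator initiated the event and the hour `t_b`
at which the target responded. The timed pairs are assembled into a
directed temporal network (self-loops allowed) with per-hour activity
snapshots and GraphML/JSON export. It is aimed at experiments like a
growth-to-stationary-phase transition sampled at 3, 4, 5, 6 and 8 h with
a few biological replicates, each analysed separately.

## Method in brief

1. **Normalize**: median-of-ratios size factors
   (`s_j = median_g k_gj / geomean_j' k_gj'`, over genes with
   all-positive counts), then `log2(count/s_j + 1)`; genes never
   expressed are dropped.
2. **Lag per pair**: the cross-correlation

   ```
   r_ab(h) = Σ_{0 ≤ i+h < N} (a_{i+h} − ā)(b_i − b̄)
             / sqrt(Σ (a_i − ā)² · Σ (b_i − b̄)²)
   ```

   is maximized in absolute value over integer index shifts h ∈ −3…3
   (the regulator series carries the shift). Pairs with 0 < h ≤ 3 —
   target apparently preceding regulator — are discarded; the retained
   band is −3 ≤ h ≤ 0.
3. **Activation times**: per gene, adjacent-interval changes
   `d_v(i,j) = v(j) − v(i)`; the matrix `M[p,q] = d_a(p) − d_b(q)`
   (regulator rows, target columns) is scanned over the eligible entries
   (`t_b ≥ t_a`) for the smallest |M|, whose row/column start hours give
   `(t_a, t_b)`.
4. **Tabulate and assemble**: a frequency table of `(t_a, t_b)`
   combinations and a timed directed network, edges active over
   `[t_a, t_b]`.

A seeded synthetic-data generator (`simulation_spec()` /
`simulate_dataset()`) produces counts tables with implanted lags and
activation times plus a truth table, so the whole pipeline is testable
without any external download; `score_recovery()` grades results against
the truth.

## Worked example

```r
library(seqreg)
sim <- simulate_dataset(simulation_spec(n_regulators = 5, seed = 42))
fit <- seqreg(sim$counts, sim$pairs)
fit
#> Sequential transcriptional activity fit
#>   sample: 'sim', 330 genes on grid 3, 4, 5, 6, 8 h
#>   pairs: 25 in, 25 analysable, 25 retained (lag band -3..0), 25 time-assigned
#>   network: 30 vertices, 25 edges

head(fit$assignments, 4)
#>   regulator target  h         r t_a t_b     m_value
#> 1     tf001 g001_1 -3 0.6034855   3   6  0.33448023
#> 2     tf001 g001_2 -1 0.6861043   3   4 -0.25367710
#> 3     tf001 g001_3 -1 0.6973699   3   4 -0.05008796
#> 4     tf001 g001_4  0 0.7618543   3   3  0.28259485

fit$freq_table
#> Frequency of activation times (rows: target t_b, columns: regulator t_a)
#>      3 4 5 6 Sum
#> 3    5 0 0 0   5
#> 4    5 3 0 0   8
#> 5    5 1 0 0   6
#> 6    5 1 0 0   6
#> Sum 20 5 0 0  25
```

Reading the output: every pair of the simulated regulon was retained
(lags all in the −3…0 band). The first pair responds three sampling
intervals after its regulator (`h = -3`), with the regulator initiating
in the interval starting at 3 h and the target in the one starting at
6 h. The frequency table fills only where `t_b ≥ t_a` — a target never
responds before its regulator. Against the generator's truth table:

```r
score_recovery(sim$truth, fit$lags, fit$assignments)
#> recovery over 25 pairs: lag 96.0%, activation times 100.0%
```

`export_network(fit$network, "net.graphml")` writes the temporal network
with `t_a`/`t_b` on the edges; `snapshot(fit$network, 5)` flags what is
active at 5 h; `plot(fit)` draws one panel per grid hour.

For a multi-sample study use `run_pipeline(pipeline_config(...))`, which
analyses each biological sample independently and writes per-sample lag
tables, assignments, frequency tables, networks and a JSON run log.

## Scope

Per-sample analysis only (no consensus network is computed — a shared
edge list across samples is reported as a convenience); no significance
testing; gene matching is exact case-folded names, with TF complexes and
operon resolution out of scope. The methods vignette
(`vignettes/sequential-activity.Rmd`) documents the model, the
conventions (shift direction, eligibility, tie-breaking) and the design
of the synthetic benchmark, including what passing it does and does not
demonstrate.
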