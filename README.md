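# burstscape

Model-based analysis of transcriptional uncertainty in single-cell
expression data.

During differentiation, cells pass through transition states whose gene
expression is unusually heterogeneous. burstscape quantifies this with a
mechanistic model: every gene in every cell state is described by the
two-state (telegraph) model of transcription, in which a promoter
switches OFF→ON at rate θ<sub>on</sub>, ON→OFF at rate θ<sub>off</sub>,
transcribes at rate θ<sub>t</sub> while ON, and mRNA degrades at rate
θ<sub>d</sub> ≡ 1 (all rates per mRNA lifetime). The stationary mRNA
count is Poisson–Beta: m ~ Poisson(θ<sub>t</sub>·p) with
p ~ Beta(θ<sub>on</sub>, θ<sub>off</sub>). Transcriptional bursts are
summarized by the burst size S = θ<sub>t</sub>/θ<sub>off</sub> and burst
frequency F = θ<sub>on</sub>.

A cell's **transcriptional uncertainty** is the negative log-likelihood
(NLL) of its counts, NLL<sub>n</sub> = Σ<sub>g</sub> NLL<sub>g,n</sub>,
under per-(gene, cluster) telegraph parameters fitted by grid maximum
likelihood — high NLL marks high-entropy, heterogeneous cell states. On
top of this the package provides:

* likelihood-greedy **consensus clustering** of cells (with eigengap
  selection of K and k-medoids finalization);
* **lineage inference** from likelihood-based cluster distances, cell
  placement on lineage edges by distribution interpolation, and
  **pseudotime**;
* per-cell and per-gene NLL summaries: moving-average NLL along lineage
  paths, high-uncertainty gene calls (mean + 3 SD rule), and the
  **uncertainty landscape** — NLL fitted on a regular 30×30 grid over a
  2-D PCA embedding;
* correlation of cluster-averaged NLL with **burst size/frequency**
  (Pearson r with the t = r·√((n−2)/(1−r²)) score), and a lagged
  comparison of **RNA-velocity magnitude** against NLL along pseudotime;
* a **synthetic lineage generator** with full ground truth (telegraph
  parameters, labels, pseudotime, planted burst inflation, velocity
  lead) for end-to-end validation.

## Worked example

Simulate a bifurcating lineage (5 clusters — one burst-inflated
transition state at the branch point — 100 cells each, 60 genes) and run
the full pipeline:

```r
library(burstscape)

sc  <- preset_scenarios(seed = 1)[["bifurcation-5"]]
dat <- generate_lineage_data(sc)

res <- run_pipeline(dat$expression, out_dir = "bif5_run",
                    config = list(seed = 1, cluster.k = 5,
                                  cluster.n_runs = 8,
                                  grid.theta_on_min = 0.01,
                                  grid.theta_on_max = 10,
                                  grid.theta_on_n = 12,
                                  grid.theta_off_min = 0.1,
                                  grid.theta_off_n = 12,
                                  grid.theta_t_n = 18,
                                  grid.m_max = 150),
                    velocity = dat$velocity)

res$clustering
#> telegraph clustering: 500 cells in 5 clusters, total log-likelihood -59896.77
#> cluster
#>   1   2   3   4   5
#> 100 100  99 101 100

res$graph
#> lineage graph: 5 clusters, root 1
#>  k1 k2 distance
#>   1  2 5.883140
#>   3  4 6.331651
#>   2  3 6.645849
#>   3  5 7.026910

res$correlations
#>          variable         r   n        t            p significant
#> 1 burst_frequency 0.1961421 300 3.453011 6.346841e-04        TRUE
#> 2      burst_size 0.4222159 300 8.040391 2.125367e-14        TRUE

res$velocity_lag$best_lag
#> [1] 4
```

Reading the output: the clustering recovers the five planted populations
(ARI ≈ 0.99 against the ground truth in `dat$truth$labels`); the lineage
edges 1–2, 2–3, 3–4, 3–5 reproduce the planted topology with the branch
at cluster 3; cluster-averaged gene NLL correlates positively and
significantly with both burst frequency and burst size over the 300
(gene, cluster) pairs; and the velocity magnitude leads the NLL rise by
4 of 20 pseudotime bins — one cluster, the planted lead. `bif5_run/`
contains every table as CSV (labels, fitted parameters, lineage edges,
placements with pseudotime and NLL, moving-average NLL per path,
high-uncertainty genes, embedding, 30×30 landscape grid, correlations,
velocity summary) plus a manifest with the configuration and checksums.

## Package layout

| | |
|---|---|
| `R/telegraph.R` | stationary PMF (Gauss–Jacobi quadrature), sampler, grid MLE, burst metrics |
| `R/preprocess.R`, `R/io.R` | normalization, filters, variable genes; readers/writers, config |
| `R/cluster.R` | greedy likelihood clustering, consensus, k-medoids, eigengap |
| `R/lineage.R` | cluster distances, lineage graph, cell placement, pseudotime |
| `R/uncertainty.R` | NLL summaries, moving averages, high-uncertainty genes, landscape |
| `R/burst-stats.R` | burst/velocity correlation machinery |
| `R/synthetic.R` | scenario presets and the lineage data generator |
| `R/pipeline.R` | `run_pipeline()` orchestration and output bundle |
| `src/telegraph.cpp` | PMF recurrences, Gillespie simulator, likelihood kernels |

The methods vignette (`vignettes/uncertainty-landscapes.Rmd`) documents
the model, the numerical choices, the generator design and its
limitations.
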