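# dcovnet

Directed functional connectivity from haemodynamic time series via
differential covariance.

## The problem

Resting-state fMRI yields one BOLD time trace per brain region (or ICA
component).  Most functional-connectivity (FC) estimators — covariance,
partial covariance, their regularized versions — are *symmetric*: they
cannot say which region drives which, and they accumulate false
positive edges through common-input and chain effects.  **Differential
covariance (dCov)** treats the recording as a linear dynamical system
`dV/dt = W V + noise` and estimates directed influence from the
covariance between one node's temporal *derivative* (its input, the
"sink" side) and another node's *signal* (its output, the "source"
side):

```
Δc[i, j] = cov(dz_i, z_j)                       (raw dCov; row = sink)
Δp[i, j] = Δc[i, j] − Cov[j, K] Cov[K, K]⁻¹ Δc[i, K]ᵀ   (partialled on K = all other nodes)
Δp       = Δs + L,   Δs = argmin ‖Δs‖₁ + α‖L‖_*          (sparse + low-rank split)
```

For a stationary linear system `Δc ≈ W Σ` is close to antisymmetric and
its support tracks the true wiring `W`, so thresholded dCov networks
match structural connectivity better than covariance-based ones.

`dcovnet` implements the full analysis chain for this approach:

* **Synthetic ground truth** — sparse stable networks, Euler–Maruyama
  linear neural dynamics, a four-state Balloon–Windkessel haemodynamic
  forward model (RK4), TR downsampling, surrogate structural
  connectomes (ordinal 1–7 "tracing" scale or symmetric "dMRI" scale)
  and surrogate behaviour tables.
* **Backward reconstruction** — inversion of the linearized Balloon
  model, `z = p₄y⁽⁴⁾ + p₃y⁽³⁾ + p₂ÿ + p₁ẏ + p₀y`, recovering a
  surrogate neural signal `z = q₁V̇ + q₀V` from BOLD.
* **Seven FC estimators** — `cov`, `pcov`, `l1reg`, `l2reg`,
  `cgranger` (conditional Granger causality with χ² p-values),
  `dcov_c`, `dcov_p`, `dcov_s`.
* **Edge significance** — node-wise AR bootstrap (BIC-by-2 order rule),
  Gaussian per-edge null, two-sided p-values, threshold binarization
  and sparsity matching.
* **FC–SC comparison** — structural-connectivity-strength (SCS) pooling
  across subjects and the ASCS curve over binarization thresholds.
* **Graph topology** — degrees, BFS shortest paths, triangles, global
  and local efficiency, clustering, transitivity, modularity with a
  greedy partition search, for directed and undirected binary graphs.
* **Behaviour linkage** — confound regression of a per-subject network
  statistic and significance-ranked correlations with behavioural
  measures.

## Worked example

```r
library(dcovnet)

net <- generate_network(n_nodes = 10, density = 0.2, seed = 1)  # ground truth
V   <- simulate_neural(net, T = 50000, dt = 0.01, seed = 2)     # neural traces
y   <- downsample(balloon_forward(V), TR = 0.5)                 # BOLD at TR = 0.5 s
z   <- backward_reconstruct(y)                                  # surrogate neural signal
z
#> <dcov_ts> 10 nodes x 992 samples, dt = 0.5 s, kind = reconstructed

sig <- ar_bootstrap_significance(z, "dcov_p", n_surrogates = 200, seed = 3)
binarize(sig, threshold = 0.01)
#> <binary_network> 10 nodes, 8 edges, directed, threshold 0.01

sc <- surrogate_sc(net, "mouse")          # ordinal 1..7 structural surrogate
tidy(ascs_curve(sig, sc, thresholds = c(0.05, 0.01)))
#> # A tibble: 2 × 4
#>   method threshold n_edges  ascs
#>   <chr>      <dbl>   <dbl> <dbl>
#> 1 dcov_p      0.05      14  3.07
#> 2 dcov_p      0.01       8  3.88
```

The mean off-diagonal SC here is 2.14, so the edges that survive
significance testing sit on substantially stronger structural
connections (ASCS 3.07), and tightening the threshold from 0.05 to
0.01 raises ASCS further (3.88): the surviving dCov edges are
preferentially the anatomically strong ones.  Topology of the
binarized network comes from `topology_report()`:

```r
glance(topology_report(binarize(sig, 0.05)))
#> # A tibble: 1 × 9
#>   directed n_nodes n_edges global_efficiency local_efficiency clustering ...
#> 1 TRUE          10      14             0.285                0          0
```

A JSON-configured end-to-end run (simulate → reconstruct → estimate →
significance → ASCS → topology → behaviour) is available as
`run_pipeline(config, out_dir)`, or from the shell through the thin
CLI at `inst/cli/dcovnet.R` (subcommands `run`, `simulate`,
`reconstruct`, `estimate`, `testsig`, `compare-sc`, `topology`,
`behavior`).

## Notes and conventions

* Directed matrices use **row = sink, column = source** throughout;
  graph-topology code converts internally to the adjacency convention
  `a[i, j] = edge i → j`.
* Granger p-values and edge p-values are deliberately *uncorrected*
  for multiple comparisons; binarization thresholds play that role.
* See the methods vignette (`vignettes/dcovnet-methods.Rmd`) for the
  model assumptions, parameter defaults with units, numerical choices
  and known limitations.
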