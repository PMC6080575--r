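# devmeta

Decomposition of developing brain networks into stage-evolving
meta-networks.

## The problem

Cross-sectional morphometry studies build one **structural correlation
network** per age group: nodes are cortical regions (e.g., 78 AAL regions),
and the weight of an edge is the absolute Pearson correlation of a regional
measure — typically mean cortical thickness — across the subjects scanned
at that age. An age-ordered sequence of such networks (say, ages 3–20)
traces how inter-regional coordination reorganizes during development, but
classical matrix decompositions treat the sequence as static and miss the
dynamics.

`devmeta` implements a spatiotemporal decomposition of such a sequence for
researchers studying developmental (or any longitudinal) network data. It:

1. **Builds** the networks from per-age subject-by-ROI tables, after
   removing confounds (gender, overall mean thickness) by linear
   regression, and stacks the vectorized upper triangles into an
   `M x tau` matrix `X` (`M = N(N-1)/2` connections, `tau` time points).
2. **Identifies developmental stages** by consensus k-means: for each
   candidate stage count `G`, 100 randomized k-means runs are summarized
   in a co-clustering consensus matrix `C`, scored by the **dispersion
   coefficient** `rho(C) = (1/tau^2) * sum 4 (C_ij - 1/2)^2`; the most
   consistent partition at the finest granularity wins.
3. **Factorizes** the staged sequence. With `X = [X^1 ... X^G]`, each
   stage block is modelled as `X^t ~ U^t V^tT`, where the `M x p`
   stage states `U^t` are non-negative with (near-)orthonormal columns —
   `p` **developmental meta-networks** whose connection patterns may
   evolve across stages — and `V` (`tau x p`) holds non-negative shared
   **trajectories**, whose stage blocks `V^t` are cut out by mask
   matrices. The objective

   ```
   J = sum_t 1/2 ||X^t - U^t V^tT||_F^2 + lambda/2 ||V||_F^2
       + alpha/4 sum_{k,l} W_U(k,l) ||U^k - U^l||_F^2
       + beta/4  sum_{i,j} W_V(i,j) ||v_i - v_j||^2
   ```

   combines reconstruction, a ridge on `V` (the non-negative surrogate of
   a nuclear-norm penalty), and temporal-smoothness regularizers on chain
   graphs over consecutive stages (`W_U`) and time points (`W_V`). It is
   minimized by damped multiplicative updates from many random restarts.
   The number of meta-networks is chosen by maximizing the **minimal
   trajectory distance** (MTD) between L2-normalized trajectory columns.
4. **Characterizes connections**: per meta-network, *stable connections*
   have the least normalized divergence
   `Omega = (sum_{k,l} |u^k - u^l|) / mean_t(u^t)` across stage states
   (top 2%, excluding connections below the root-mean-square strength
   threshold `delta_r`), and *rapidly-changing connections* are those
   whose between-stage change `Delta u` shares its sign with the
   meta-network's stage-contribution change `Delta v-bar` and is largest
   in magnitude.
5. **Quantifies reproducibility** by splitting the sequence into
   odd/even-position halves, factorizing each independently, matching
   components with the Hungarian algorithm, and reporting cosine
   similarities of matched meta-networks and trajectories.

A planted-model generator (`generate_planted_networks`,
`generate_thickness_tables`) emulates the whole data-generating process,
so every step is testable without access to any imaging repository.

## Worked example

```r
library(devmeta)

sim <- generate_planted_networks(seed = 1)   # 40 nodes, 12 time points
X <- sim$networks
X
#> developmental_networks: 40 nodes, 780 connections, 12 time points (1..12)

sel <- select_stage_partition(X, G_range = 2:6, n_runs = 100, seed = 2)
round(sel$dispersion, 3)
#>     2     3     4     5     6
#> 0.577 1.000 0.920 0.912 0.900
sel$partition
#> stage_partition: 3 stages over 12 time points
#>   stage 1: time points 1, 2, 3, 4
#>   stage 2: time points 5, 6, 7, 8
#>   stage 3: time points 9, 10, 11, 12

fit <- dmd_fit(X, sel$partition, dmd_config(p = 3, n_init = 10, seed = 3))
fit
#> dmd_result: 3 meta-networks, 3 stages, 12 time points
#>   final objective 1.11367 after 208 iterations (restart 9 of 10)
#>   orthogonality gap per stage: 0.381, 0.360, 0.442

rep <- characterize_dms(fit, top_fraction = 0.02)
round(rep$contributions, 3)   # stage contributions, one column per DM
#>       [,1]  [,2]  [,3]
#> [1,] 0.055 0.223 0.945
#> [2,] 0.198 0.807 0.230
#> [3,] 0.966 0.220 0.050
```

The dispersion curve is maximal (exactly 1: all 100 runs agree) at
`G = 3`, recovering the three planted stages. The fitted stage
contributions show one meta-network fading with age, one peaking in the
middle stage, and one rising — the planted trajectory shapes. The top
stable connections of each meta-network (`rep$stable`) list the planted
support edges with near-zero divergence, and

```r
repro <- split_half_reproducibility(X, sel$partition,
                                    dmd_config(p = 3, n_init = 10, seed = 3))
#> split-half mean cosine: U 0.869, V 0.973
```

shows that meta-networks and trajectories refit on odd/even halves match
closely.

The same pipeline runs from the shell:

```sh
Rscript exec/devmeta simulate --seed 1 --out sim/
Rscript exec/devmeta stages   --stack sim/stack.tsv --g-min 2 --g-max 6 --seed 2 --out stages.json
Rscript exec/devmeta fit      --stack sim/stack.tsv --stages stages.json --p 3 --seed 3 --out out/
```

or end to end via a YAML config with `Rscript exec/devmeta run --config
config.yaml`, which writes every artifact plus a run manifest.

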