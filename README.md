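# piclink

Similarity-index link prediction for undirected simple networks —
protein–protein interaction maps, neural wiring diagrams, food webs,
communication and social graphs. Given an observed network, the package
scores every non-observed node pair by its likelihood of being a missing
or future link, and evaluates scorers with the field's standard AUC /
precision@L protocol.

Its core is the **potential information capacity (PIC) index**. Every
neighbor of an endpoint is an anchor of an information channel; a two-hop
channel through a relay of degree $k$ transfers $1/(k-1)$ of a unit, and,
Cannikin-Law style, a pair's multipath capacity is pinned to its weakest
path — the one through the highest-degree common neighbor $k^{max}$:

$$IC(i,j) = \Big(a_{ij} + \frac{n_{ij}}{k^{max}_{ij}-1}\Big)^{\beta},
\qquad
s_{xy} = \sum_{z\in\Gamma(y)} IC(x,z) + \sum_{z\in\Gamma(x)} IC(y,z),$$

where $n_{ij}$ is the number of common neighbors, $a_{ij}$ the adjacency
flag and $\beta \ge 0$ a strength parameter ($\beta = 0$ reduces the score
to the degree sum $k_x + k_y$). Nine classical baselines ship alongside:
CN, RA, AA, CAR, PA, LP, Katz, ACT and Cos+ (the last two via the
Laplacian pseudoinverse). A Barabási–Albert generator provides synthetic
scale-free test networks, and a CLI wires everything into reproducible
runs on edge-list files.

## Worked example

```r
library(piclink)

b5 <- fixture_graph("bucket5")        # edges 1-2, 2-3, 3-4, 4-5, 2-4
score_all(b5, "PIC", beta = 1)
#>   node_u node_v score
#> 1      1      3   3.0
#> 2      1      4   3.5
#> 3      1      5   1.0
#> 4      2      5   3.5
#> 5      3      5   3.0
```

The score of pair (1,3) decomposes into three channels: through 3's
neighbors 2 and 4, $IC(1,2) = 1$ (a direct link, no common neighbor) and
$IC(1,4) = 0.5$ (one two-hop path through node 2, degree 3, so transfer
$1/(3-1)$); through 1's neighbor 2, $IC(3,2) = 1.5$ (direct link plus one
path through node 4). Total $1 + 0.5 + 1.5 = 3$.

Evaluation on a synthetic scale-free network:

```r
g <- generate_ba(300, 2, seed = 1)
topology_stats(g)
#> network: 300 nodes, 597 edges
#>   <k> = 3.98  <d> = 3.57  C = 0.058  r = -0.159  H = 2.20

evaluate_index(g, "PIC", beta = 0.9, n_realizations = 20, cutoff = 100)
#> index PIC over 20 realization(s):
#>   AUC       0.5529 (sd 0.0252)
#>   precision 0.0165 (sd 0.0131) at L = 100

beta_sweep(g, beta_grid = seq(0, 2, by = 0.5), n_realizations = 20)
#> beta sweep over 5 grid point(s), 20 realization(s):
#>   max AUC       0.7021 at beta = 0
#>   max precision 0.0265 at beta = 0
```

Each AUC/precision value is an average over 20 independent 90/10
train/probe splits. On pure preferential-attachment graphs the sweep peaks
at $\beta = 0$: link formation there is driven by degree (channel count),
and the degree-sum limit of PIC captures it — and still beats common
neighbors (CN averages AUC 0.5397 on the same splits). On networks where
capacity matters more than count, the optimum moves above 1; $\beta
\approx 0.9$ (AUC) and $\beta \approx 0.4$ (precision) are good defaults
on real networks.

## Command line

```sh
inst/cli/piclink generate --nodes 800 --m 2 --seed 1 --output sd.txt
inst/cli/piclink stats    --input sd.txt
inst/cli/piclink score    --input sd.txt --index PIC --beta 0.9 --output scores.tsv
inst/cli/piclink evaluate --input sd.txt --index PIC --beta 0.9 \
                          --realizations 20 --cutoff 100 --output eval.tsv
inst/cli/piclink sweep    --input sd.txt --betas 0,0.5,1,1.5,2 --output sweep.tsv
```

Inputs are plain edge lists (two whitespace-separated labels per line, `#`
comments; `.graphml` also accepted). All commands are deterministic given
their seeds; defaults can be kept in a YAML file passed with `--config`.

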