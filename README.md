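# mtcov

Overlapping community detection for **directed, weighted, multilayer
networks with categorical node attributes**.

Most community-detection methods use only the interaction topology, and
node metadata — religion, caste, age class, cell type — is relegated to
post-hoc validation. `mtcov` instead treats the attribute as a second data
source and *infers* how strongly it correlates with the community
structure, for networks where interactions come in several types (layers).
It is aimed at computational social scientists and network biologists who
have an edge list with layer labels, one categorical covariate per node,
and want soft community memberships, link prediction, or attribute
prediction out of the same fitted model.

## Model

With $N$ nodes, $L$ layers and $C$ communities, every node gets two
simplex-normalized membership vectors ($u_i$ for outgoing, $v_i$ for
incoming links). Edge counts are Poisson,

$$a_{ij}^{(\alpha)} \sim \mathrm{Pois}\Big(\sum_{k,l} u_{ik} v_{jl} w_{kl}^{(\alpha)}\Big),$$

with a $C \times C$ affinity matrix $W^{(\alpha)}$ per layer (assortative,
disassortative, core–periphery, directionally biased — anything
non-negative). The one-hot attribute $x_i$ is multinomial,

$$\pi_{iz} = \tfrac12 \sum_k \beta_{kz} (u_{ik} + v_{ik}),$$

with $\beta_{kz}$ the inferred community–category association. The joint
objective

$$\mathcal{L} = (1-\gamma)\,\mathcal{L}_G + \gamma\,\mathcal{L}_X,
\qquad \gamma \in [0,1],$$

interpolates between purely topological ($\gamma=0$) and purely
attribute-driven ($\gamma=1$) clustering. Inference is EM with closed-form
updates, sparse in the edges ($O(EC^2 + NCZ)$ per iteration), with
multiple random restarts. $\gamma$ and $C$ can be chosen by 5-fold
cross-validation on held-out link-prediction AUC and attribute accuracy.

## Worked example

Generate a standard two-layer benchmark (one assortative and one
disassortative layer, two planted communities of 500 nodes, average degree
4 per layer), attach an attribute matching the planted community for 70%
of nodes, and fit with $\gamma = 0.7$:

```r
library(mtcov)

bench <- make_benchmark("G1", seed = 7)                  # N = 1000, C = 2, k = 4
bench$network
#> multilayer_network: 1000 nodes, 2 layers, 8829 non-zero entries (total weight 8859), directed

X   <- bench$attributes(match_ratio = 0.7, seed = 8)
fit <- mtcov_fit(bench$network, X, C = 2, gamma = 0.7, seed = 9)
fit
#> mtcov_fit: N=1000, C=2, L=2, gamma=0.7
#>   best of 10 restarts: loglik -16106.0540 after 100 iterations (converged)

score_against_truth(bench$truth, fit$params)
#> $f1      [1] 0.989
#> $jaccard [1] 0.978
#> $cs      [1] 0.978
#> $l1      [1] 0.0788
```

The scores compare detected communities with the planted ones,
direction-averaged over $U$ and $V$: matched F1 and Jaccard on the hard
(argmax) partitions, and cosine similarity / halved $L_1$ error on the
soft memberships under the best community relabelling. Here 98.9% matched
F1 means recovery is near-perfect even though neither source alone
identifies the partition — a single assortative+disassortative layer pair
at this sparsity cannot (F1 around 0.5 without attributes), and 30% of
the attributes are noise.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/mtcov.R generate --benchmark G1 --seed 1 --outdir bench/
Rscript inst/cli/mtcov.R fit --edges bench/edges.tsv --attributes bench/attributes.csv \
        --C 2 --gamma 0.7 --outdir fit/
Rscript inst/cli/mtcov.R evaluate --fitdir fit/ --truth bench/truth.csv
Rscript inst/cli/mtcov.R cv --edges bench/edges.tsv --attributes bench/attributes.csv \
        --C-grid 2,3 --gamma-grid 0,0.3,0.6,0.9
```

Input formats: a long-format TSV edge list with header
`source target layer weight` (weights are non-negative integer counts;
self-loops and zero-weight records are dropped, duplicates summed) and a
CSV attribute table (`node` column plus attribute columns; several
attributes can be combined into one super-attribute, continuous ones
binned with `--bin-width`).

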