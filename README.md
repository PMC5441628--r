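# sscd — semi-supervised community detection with pairwise constraints

Community detection from network topology alone breaks down on sparse,
noisy graphs: below a detectability threshold no algorithm can recover
the groups from edges only. But domain knowledge often supplies
*pairwise constraints* — **must-link** pairs that belong to the same
community and **cannot-link** pairs that belong to different ones.
`sscd` encodes those constraints as positive and negative links of a
signed network and folds them into a symmetric nonnegative matrix
factorization:

```
min_{H >= 0}  || A - H Hᵀ ||²_F  +  γ₁ tr(Hᵀ Aⁿ H)  +  γ₂ tr(Hᵀ L H)
```

where `A` is the adjacency matrix, `Aⁿ` carries the cannot-links,
`L = D − Aᵖ` is the Laplacian of the must-link graph, and
`H ∈ R^{n×k}` holds each node's community strengths. The problem is
solved by the multiplicative update

```
H_ij ← H_ij · (2AH + γ₂AᵖH)_ij / (2HHᵀH + γ₁AⁿH + γ₂DH)_ij
```

(O(n²k) per iteration, reducing exactly to plain symmetric NMF when
γ₁ = γ₂ = 0), and hardened to a partition by row-wise argmax. The
package is for anyone benchmarking or applying constrained community
detection: it also provides prior budgeting and sampling from ground
truth, NMI/Purity scoring, three published comparison methods
(NMF_LSE, PMF, SNMF_SS), a planted-partition generator, and the full
sweep protocols (prior percentages, γ₁ × γ₂ grids, repeated-run
averaging) — all tidyverse-friendly (tibbles in and out, `tidy()` /
`glance()` / `autoplot()`).

## Worked example

```r
library(sscd)

# a 3-block planted partition far below the detectability threshold:
# ~4.7 within-block vs ~6.4 between-block expected neighbours per node
sim <- planted_partition(c(40, 40, 40), p_in = 0.12, p_out = 0.08, seed = 8)

# topology alone fails
unsup <- sscd_fit(sim$network, k = 3, seed = 1)
nmi(hard_assign(unsup), sim$truth)
#> [1] 0.04454327

# 20% of the must-link budget + 5% of the cannot-link budget as priors
cs <- sample_constraints(sim$truth, pct_must = 0.2, pct_cannot = 0.05, seed = 2)
semi <- sscd_fit(sim$network, k = 3, constraints = cs, seed = 1)
nmi(hard_assign(semi), sim$truth)
#> [1] 0.7737112
purity(hard_assign(semi), sim$truth)
#> [1] 0.9416667

glance(semi)
#> # A tibble: 1 × 7
#>   method     n     k objective n_iter converged n_communities
#>   <chr>  <int> <int>     <dbl>  <int> <lgl>             <int>
#> 1 sscd     120     3     1189.     54 TRUE                  3
```

NMI (normalized mutual information) is 0 for partitions independent of
the ground truth and 1 for perfect recovery: the same network moves
from essentially random (0.04) to largely recovered (0.77) once a
fifth of the within-community pairs are supplied as priors. Purity
(0.94) is the fraction of nodes matching their detected community's
majority true label.

Networks are read with `read_edge_list()` / `read_gml()`, ground truth
with `read_labels()`, user constraints with `read_constraints()`;
`write_report()` emits a membership TSV plus a JSON sidecar with
metrics, hyperparameters, seed and the objective trace. `prior_sweep()`
and `param_grid()` run the full averaged protocols, and `exec/sscd` is
a command-line wrapper (`detect`, `evaluate`, `simulate`,
`sweep-priors`, `sweep-params`) over the same functions.

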