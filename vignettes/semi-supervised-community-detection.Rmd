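---
title: "Semi-supervised community detection with pairwise constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised community detection with pairwise constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sscd)
library(ggplot2)
```

## The problem

Community structure — groups of nodes more densely connected internally
than externally — often cannot be recovered from topology alone. Sparse,
noisy networks sit below a detectability threshold where no algorithm
can find the planted groups from edges only. In many applications,
however, domain knowledge supplies *pairwise constraints*: must-link
pairs (two nodes belong to the same community) and cannot-link pairs
(they belong to different ones). This package treats those constraints
as *positive and negative links* overlaid on the topology — a signed
network — and pushes the detected communities to keep negative links
between groups and positive links within them.

## Model

Let $A \in \{0,1\}^{n \times n}$ be the symmetric adjacency matrix,
$A^p$ the positive-link matrix (one entry pair per must-link
constraint) and $A^n$ the negative-link matrix (cannot-links). With
$H \in \mathbb{R}^{n \times k}_{\ge 0}$ the community-strength matrix,
the method minimizes

$$
f(H) \;=\; \lVert A - H H^\top \rVert_F^2
\;+\; \gamma_1\, \mathrm{tr}(H^\top A^n H)
\;+\; \gamma_2\, \mathrm{tr}(H^\top L H),
\qquad H_{ij} \ge 0,
$$

where $L = D - A^p$ is the Laplacian of the positive links and $D$ its
degree matrix. The first term is symmetric NMF of the topology: rows of
$H$ embed nodes in a $k$-dimensional nonnegative latent space in which
co-membership appears as large inner products. The second term is the
continuous relaxation of a ratio cut on the negative links — it grows
when cannot-linked nodes share latent mass, so minimizing it pushes
them apart. The third term is the familiar graph-regularization
penalty on the positive links: $\mathrm{tr}(H^\top L H) = \tfrac12
\sum_{ij} A^p_{ij} \lVert H_{i\cdot} - H_{j\cdot} \rVert^2$ shrinks the
latent distance between must-linked nodes. Both relaxations replace the
hard per-community indicator vectors (value $1/|\pi_c|$ inside
community $c$, 0 outside) by the nonnegative columns of $H$; the
package studies non-overlapping partitions only, so after fitting, node
$i$ is assigned to $\arg\max_j H_{ij}$ (`hard_assign()`), ties to the
lowest column index, all-zero rows to community 1 with a warning.

Setting the gradient split aside, the stationarity (KKT) condition

$$
\big(-4AH + 4HH^\top H + 2\gamma_1 A^n H + 2\gamma_2 L H\big)_{ij}
H_{ij} = 0
$$

yields the multiplicative update implemented in `sscd_update()`:

$$
H_{ij} \leftarrow H_{ij}\,
\frac{(2AH + \gamma_2 A^p H)_{ij}}
     {(2HH^\top H + \gamma_1 A^n H + \gamma_2 D H)_{ij}} .
$$

Each iteration costs $O(n^2 k)$ — the same as plain symmetric NMF, to
which the method reduces exactly when $\gamma_1 = \gamma_2 = 0$.

## Parameters

| parameter | default | role |
|---|---|---|
| `k` | — | number of communities (not selected automatically) |
| `gamma1` | 1 | weight of the negative-link (cannot) penalty; unitless |
| `gamma2` | 1 | weight of the positive-link Laplacian (must) penalty |
| `max_iter` | 200 | iteration cap |
| `tol` | 1e-6 | relative objective-change stopping threshold |
| `eps` | 1e-10 | denominator floor in the update |
| `n_restarts` | 1 | seeded restarts, best objective kept |

Both weights default to 1, the setting used throughout the sweep
protocols. Experience with the parameter grid (`param_grid()`) is that
results are fairly insensitive to `gamma1` over a wide range, while
`gamma2` matters more; values of order 1–5 are a reasonable operating
range, and `autoplot()` on a grid result shows the landscape for a
given network.

## Numerical choices

* **Initialization.** $H_{ij} \sim U(0.01, 1)$, seeded. Strictly
  positive entries avoid the zero-locking of multiplicative updates (a
  zero entry can never become positive again).
* **Stopping.** $|f_t - f_{t-1}| / \max(f_{t-1}, 10^{-12}) <$ `tol`, or
  `max_iter`.
* **Denominator guard.** The update floors the denominator at `eps`
  (`pmax(den, eps)`) rather than adding `eps` to it: flooring guards
  0/0 identically but leaves every healthy denominator untouched, so an
  exact KKT point is an exact fixed point of the implemented map (to
  machine precision), which the test suite asserts at 1e-12.
* **Non-monotonicity of the update.** The undamped ratio rule above
  does *not* guarantee descent of $f$: for symmetric NMF the global
  scale of $H$ follows $c \mapsto 1/c$ near a fixed point, producing a
  period-2 oscillation of the objective while the row-wise *direction*
  of $H$ (which is all that hardening uses) stabilizes. The smallest
  example shows it: $A = \begin{pmatrix}0&1\\1&0\end{pmatrix}$, $k=1$,
  $H = (1,1)^\top \mapsto (0.5,0.5)^\top \mapsto (1,1)^\top \cdots$
  with objective $2 \to 1.25 \to 2$. The rule is kept in its stated
  form because the reduction to plain symmetric NMF at
  $\gamma_1=\gamma_2=0$ is part of the method's contract; users who
  need a monotone trace can damp externally (average successive
  iterates) at the cost of that equivalence. With constraints present
  the regularizers break the scale symmetry and the trace typically
  converges; the diagnostic `descent_max_rel_increase` in the
  acceptance script reports the worst observed rise honestly.
* **Local minima and restarts.** The objective is nonconvex; a single
  random start can stall. `n_restarts > 1` refits from derived seeds
  and keeps the lowest final objective. The default stays 1 because the
  evaluation protocol averages metrics over independent runs rather
  than selecting them; the one place the package itself uses restarts
  is the full-supervision recovery check (all intra-community pairs as
  must-links), which is a statement about the objective's *minimizer*
  and therefore fits best-of-8 restarts to reach it reliably.
* **Degenerate inputs.** Empty constraint sets give $A^p = A^n = 0$ and
  plain symmetric NMF. Empty detected communities are permitted;
  reporting compacts community indices. A pair constrained both ways is
  an error naming the offenders.

## Constraints: budgets, sampling, encoding

For ground-truth community sizes $N_1,\dots,N_K$ the number of distinct
must-link pairs is $M = \sum_k N_k(N_k-1)/2$ and of cannot-link pairs
$C = \sum_{i<j} N_i N_j$; together they tile all $n(n-1)/2$ pairs, a
property the tests check exhaustively. Prior "percentages" are always
fractions of these budgets, converted to counts with `floor()`.
`sample_constraints()` draws uniformly without replacement — including
intra-community pairs already joined by an edge, since the budget
counts all intra pairs. A mixed experiment at total level $x$ splits it
as $x/2$ of *each* budget (`mix = "half_half"` in `prior_sweep()`);
because the cannot budget is usually much larger, this yields many more
cannot pairs than must pairs, which mirrors how the mixed protocol is
defined rather than equalizing the counts. No transitive closure or
other logical inference is applied to constraints. The topology stays
in $A$ and sampled must-links in $A^p$: the objective carries them as
separate terms with separate weights. `encode_signed(fold_topology =
TRUE)` folds the edges into $A^p$ for users who want the
edges-as-positive-links reading; it is off by default because the
objective and update treat $A$ and $A^p$ distinctly.

## Evaluation

`nmi()` implements normalized mutual information from the confusion
matrix $F$ ($F_{ij}$ = nodes in detected community $i$ with true label
$j$), with $0 \log 0 = 0$; it is 1 for identical partitions, 0 for
independent ones, symmetric, label-permutation invariant, and
log-base free. If both partitions are trivial the denominator vanishes
and the value is defined as 1 with a warning. `purity()` is the
fraction of nodes covered by their detected community's majority true
label; splitting a detected community never decreases it, so it should
be read alongside NMI, not alone.

## Comparison methods

Three published constrained-factorization schemes are implemented in
their single-network symmetric form (`fit_nmf_lse()`, `fit_pmf()`,
`fit_snmf_ss()`); all share the multiplicative engine and reduce to
plain symmetric NMF with no constraints.

* *NMF_LSE* adds $\lambda\,\mathrm{tr}(H^\top L_m H)$ over the
  must-link graph only (weight 1 by default); cannot-links have no
  effect on it, which the tests assert.
* *PMF* adds $\mathrm{tr}(H^\top \Theta H)$ with $\Theta_{ij} = \delta$
  (default 2) at cannot pairs and $-\theta$ (default 1) at must pairs;
  the positive part of $\Theta$ is routed to the update's denominator
  and the negative part to its numerator. The original scheme addresses
  multi-type data; only the symmetric single-network analogue needed
  for comparison is implemented — an interpretation, flagged as such.
* *SNMF_SS* factorizes $\tilde A = A - \alpha M + \beta C$ (defaults
  $\alpha = 0.001$, $\beta = 0.1$), clamping negative entries at 0
  because the multiplicative update cannot accept them. As printed,
  this formula *subtracts* weight at must pairs and *adds* it at cannot
  pairs; it is implemented exactly as stated, with
  `flip_signs = TRUE` available for the intuitive orientation.

## What the generator emulates — and what it does not

`planted_partition()` draws each intra-block pair with probability
`p_in` and each inter-block pair with `p_out` (equal `p_in` across
blocks — the minimal adequate model for unweighted assortative
networks; no degree correction, no overlap). The bundled regimes of
`fixture_suite()`:

* **easy** — 2 blocks of 20, `p_in` 0.5, `p_out` 0.02: recoverable from
  topology alone; used to check exact recovery and run-to-run
  stability.
* **ambiguous** — 3 blocks of 40, `p_in` 0.12, `p_out` 0.08: far below
  the detectability threshold (each node expects ~4.7 within-block and
  ~6.4 between-block neighbours), so topology-only NMI is near 0 and
  any improvement is attributable to the priors.
* **unbalanced** — blocks 60/30/15, `p_in` 0.3, `p_out` 0.05: unequal
  sizes for the reporting/compaction paths.

Sizes (n ≈ 40–120) were chosen so a full sweep runs in seconds; the
real networks the method targets are larger (up to thousands of nodes),
sparser, heavy-tailed in degree, and carry correlated noise none of
which the generator reproduces. Passing these tests therefore
demonstrates correctness of the machinery and the qualitative
prior-response trends, not performance claims on real data. On the
ambiguous regime at the default weights, must-link priors raise mean
NMI monotonically with prior volume, but the rise saturates below
perfect recovery even at 30% of the budget — the quartic topology term
retains weight against the linear-in-$H$ regularizers — and the
$\Theta$-based comparison method, which rewards must pairs directly in
the numerator, is the strongest performer on this particular synthetic
regime. Both behaviours are computed and reported by the acceptance
script rather than asserted away.

## Experiment protocol

`prior_sweep()` and `param_grid()` reproduce the evaluation protocol:
for every cell (method × percentage, or $\gamma_1 \times \gamma_2$ with
5%/5% priors), each of `runs` repetitions resamples *both* the
constraints and the initialization from a seed derived
deterministically from the master seed, the method, the cell and the
run index, then reports mean and variance of NMI and Purity. The
default is 50 runs (tests use 10–20 for speed); sweeps are reproducible
bit-for-bit from the master seed. Per-cell fit errors are recorded in
the `failed` column, not fatal.

## A worked example

```{r example}
sim <- planted_partition(c(40, 40, 40), p_in = 0.12, p_out = 0.08, seed = 8)
unsup <- sscd_fit(sim$network, k = 3, seed = 1)
nmi(hard_assign(unsup), sim$truth)

cs <- sample_constraints(sim$truth, pct_must = 0.2, pct_cannot = 0.05, seed = 2)
semi <- sscd_fit(sim$network, k = 3, constraints = cs, seed = 1)
nmi(hard_assign(semi), sim$truth)

glance(semi)
```

```{r sweep, fig.width = 6, fig.height = 3.5}
sw <- prior_sweep(sim$network, sim$truth, methods = c("sscd", "nmf_lse"),
                  percentages = c(0, 0.1, 0.2, 0.3), mix = "must_only",
                  runs = 10, seed = 3)
autoplot(sw)
```

## Known limitations

* `k` must be supplied; there is no automatic model selection.
* Binary undirected networks only; weights in input files are dropped
  with a warning.
* The objective trace of the undamped update is not guaranteed
  monotone (see above); convergence is declared on relative objective
  change, which a scale oscillation can postpone to `max_iter`.
* Hard, non-overlapping assignments only.
* Very large cannot-link volumes (more negative than positive links)
  can degrade detection — keeping cannot-link priors below the edge
  count of the network is a sensible rule of thumb.
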