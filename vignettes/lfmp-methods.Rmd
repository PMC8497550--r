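---
title: "Predicting lncRNA-disease associations without lncRNA-disease training data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lncRNA-disease associations without lncRNA-disease training data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfmp)
```

## The problem and the model

Experimentally confirmed lncRNA-disease associations are scarce, which
cripples any predictor trained on them directly. The model implemented here
(LFMP) sidesteps the problem: it never consumes lncRNA-disease data. Its only
inputs are two better-populated association layers, a binary lncRNA-miRNA
adjacency matrix $A_{LM}$ ($m \times n$) and a binary miRNA-disease adjacency
matrix $A_{MD}$ ($n \times e$), reconciled to a shared miRNA axis. Known
lncRNA-disease associations are used exclusively as evaluation labels.

The pipeline has three stages.

**1. Preliminary scores.** $A_{LD} = A_{LM} A_{MD}$, so entry $(i,j)$ counts
the miRNAs shared between lncRNA $i$ and disease $j$ — the number of length-2
paths through the intermediate layer. This matrix is informative but sparse
and integer-valued.

**2. Latent factor densification.** $A_{LD}$ is approximated by
$\psi = XY$ with $X \in \mathbb{R}^{m\times K}$, $Y \in \mathbb{R}^{K\times e}$,
minimizing

$$L(X,Y) = \sum_{i,j}\big(A_{LD,ij} - X_i^\top Y_j\big)^2
  + \lambda\big(\lVert X\rVert_F^2 + \lVert Y\rVert_F^2\big)$$

by full-batch gradient descent with simultaneous updates
$X \leftarrow X - \alpha\,(2(XY - A_{LD})Y^\top + 2\lambda X)$ and
symmetrically for $Y$. The reconstruction $\psi$ fills in the zero cells of
$A_{LD}$ through shared latent structure; larger entries mean stronger
predicted association.

**3. Similarity-space projection and fusion.** Cosine and Jaccard similarity
are computed over the binary association profiles — rows of $A_{LM}$ for
lncRNAs, columns of $A_{MD}$ for diseases — and integrated entrywise as their
average where cosine is non-zero, Jaccard otherwise, giving $ILS$
($m \times m$) and $IDS$ ($e \times e$). The score matrix is projected
through each similarity space,

$$LP(i,:) = \frac{\sum_j ILS(i,j)\,\psi(j,:)}{\lVert ILS(i,:)\rVert},\qquad
  DP(:,j) = \frac{\sum_i IDS(i,j)\,\psi(:,i)}{\lVert IDS(:,j)\rVert},$$

and the two projections fused with weight $\omega$:

$$S(i,j) = \frac{\omega\,LP(i,j) + (1-\omega)\,DP(i,j)}
                {\lVert ILS(i,:)\rVert + \lVert IDS(:,j)\rVert}.$$

On binary profiles the Jaccard fallback in the integration rule is provably
vacuous — cosine and Jaccard vanish together, exactly when two supports are
disjoint — but it is implemented literally so that non-binary profiles behave
as documented. The test suite asserts the equivalence on random binary
inputs.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 2e-4 | gradient descent learning rate (published value) |
| `lambda` | 4e-3 | L2 penalty on both factors (published value) |
| `omega` | 0.3 | lncRNA-projection share in the fusion (published sweep optimum on [0,1]) |
| `k_dim` | 50 | latent dimension $K$ |
| `max_iters` | 5000 | iteration cap |
| `tol` | 1e-6 | relative loss-change stopping rule |
| `projection_style` | `"paper"` | `"paper"` or `"ncp"`, see below |

`alpha`, `lambda` and `omega` are the published settings. $K$, the iteration
budget, the stopping rule and the initialization are **not** published, so
published AUC values cannot be bit-reproduced; our choices are: $K = 50$
(well below the $\min(m,e) = 373$ of the corpus the method was built for,
configurable everywhere), a 5000-iteration cap with a $10^{-6}$ relative
loss-change tolerance, and factors initialized uniformly on
$[0, 1/\sqrt{K})$ — non-negative, matching a non-negative count target, with
initial reconstruction entries of order 1.

## Numerical and design choices

* **Loss summation.** The squared error is summed over *all* $m \times e$
  entries of $A_{LD}$, not only the non-zeros: scoring the zero cells is the
  entire point of the densification. The training target's membership set is
  ambiguous in the original description; this reading follows its stated
  intent ("X and Y are obtained by decomposition" of the full matrix).
* **Update scheme.** Simultaneous full-batch updates of $X$ and $Y$, not
  alternating least squares and not per-entry stochastic steps; the
  regularization term is part of the $\alpha$-scaled gradient. Both choices
  are pinned by a central-finite-difference gradient check (relative error
  below $10^{-5}$).
* **Double normalization.** As printed, the projections are divided by a
  similarity norm once in $LP$/$DP$ and again in the fusion denominator.
  Classical network consistency projection normalizes once. Whether the
  double division is intentional cannot be determined from the source, so
  the printed form is the default (`projection_style = "paper"`) and the
  single-normalization variant is available as `projection_style = "ncp"`.
  The two give different score scales but often similar rankings; all
  correctness tests run the default and the oracle covers both.
* **Degenerate entities.** An entity whose association profile is all zeros
  (possible after intersection alignment) gets a zero similarity row
  *including the diagonal*, projects to zero, and scores zero wherever both
  similarity norms vanish. Such entities are retained, not dropped, so
  output dimensions stay predictable.
* **Ties.** Ranking AUC uses midrank correction (all-tied scores give
  exactly 0.5); candidate rankings break ties by lncRNA name so runs are
  reproducible. The trapezoid of the threshold-sweep ROC and the rank-based
  AUC agree to $10^{-12}$ by construction, and the tests assert it.
* **Cross-validation semantics.** Because the model never consumes
  lncRNA-disease labels, LOOCV degenerates gracefully: scores are fixed, each
  held-out positive is ranked against all unlabeled pairs, and the aggregate
  equals the global positives-vs-unlabeled ranking AUC. k-fold partitions the
  evaluation labels only. All pairs absent from the label list are treated as
  unlabeled negatives, the standard convention in this literature.
* **Alignment.** The two input layers are reconciled to common miRNAs by
  intersection by default (the corpus the method was built on reports a
  single shared miRNA count), with a zero-padding union mode as the
  alternative. Alignment never flips an existing association between
  retained entities (property-tested).
* **Identifier normalization** (trim, collapse whitespace runs, upper-case
  RNA symbols, lower-case disease terms) is available but off by default:
  the counts in curated corpora are only reproducible under *some* cleaning
  rule, and synthetic data needs none.

## What the synthetic generator emulates — and what it does not

`generate_network()` draws a planted partition tripartite network: every
lncRNA, miRNA and disease gets a module uniformly at random; both bipartite
layers draw edges with probability `p_in` within modules and `p_out` across;
ground-truth lncRNA-disease positives are same-module pairs kept with
probability `q`. The planted truth is thus carried by shared miRNA
neighbourhoods — the very signal the predictor exploits — so recovering it is
a fair test of the method rather than of the generator.

Defaults (`m = 60`, `n = 30`, `e = 40`, `g = 3`, `p_in = 0.6`,
`p_out = 0.05`, `q = 0.5`) are chosen so that the trivial path-count baseline
$A_{LD}$ already ranks positives well (AUC above 0.75 on average) and the
full pipeline measurably improves on it; with `q = 0.5`, half of the
same-module pairs are unlabeled look-alikes of the positives, which caps the
attainable AUC below 1 and keeps the benchmark honest.

The generator does **not** reproduce real corpora: degree distributions are
binomial, not heavy-tailed; there is no identifier noise; modules are
disjoint and equally sized in expectation. A green end-to-end test therefore
establishes that the implementation recovers plantable structure through the
intended mechanism — not that it attains any published AUC on curated
databases, which additionally depend on unpublished $K$, iteration count and
initialization.

## Worked example

```{r example}
sim <- generate_network(synthetic_config(seed = 11))
run <- suppressWarnings(lfmp_run(sim$triple, lfmp_config(seed = 11)))
loocv_auc(run$scores, sim$truth)
rank_candidates(run$scores, "DIS001", top_n = 5)
```

The suppressed warning is deliberate: the default $K = 50$ is not below
$\min(m, e) = 40$ at this toy scale, so the factorization is not low-rank
there — harmless for prediction, and flagged so users notice on real-sized
data.

## Known limitations

* Published AUCs are not bit-reproducible (unpublished hyperparameters and
  initialization); at corpus scale the defaults land in the published
  vicinity but this is reported, not guaranteed.
* Full-batch gradient descent at the published learning rate converges
  slowly on large dense targets; the loss-change tolerance usually stops it
  far before the cap, and divergence raises an error suggesting a smaller
  `alpha` rather than returning garbage.
* No identifier mapping across nomenclatures: edge lists are matched as
  (normalized) strings.
* Evaluation treats unlabeled pairs as negatives; true-but-unknown
  associations therefore depress measured AUC, as in all positive-unlabeled
  settings.
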