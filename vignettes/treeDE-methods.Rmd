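---
title: "Tree-guided Bayesian differential expression: model and methods"
author: "treeDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-guided Bayesian differential expression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeDE)
```

## The problem

Differential expression (DE) in single-cell RNA-seq is usually tested one
cell type at a time after clustering and annotation. But related cell
types respond to a perturbation in a correlated way: a gene induced by an
infection in CD4 T cells is very often induced in CD8 T cells too.
Testing each type in isolation throws that information away, which
especially hurts rare cell types — a dendritic-cell population
contributing 1% of cells rarely has the counts to reach significance on
its own, even when its T-cell relatives carry clear evidence for the same
gene.

treeDE couples the per-type tests through a cell-type tree. Evidence for
DE in one leaf raises the prior odds of DE in nearby leaves, with the
coupling strength estimated from the data. The output is, for every gene
and cell type, a posterior probability that the gene is DE with respect
to the tested subject-level factor.

## Data model

Let $X_{gikc}$ be the count of gene $g$ in cell $c$ of cell type $k$ from
subject $i$. Counts are summed per (subject, type) into pseudo-bulk
matrices, library-size normalized and log-transformed:

$$Y_{gik} = \log\!\left(1 + \frac{\sum_c X_{gikc}}{\ell_{ik}}\, s_0\right),$$

with $\ell_{ik}$ the pseudo-bulk library size and $s_0 = 10^4$ the usual
scale factor. Modelling at the pseudo-bulk level makes subjects — not
cells — the units of replication, which is what protects the test from
pseudo-replication (see below).

Given the latent DE indicator $Z_{gk} \in \{0, 1\}$, expression follows a
Gaussian linear model

$$Y_{gik} \mid Z_{gk} \sim N\!\left(\mu_{gk} + C_i^\top\beta_{gk} +
Z_{gk} A_i^\top \delta_{gk},\ \sigma^2_{gk}\right),$$

where $A_i$ is the tested factor (binary or continuous, possibly
vector-valued) and $C_i$ optional covariates. For each gene and type the
null ($Z=0$) and alternative ($Z=1$) models are fitted by ordinary least
squares with the maximum-likelihood variance $\hat\sigma^2 =
\mathrm{RSS}/N_k$; both per-hypothesis log-likelihoods are stored. Each
hypothesis carries its own variance estimate — the generalized
likelihood-ratio convention; since the models are nested, the alternative
log-likelihood never falls below the null.

## The cell-type tree and its priors

The hierarchy is estimated from first-pass per-type DE statistics
(`screenDE()`): genes with $|t| > 2.58$ (the two-sided normal critical
value at $p = .01$) in at least one type are retained, cell types are
compared by the Pearson correlation $r$ of their statistic vectors, and
the distance $d = (1 - r)/2$ is clustered agglomeratively (average
linkage by default). A user tree in newick format can be supplied
instead, e.g. to probe robustness to mis-specified hierarchies.

Each node of the tree carries a DE state: $Z_{gk}$ at leaves, $D$ at
internal nodes. The root is Bernoulli with marginal $\pi_{\text{root}}$;
every other node is Bernoulli($p$) when its parent is in state 1 and is 0
with probability one otherwise. The parameters are estimated genome-wide
from the screen's p-values at threshold $0.01$: a node's marginal
$\hat\pi$ is the fraction of genes significant in at least one of its
descendant types (minimum p-value over members), and the conditionals are
ratios $\hat p = \hat\pi_{\text{node}} / \hat\pi_{\text{parent}}$.
Because a node's significant set is nested in its parent's, marginals
decrease from root to leaf and all conditionals lie in $(0, 1]$.
Boundary estimates are moved $1/(2G)$ away from 0 and 1 so that
log-probabilities stay finite; this is the only regularization applied.

**Internal states as OR of the leaves.** The top-down Bernoulli
generative process technically allows an internal node to be "on" while
all of its leaves are "off". For inference we adopt the convention that
an internal state equals the OR of its descendant leaves, which makes the
internal states a deterministic function of $Z$ and reduces the joint
support to the $2^K$ leaf configurations. The collapsed prior then sums
to slightly less than one (the missing mass is exactly the
"node on, all leaves off" paths — about 0.1% for the default simulation
tree); posteriors are normalized within the collapsed set and are
therefore proper. The simulator, by contrast, samples the full generative
process, matching how the truth is defined in the benchmark design.

## Posterior computation

The likelihood factorizes over types and subjects, so a configuration's
log-likelihood is just the sum over leaves of the stored null or
alternative value. For each gene, all $2^K$ configurations are evaluated
(log prior + log likelihood), the marginal likelihood is obtained by
log-sum-exp, and

$$P(Z_{gk} = 1 \mid Y_g) = \frac{\sum_{Z:\,Z_k = 1} P(Y_g, Z)}
{\sum_{Z} P(Y_g, Z)}.$$

The enumeration is exact and is refused (rather than approximated) beyond
`kMax = 16` leaves; at the default $K = 6$ there are 64 terms per gene
and the computation is vectorized over genes in chunks. Genes are called
DE in a type when the posterior strictly exceeds 0.95.

## Numerical choices

* **Variance floor** $10^{-8}$ on every $\hat\sigma^2$: zero-residual
  fits (e.g. a gene exactly linear in the factor) would otherwise carry
  unbounded likelihood and dominate every posterior.
* **Log-sum-exp** throughout; log-likelihood differences of $\pm 10^4$
  neither overflow nor underflow.
* **Ties** in DE rankings are broken by gene identifier; cluster-merge
  ties are broken by sorting cell-type labels before clustering, so tree
  construction is deterministic.
* **Degenerate designs**: a cell type whose subjects have a constant
  factor value is flagged and its statistics set missing; missing
  statistics are excluded pairwise from correlations and never imputed.
  A gene-type fit that fails contributes no evidence (null and
  alternative log-likelihoods both zero) rather than poisoning the
  enumeration.
* **Missing (subject, type) pairs** (zero cells) drop that subject from
  that type's matrix only; the likelihood factorizes over types, so each
  type is fitted on its own subject subset.
* **Gene universe**: the `<10 cells` detection filter is applied per cell
  type, and the joint model runs on the intersection of genes passing in
  every type, since one DE-state vector per gene spans all $K$ types.
  Normalization happens after filtering, so library sizes refer to the
  modelled matrix.

## The simulator

`simulateDataset()` generates negative-binomial counts in the structure
of a two-group, multi-subject, multi-cell-type study (whole blood as the
template): six cell types with unequal proportions (DC at 1%), 20
subjects per group and 200,000 cells at full scale. Truth is drawn from
the generative tree of `defaultSimTree()`, whose printed parameters give
every leaf a 20% marginal DE probability and pairwise DE overlaps of 90%
(CD4–CD8, Mono–DC), 75% (B vs CD4/CD8), 60% (NK vs CD4/CD8) and 40%
across the two main clusters.

Per gene, subject and type the baseline mean is
$m_{gik} = \text{geneMean}_g \times e_{gik}$ with
$\text{geneMean} \sim \text{LogNormal}(\log 5, 1.2^2)$ truncated at 0.05
and a subject-level effect $e \sim \text{LogNormal}(0, 0.25^2)$. The
group-2 mean is $m \cdot 2^{\text{lfc}}$ with
$\text{lfc} \sim N(0.065, 0.12^2)$ for DE entries and $N(0, 0.001^2)$
otherwise, drawn independently per (gene, type). Cells receive size
factors $s \sim U(0, 0.12)$ and counts
$X \sim \mathrm{NB}(s\mu, \phi)$ in the NB2 parameterization
($\mathrm{Var} = s\mu + \phi (s\mu)^2$) with $\phi = 0.01/\mu + 0.05$
computed from the unscaled mean. Cells are allocated to (subject, type)
pairs deterministically from the proportions, and identical seeds
reproduce datasets bit for bit.

The subject-level effect is the essential ingredient: cells from the same
subject share a baseline that differs between subjects, so a cell-level
test that pools cells across subjects treats correlated observations as
independent and its false discovery rate explodes. The pseudo-bulk model
absorbs the same variation into $\sigma^2_{gk}$.

What the generator does **not** emulate: dropout beyond the NB law, batch
effects, empirical mean–variance relationships of a specific tissue, or
baseline means estimated from a real reference dataset. The gene-mean and
subject-effect laws here are synthetic stand-ins with all parameters
exposed in `defaultScenario()`; passing benchmarks on these data
demonstrates correct inference under the stated model, not performance on
any particular real dataset.

## Design choices made where the design was open

* **Normalization dialect**: natural-log `log1p(count/libsize * 1e4)`
  per pseudo-bulk column, the standard single-cell log-normalization;
  applied after the detection filter.
* **Screen backend**: the screen is defined by its contract — one signed
  statistic and p-value per gene and type. The default `nb_wald` is an NB
  GLM Wald test with a log library-size offset and a per-gene
  method-of-moments dispersion (floored at $10^{-8}$, no shrinkage);
  `ols_t` is a fast alternative operating on the same normalized values
  the main model uses (it is the pooled two-sample t when unadjusted and
  the factor is binary). Two-sided p-values throughout; raw (not
  adjusted) p-values feed the prior estimator.
* **Linkage**: average (UPGMA), the standard choice for
  correlation-derived distances; configurable.
* **Priors are genome-wide**: one $(\pi, p)$ set shared by all genes, as
  the per-gene indexing of the states (but not the parameters) implies.
* **Independent lfc per (gene, type)** among DE entries; a
  shared-direction option was considered and rejected as the formula
  indexes the fold change by both gene and type.
* **Cell allocation** is deterministic from the proportions rather than
  multinomial — it removes one source of benchmark variance without
  changing any expectation.
* **Subject effects** are drawn independently per (gene, subject, type).
  Drawing them shared across types would add cross-type correlation of
  null statistics; nothing in the benchmark design requires it.

## Problem sizes used in the tests

The packaged checks run the simulation study at a reduced scale chosen to
keep the full suite fast while preserving the qualitative regime: 2,000
genes, 10 subjects per group and 10,000 cells for the FDR and
information-sharing benchmarks (10 replicate seeds for the latter), and
50,000 genes for Monte-Carlo checks of the generative tree. Exact
enumeration is checked against an independently coded brute-force
summation for 3- and 4-leaf trees at tolerance $10^{-10}$.

## Known limitations

* The Gaussian likelihood uses plug-in MLE variances, not a marginal
  likelihood over $(\mu, \sigma^2)$. With few subjects its null tails are
  thinner than reality, so in very low signal-to-noise regimes the
  posterior-0.95 call set can contain chance hits; the 0.95 cutoff is a
  fixed convention, not an FDR-calibrated threshold. At the reduced
  benchmark scale above — where per-gene power is well under 1% — the
  handful of calls made this way is noise-dominated, and the cell-level
  straw-man comparison in the rarest type (100 DC cells) often produces
  no BH calls at all; both effects disappear at the full study scale.
* Exact enumeration is exponential in the number of cell types; beyond 16
  leaves the tool refuses rather than approximating.
* The prior estimator treats screening p-values as exchangeable across
  genes; strong inter-gene correlation (co-expression modules) is not
  modelled.
* Posteriors are conditional on the estimated tree; uncertainty in the
  tree itself is not propagated (mis-specified-tree experiments can be
  run by passing a user tree).

## A minimal run

```{r example, eval = FALSE}
sc <- defaultScenario(nGenes = 500, nSubjectsPerGroup = 8,
                      totalCells = 5000)
sce <- simulateDataset(sc, seed = 1)
res <- runPipeline(sce, screenMethod = "ols_t")
head(res$calls$CD4)
priorTable(res$tree)
```
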