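#' Estimate DE-state priors on the cell-type tree
#'
#' Marginal priors are estimated genome-wide from the screening p-values:
#' for a leaf, the fraction of genes with p below `pvalThreshold` in that
#' cell type; for an internal node, the fraction of genes significant in at
#' least one descendant cell type (minimum p over the node's members below
#' the threshold). Conditional inheritance probabilities are the ratios of
#' a node's marginal to its parent's. Because a node's significant gene set
#' is contained in its parent's by construction, every conditional lies in
#' (0, 1]. Marginals of exactly 0 or 1 are floored/ceilinged at
#' `1/(2G)` from the boundary so that log-probabilities stay finite.
#'
#' @param tree a [CellTypeTree-class] whose leaves match
#'   `cellTypes(screen)`.
#' @param screen a [ScreenResult-class] on the shared gene universe.
#' @param pvalThreshold significance cutoff on screening p-values
#'   (default 0.01).
#' @return the tree with `pi` and `p` filled (see [priorTable()]).
#' @export
estimatePriors <- function(tree, screen, pvalThreshold = 0.01) {
  stopifnot(is(tree, "CellTypeTree"), is(screen, "ScreenResult"))
  .assertScalarNumber(pvalThreshold, "pvalThreshold",
                      lower = .Machine$double.eps, upper = 1)
  leaves <- leafLabels(tree)
  if (!setequal(leaves, cellTypes(screen)))
    stop("tree leaves and screen cell types differ")
  pv <- screen@pval[, leaves, drop = FALSE]
  G <- nrow(pv)
  sig <- !is.na(pv) & pv < pvalThreshold
  nd <- tree@nodes
  eps <- 1 / (2 * G)
  pi <- vapply(tree@members, function(m)
    mean(rowSums(sig[, m, drop = FALSE]) > 0), numeric(1))
  if (any(pi <= 0) || any(pi >= 1)) {
    warning("boundary prior estimate(s) moved to ", signif(eps, 3),
            " from 0/1 to keep probabilities proper")
    pi <- pmin(pmax(pi, eps), 1 - eps)
  }
  nd$pi <- pi
  root <- .rootNode(tree)
  nd$p <- NA_real_
  notRoot <- nd$id[-root]
  nd$p[notRoot] <- pmin(nd$pi[notRoot] / nd$pi[nd$parent[notRoot]], 1)
  tree@nodes <- nd
  validObject(tree)
  tree
}

#' Log prior probability of a DE-state configuration
#'
#' Evaluates the tree-factorized prior of a leaf configuration `Z`, with
#' every internal node's state taken as the OR of its descendant leaves
#' (the convention under which the internal states are determined by `Z`
#' and the exact enumeration runs over the 2^K leaf configurations). The
#' root contributes a Bernoulli(`pi_root`) factor; every other node whose
#' parent is in state 1 contributes Bernoulli(`p`); nodes under a
#' state-0 parent are 0 with probability one.
#'
#' @param tree a [CellTypeTree-class] with priors filled.
#' @param Z binary vector of length K, ordered like `leafLabels(tree)` (or
#'   named by cell type).
#' @return the log prior probability.
#' @export
jointPriorLogProb <- function(tree, Z) {
  K <- sum(tree@nodes$leaf)
  if (length(Z) != K) stop("Z must have length ", K)
  if (!is.null(names(Z))) Z <- Z[leafLabels(tree)]
  if (anyNA(Z) || !all(Z %in% c(0, 1))) stop("Z must be binary")
  cfg <- .configPriorLogProb(tree, matrix(as.numeric(Z), nrow = 1))
  drop(cfg)
}

# log prior for each row of a (nconf x K) 0/1 leaf-configuration matrix
.configPriorLogProb <- function(tree, Zmat) {
  nd <- tree@nodes
  if (anyNA(nd$pi)) stop("tree priors are not set; run estimatePriors()")
  root <- .rootNode(tree)
  M <- nrow(nd)
  memberMat <- matrix(0, M, sum(nd$leaf))
  for (n in seq_len(M)) memberMat[n, tree@members[[n]]] <- 1
  D <- (Zmat %*% t(memberMat)) > 0           # nconf x M node states
  lp <- ifelse(D[, root], log(nd$pi[root]), log1p(-nd$pi[root]))
  for (n in nd$id[-root]) {
    pa <- nd$parent[n]
    term <- ifelse(D[, pa],
                   ifelse(D[, n], log(nd$p[n]), log1p(-nd$p[n])),
                   0)   # parent off => node off with probability 1
    lp <- lp + term
  }
  lp
}

# all 2^K leaf configurations (rows) in leaf-id column order, plus their
# log prior; shared by posterior computation and analytic checks
.enumerateConfigs <- function(tree) {
  K <- sum(tree@nodes$leaf)
  Zmat <- as.matrix(expand.grid(rep(list(c(0, 1)), K), KEEP.OUT.ATTRS = FALSE))
  colnames(Zmat) <- leafLabels(tree)
  list(Z = Zmat, logPrior = .configPriorLogProb(tree, Zmat))
}

#' Analytic DE probabilities implied by tree priors
#'
#' `treeLeafMarginals()` gives each leaf's marginal DE probability under
#' the generative tree prior — the product of inheritance probabilities
#' along the root-to-leaf path times the root marginal.
#' `treePairOverlap()` gives the expected overlap fraction of DE genes
#' between two leaves, `P(Z_a = 1, Z_b = 1) / P(Z_a = 1)`: conditional on
#' their lowest common ancestor being DE, the two root-to-leaf suffixes
#' are independent, so the joint is the LCA's marginal times both
#' conditional path products.
#'
#' @param tree a [CellTypeTree-class] with priors filled.
#' @param a,b leaf labels.
#' @return `treeLeafMarginals()`: named numeric vector over leaves;
#'   `treePairOverlap()`: a single probability.
#' @export
treeLeafMarginals <- function(tree) {
  nd <- tree@nodes
  if (anyNA(nd$pi)) stop("tree priors are not set")
  setNames(nd$pi[nd$leaf], nd$label[nd$leaf])
}

#' @rdname treeLeafMarginals
#' @export
treePairOverlap <- function(tree, a, b) {
  nd <- tree@nodes
  if (anyNA(nd$pi)) stop("tree priors are not set")
  leaves <- leafLabels(tree)
  ia <- match(a, leaves); ib <- match(b, leaves)
  if (anyNA(c(ia, ib))) stop("unknown leaf label")
  pathUp <- function(n) {
    path <- n
    while (!is.na(nd$parent[n])) { n <- nd$parent[n]; path <- c(path, n) }
    path
  }
  pa <- pathUp(ia); pb <- pathUp(ib)
  lca <- pa[min(which(pa %in% pb))]
  condProd <- function(path, stop) prod(nd$p[path[seq_len(which(path == stop) - 1)]])
  joint <- nd$pi[lca] * condProd(pa, lca) * condProd(pb, lca)
  joint / nd$pi[ia]
}
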