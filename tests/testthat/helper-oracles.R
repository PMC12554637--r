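# Independent oracle implementations used to check the package's
# computations. These are written against explicit node/parent
# specifications with plain loops, deliberately not sharing code with the
# package internals.

# Brute-force posterior over all 2^K leaf configurations for one gene.
# spec: list(parent = integer vector over nodes (NA = root),
#            leafOf = integer leaf index per node (NA for internal),
#            piRoot, p = numeric per node (NA at root))
# ll0, ll1: per-leaf log-likelihoods for the gene.
bruteForcePosterior <- function(spec, ll0, ll1) {
  K <- sum(!is.na(spec$leafOf))
  M <- length(spec$parent)
  root <- which(is.na(spec$parent))
  configs <- expand.grid(rep(list(0:1), K))
  joint <- numeric(nrow(configs))
  # descendant leaves of each node, by upward walks
  descend <- vector("list", M)
  for (n in seq_len(M)) descend[[n]] <- integer(0)
  for (n in seq_len(M)) {
    if (is.na(spec$leafOf[n])) next
    m <- n
    repeat {
      descend[[m]] <- c(descend[[m]], spec$leafOf[n])
      if (is.na(spec$parent[m])) break
      m <- spec$parent[m]
    }
  }
  for (ci in seq_len(nrow(configs))) {
    Z <- as.numeric(configs[ci, ])
    D <- vapply(seq_len(M), function(n) as.numeric(any(Z[descend[[n]]] == 1)),
                numeric(1))
    pr <- if (D[root] == 1) spec$piRoot else 1 - spec$piRoot
    for (n in setdiff(seq_len(M), root)) {
      pa <- spec$parent[n]
      if (D[pa] == 0) {
        if (D[n] != 0) pr <- 0
      } else {
        pr <- pr * if (D[n] == 1) spec$p[n] else 1 - spec$p[n]
      }
    }
    ll <- 0
    for (k in seq_len(K)) ll <- ll + if (Z[k] == 1) ll1[k] else ll0[k]
    joint[ci] <- pr * exp(ll)
  }
  tot <- sum(joint)
  post <- vapply(seq_len(K), function(k)
    sum(joint[configs[, k] == 1]) / tot, numeric(1))
  list(posterior = post, configProb = joint / tot, marginal = tot)
}

# a 3-leaf caterpillar ((L1,L2),L3) with hand-set priors, both as an
# explicit spec for the oracle and as a package CellTypeTree
chainTreePair <- function(piRoot = 0.4, pAB = 0.7, p1 = 0.6, p2 = 0.5, p3 = 0.8) {
  spec <- list(
    parent = c(5L, 5L, 4L, NA, 4L),  # nodes: L1, L2, L3, root, AB
    leafOf = c(1L, 2L, 3L, NA, NA),
    piRoot = piRoot,
    p = c(p1, p2, p3, NA, pAB)
  )
  tree <- readCellTypeTree("((L1,L2),L3);")
  tree <- setTreePriors(tree, piRoot = piRoot,
                        p = c("L1+L2" = pAB, "L1" = p1, "L2" = p2, "L3" = p3))
  list(spec = spec, tree = tree)
}

# random fits object (class GeneModelFits) over given types
randomFits <- function(G, types, scale = 5) {
  mk <- function() matrix(rnorm(G * length(types), sd = scale), G, length(types),
                          dimnames = list(sprintf("g%03d", seq_len(G)), types))
  ll0 <- mk()
  ll1 <- ll0 + matrix(abs(rnorm(G * length(types), sd = scale)), G, length(types))
  structure(list(ll0 = ll0, ll1 = ll1, delta = mk(),
                 sigma2_0 = abs(mk()), sigma2_1 = abs(mk()),
                 nsub = setNames(rep(10L, length(types)), types),
                 cellTypes = types, geneIds = rownames(ll0)),
            class = "GeneModelFits")
}

# small labelled SingleCellExperiment built directly from a dense matrix
makeSCE <- function(counts, subject, cellType, A = NULL) {
  colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(subject = subject, cell_type = cellType,
                                   row.names = colnames(counts)))
  if (!is.null(A))
    S4Vectors::metadata(sce)$design <-
      data.frame(A = A, row.names = unique(subject))
  sce
}
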