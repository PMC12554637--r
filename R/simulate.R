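#' Default six-cell-type simulation tree
#'
#' The generative cell-type hierarchy used by the simulation study:
#' topology `((NK,(B,(CD4,CD8))),(Mono,DC))` with root marginal 0.5 and
#' inheritance probabilities 0.667 for \{NK,B,CD4,CD8\}, 0.8 for
#' \{B,CD4,CD8\}, 0.6 for NK, 0.833 for \{CD4,CD8\}, 0.75 for B, 0.9 for
#' CD4 and CD8, 0.444 for \{Mono,DC\}, 0.9 for Mono and DC. These values
#' make every leaf DE with probability 0.20 marginally, with pairwise DE
#' overlap fractions of 0.90 (CD4-CD8, Mono-DC), 0.75 (B vs CD4/CD8),
#' 0.60 (NK vs CD4/CD8) and 0.40 across the two main clusters.
#'
#' @return a [CellTypeTree-class] with generative priors filled.
#' @export
defaultSimTree <- function() {
  tree <- readCellTypeTree("((NK,(B,(CD4,CD8))),(Mono,DC));")
  setTreePriors(tree, piRoot = 0.5, p = c(
    "B+CD4+CD8+NK" = 0.667,
    "B+CD4+CD8" = 0.8,
    "NK" = 0.6,
    "CD4+CD8" = 0.833,
    "B" = 0.75,
    "CD4" = 0.9,
    "CD8" = 0.9,
    "DC+Mono" = 0.444,
    "Mono" = 0.9,
    "DC" = 0.9
  ))
}

#' Default simulation scenario
#'
#' Parameters of the negative-binomial single-cell simulation: 13,653
#' genes, 20 subjects per group, 200,000 cells over the six cell types of
#' [defaultSimTree()] with tree-correlated DE truth. Per-cell counts
#' follow `NB(s * mu, phi)` with size factor `s ~ U(0, 0.12)`, NB2
#' dispersion `phi = 0.01/mu + 0.05` computed from the unscaled mean, and
#' group-2 means multiplied by `2^lfc` with `lfc ~ N(0.065, 0.12^2)` for
#' DE entries and `N(0, 0.001^2)` otherwise. Baseline means combine a
#' gene-level log-normal expression level with a subject-level
#' multiplicative log-normal effect (the source of the between-subject
#' heterogeneity that makes cell-level tests pseudo-replicated). The DC
#' proportion is 0.01; the remaining proportions are package defaults
#' chosen to resemble whole-blood composition.
#'
#' Any argument can be overridden; `nGenes`, `nSubjectsPerGroup` and
#' `totalCells` are the usual knobs for scaled-down runs.
#'
#' @param nGenes number of genes.
#' @param nSubjectsPerGroup subjects in each of the two outcome groups.
#' @param totalCells total number of cells across all subjects and types.
#' @param proportions named simplex of cell-type proportions (must match
#'   the tree's leaves).
#' @param tree generative [CellTypeTree-class] with priors filled; leaves
#'   independent of each other can be emulated with
#'   `independentLeaves = TRUE`.
#' @param independentLeaves if `TRUE`, DE states are drawn independently
#'   per leaf with the leaf marginal probabilities (no tree coupling).
#' @param lfcDEMean,lfcDESd normal law of the log2 fold change of DE
#'   entries.
#' @param lfcNullMean,lfcNullSd normal law of the residual log2 fold
#'   change of non-DE entries.
#' @param sizeFactorMin,sizeFactorMax uniform law of the per-cell size
#'   factor.
#' @param dispersionFun function mapping the NB mean to the NB2
#'   dispersion.
#' @param baselineMeanLog,baselineSdLog log-normal law of the gene-level
#'   baseline mean (natural-log parameters).
#' @param baselineFloor lower truncation of the gene-level baseline mean.
#' @param subjectEffectSd natural-log standard deviation of the
#'   subject-level multiplicative baseline effect (0 disables subject
#'   heterogeneity).
#' @return a list of class `SimScenario`.
#' @export
defaultScenario <- function(nGenes = 13653,
                            nSubjectsPerGroup = 20,
                            totalCells = 200000,
                            proportions = c(NK = 0.08, B = 0.10, CD4 = 0.35,
                                            CD8 = 0.28, Mono = 0.18, DC = 0.01),
                            tree = defaultSimTree(),
                            independentLeaves = FALSE,
                            lfcDEMean = 0.065, lfcDESd = 0.12,
                            lfcNullMean = 0, lfcNullSd = 0.001,
                            sizeFactorMin = 0, sizeFactorMax = 0.12,
                            dispersionFun = function(mu) 0.01 / mu + 0.05,
                            baselineMeanLog = log(5), baselineSdLog = 1.2,
                            baselineFloor = 0.05,
                            subjectEffectSd = 0.25) {
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (any(proportions <= 0)) stop("proportions must be positive")
  if (!setequal(names(proportions), leafLabels(tree)))
    stop("proportions must be named by the tree's leaf labels")
  if (sizeFactorMax <= sizeFactorMin || sizeFactorMin < 0)
    stop("invalid size-factor range")
  sc <- list(nGenes = nGenes, nSubjectsPerGroup = nSubjectsPerGroup,
             totalCells = totalCells,
             proportions = proportions[leafLabels(tree)],
             tree = tree, independentLeaves = independentLeaves,
             lfcDEMean = lfcDEMean, lfcDESd = lfcDESd,
             lfcNullMean = lfcNullMean, lfcNullSd = lfcNullSd,
             sizeFactorMin = sizeFactorMin, sizeFactorMax = sizeFactorMax,
             dispersionFun = dispersionFun,
             baselineMeanLog = baselineMeanLog, baselineSdLog = baselineSdLog,
             baselineFloor = baselineFloor,
             subjectEffectSd = subjectEffectSd)
  class(sc) <- "SimScenario"
  sc
}

#' Sample ground-truth DE states from the generative tree
#'
#' Top-down sampling of the full generative model: the root state is
#' Bernoulli with the root marginal; every other node is Bernoulli with
#' its inheritance probability when the parent is in state 1 and is 0
#' otherwise. The leaf states form the truth matrix. (Unlike the collapsed
#' enumeration used for inference, this generative pass can set an
#' internal node to 1 with all of its leaves 0.)
#'
#' @param scenario a `SimScenario` (or a [CellTypeTree-class] with priors
#'   filled).
#' @param nGenes number of genes to draw (defaults to the scenario's).
#' @param seed optional integer seed.
#' @return genes x leaves binary matrix of DE states.
#' @export
sampleDEStates <- function(scenario, nGenes = NULL, seed = NULL) {
  tree <- if (is(scenario, "CellTypeTree")) scenario else scenario$tree
  independent <- !is(scenario, "CellTypeTree") && isTRUE(scenario$independentLeaves)
  if (is.null(nGenes))
    nGenes <- if (is(scenario, "CellTypeTree")) stop("supply nGenes") else scenario$nGenes
  if (!is.null(seed)) set.seed(seed)
  nd <- tree@nodes
  if (anyNA(nd$pi)) stop("tree priors are not set")
  leaves <- leafLabels(tree)
  if (independent) {
    marg <- treeLeafMarginals(tree)
    Z <- vapply(leaves, function(k) rbinom(nGenes, 1, marg[k]), numeric(nGenes))
    Z <- matrix(Z, nrow = nGenes, dimnames = list(NULL, leaves))
    return(Z)
  }
  root <- .rootNode(tree)
  state <- matrix(0, nGenes, nrow(nd))
  state[, root] <- rbinom(nGenes, 1, nd$pi[root])
  for (n in .preorder(tree)[-1])
    state[, n] <- rbinom(nGenes, 1, nd$p[n]) * state[, nd$parent[n]]
  Z <- state[, nd$id[nd$leaf], drop = FALSE]
  colnames(Z) <- leaves
  Z
}

#' Simulate a single-cell count dataset with tree-correlated DE truth
#'
#' Generates cell-level negative-binomial counts for two outcome groups
#' following the scenario's laws (see [defaultScenario()]): per gene,
#' subject and cell type a baseline mean `m = geneMean * subjectEffect`;
#' the group-2 mean is `m * 2^lfc`; each cell's count is
#' `NB(s * mu, phi)` with its own uniform size factor `s` and NB2
#' dispersion `phi(mu)` from the unscaled mean. Cells are allocated to
#' each (subject, type) pair deterministically from the cell-type
#' proportions.
#'
#' @param scenario a `SimScenario` from [defaultScenario()].
#' @param seed integer seed (identical seeds give identical datasets).
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay, colData columns `subject`, `cell_type`, `group`, and
#'   `metadata()` entries `truthZ` (genes x types binary), `truthLfc`
#'   (genes x types log2 fold changes), `design` (per-subject data.frame
#'   with binary `A`) and `scenario`.
#' @export
simulateDataset <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "SimScenario"))
  set.seed(seed)
  G <- scenario$nGenes
  types <- names(scenario$proportions)
  K <- length(types)
  N <- 2L * scenario$nSubjectsPerGroup
  subjects <- sprintf("S%02d", seq_len(N))
  A <- rep(c(0, 1), each = scenario$nSubjectsPerGroup)
  geneIds <- sprintf("g%05d", seq_len(G))

  Z <- sampleDEStates(scenario, nGenes = G)
  lfc <- matrix(rnorm(G * K, scenario$lfcNullMean, scenario$lfcNullSd),
                G, K, dimnames = list(geneIds, types))
  nde <- sum(Z == 1)
  lfc[Z == 1] <- rnorm(nde, scenario$lfcDEMean, scenario$lfcDESd)
  rownames(Z) <- geneIds

  geneMean <- pmax(rlnorm(G, scenario$baselineMeanLog, scenario$baselineSdLog),
                   scenario$baselineFloor)
  cellsPerSubject <- scenario$totalCells / N
  nPerType <- pmax(1L, as.integer(round(cellsPerSubject * scenario$proportions)))
  names(nPerType) <- types

  nBlocks <- N * K
  ti <- vector("list", nBlocks); tj <- vector("list", nBlocks)
  tx <- vector("list", nBlocks); meta <- vector("list", nBlocks)
  b <- 0L; cellsSoFar <- 0L
  for (i in seq_len(N)) {
    for (k in seq_len(K)) {
      nCells <- nPerType[k]
      subjEff <- if (scenario$subjectEffectSd > 0)
        rlnorm(G, 0, scenario$subjectEffectSd) else rep(1, G)
      m <- geneMean * subjEff
      mu <- if (A[i] == 1) m * 2^lfc[, k] else m
      if (any(mu <= 0)) stop("nonpositive simulated mean")
      phi <- scenario$dispersionFun(mu)
      s <- runif(nCells, scenario$sizeFactorMin, scenario$sizeFactorMax)
      cnt <- rnbinom(G * nCells, mu = outer(mu, s), size = rep(1 / phi, nCells))
      nz <- which(cnt > 0)
      b <- b + 1L
      ti[[b]] <- (nz - 1L) %% G + 1L
      tj[[b]] <- cellsSoFar + (nz - 1L) %/% G + 1L
      tx[[b]] <- cnt[nz]
      meta[[b]] <- data.frame(subject = subjects[i], cell_type = types[k],
                              group = A[i],
                              stringsAsFactors = FALSE)[rep(1, nCells), ]
      cellsSoFar <- cellsSoFar + nCells
    }
  }
  cellIds <- sprintf("cell%06d", seq_len(cellsSoFar))
  counts <- sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                         dims = c(G, cellsSoFar),
                         dimnames = list(geneIds, cellIds))
  cd <- do.call(rbind, meta)
  rownames(cd) <- cellIds
  design <- data.frame(A = A, row.names = subjects)
  sce <- SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(cd)
  )
  metadata(sce) <- list(truthZ = Z, truthLfc = lfc, design = design,
                        scenario = scenario, seed = seed)
  sce
}
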