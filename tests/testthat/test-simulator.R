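test_that("the default scenario encodes the designed study conditions", {
  sc <- defaultScenario()
  expect_equal(sc$nGenes, 13653)
  expect_equal(sc$nSubjectsPerGroup, 20)
  expect_equal(sc$totalCells, 200000)
  expect_equal(sum(sc$proportions), 1)
  expect_equal(unname(sc$proportions["DC"]), 0.01)
  tab <- priorTable(sc$tree)
  expect_equal(tab$pi[!tab$leaf & grepl("\\+.*\\+.*\\+.*\\+", tab$label)], 0.5)
  expect_equal(unname(treeLeafMarginals(sc$tree)), rep(0.2, 6), tolerance = 1e-3)
  expect_equal(sc$dispersionFun(1), 0.06)    # 0.01/mu + 0.05 at mu = 1
  expect_error(defaultScenario(proportions = c(NK = 0.5, B = 0.6)),
               "sum to 1")
})

test_that("DE-state sampling follows the generative tree", {
  tr0 <- setTreePriors(readCellTypeTree("(a,b);"), piRoot = 0,
                       p = c(a = 0.5, b = 0.5))
  expect_true(all(sampleDEStates(tr0, nGenes = 100, seed = 1) == 0))
  tr1 <- setTreePriors(readCellTypeTree("(a,b);"), piRoot = 1,
                       p = c(a = 1, b = 1))
  expect_true(all(sampleDEStates(tr1, nGenes = 100, seed = 1) == 1))

  Z <- sampleDEStates(defaultSimTree(), nGenes = 50000, seed = 91)
  expect_equal(unname(colMeans(Z)), rep(0.2, 6), tolerance = 0.01)
  expect_equal(sum(Z[, "CD4"] & Z[, "CD8"]) / sum(Z[, "CD4"]), 0.90,
               tolerance = 0.02)
  expect_equal(sum(Z[, "B"] & Z[, "CD4"]) / sum(Z[, "B"]), 0.75,
               tolerance = 0.02)
  expect_equal(sum(Z[, "NK"] & Z[, "Mono"]) / sum(Z[, "NK"]), 0.40,
               tolerance = 0.02)

  # independent leaves keep the marginals but lose the coupling
  sc <- defaultScenario(nGenes = 50000, independentLeaves = TRUE)
  Zi <- sampleDEStates(sc, seed = 92)
  expect_equal(unname(colMeans(Zi)), rep(0.2, 6), tolerance = 0.01)
  expect_equal(sum(Zi[, "CD4"] & Zi[, "CD8"]) / sum(Zi[, "CD4"]), 0.20,
               tolerance = 0.02)
})

test_that("simulated datasets are reproducible and structurally sound", {
  sc <- defaultScenario(nGenes = 100, nSubjectsPerGroup = 3, totalCells = 600,
                        proportions = c(NK = 0.3, B = 0.2, CD4 = 0.2, CD8 = 0.1,
                                        Mono = 0.1, DC = 0.1))
  sce1 <- simulateDataset(sc, seed = 5)
  sce2 <- simulateDataset(sc, seed = 5)
  expect_identical(as.matrix(SummarizedExperiment::assay(sce1)),
                   as.matrix(SummarizedExperiment::assay(sce2)))
  expect_identical(S4Vectors::metadata(sce1)$truthZ,
                   S4Vectors::metadata(sce2)$truthZ)
  sce3 <- simulateDataset(sc, seed = 6)
  expect_false(identical(as.matrix(SummarizedExperiment::assay(sce1)),
                         as.matrix(SummarizedExperiment::assay(sce3))))

  cnt <- SummarizedExperiment::assay(sce1)
  expect_true(all(cnt >= 0))
  expect_true(all(cnt == round(cnt)))
  cd <- as.data.frame(SummarizedExperiment::colData(sce1))
  expect_equal(length(unique(cd$subject)), 6)
  expect_setequal(unique(cd$cell_type), names(sc$proportions))
  # group labels constant within subject
  expect_true(all(tapply(cd$group, cd$subject, function(g) length(unique(g))) == 1))
})

test_that("count moments follow the NB2 law and its Poisson limit", {
  # fixed mean and dispersion, many cells of one subject/type
  sc <- defaultScenario(nGenes = 200, nSubjectsPerGroup = 1, totalCells = 4000,
                        proportions = c(NK = 0.995, B = 0.001, CD4 = 0.001,
                                        CD8 = 0.001, Mono = 0.001, DC = 0.001),
                        subjectEffectSd = 0, baselineSdLog = 0,
                        baselineMeanLog = log(5),
                        sizeFactorMin = 0.5, sizeFactorMax = 0.5000001,
                        lfcDESd = 0, lfcDEMean = 0, lfcNullSd = 0)
  sce <- simulateDataset(sc, seed = 7)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  sel <- cd$cell_type == "NK" & cd$subject == "S01"
  x <- as.matrix(SummarizedExperiment::assay(sce))[, sel]
  mu <- 0.5 * 5                        # s * gene mean
  phi <- 0.01 / 5 + 0.05               # from the unscaled mean
  expect_equal(mean(rowMeans(x)), mu, tolerance = 0.05)
  expect_equal(mean(apply(x, 1, var)), mu + phi * mu^2, tolerance = 0.1)

  # dispersion override to ~0 gives Poisson moments (variance ~ mean)
  scP <- defaultScenario(nGenes = 200, nSubjectsPerGroup = 1, totalCells = 4000,
                         proportions = sc$proportions, subjectEffectSd = 0,
                         baselineSdLog = 0, baselineMeanLog = log(5),
                         sizeFactorMin = 0.5, sizeFactorMax = 0.5000001,
                         lfcDESd = 0, lfcDEMean = 0, lfcNullSd = 0,
                         dispersionFun = function(mu) 1e-8)
  sceP <- simulateDataset(scP, seed = 8)
  xP <- as.matrix(SummarizedExperiment::assay(sceP))[, sel]
  expect_equal(mean(apply(xP, 1, var)) / mean(rowMeans(xP)), 1, tolerance = 0.1)
})

test_that("realized fold changes follow the configured laws", {
  sc <- defaultScenario(nGenes = 4000, nSubjectsPerGroup = 2, totalCells = 400,
                        proportions = c(NK = 0.3, B = 0.2, CD4 = 0.2, CD8 = 0.1,
                                        Mono = 0.1, DC = 0.1))
  sce <- simulateDataset(sc, seed = 9)
  md <- S4Vectors::metadata(sce)
  de <- md$truthLfc[md$truthZ == 1]
  null <- md$truthLfc[md$truthZ == 0]
  # folded-normal mean of N(0.065, 0.12^2) within Monte-Carlo error
  foldedMean <- function(m, s) s * sqrt(2 / pi) * exp(-m^2 / (2 * s^2)) +
    m * (1 - 2 * pnorm(-m / s))
  expect_equal(mean(abs(de)), foldedMean(0.065, 0.12), tolerance = 0.01)
  expect_equal(sd(null), 0.001, tolerance = 0.05)
  expect_lt(abs(mean(null)), 1e-4)

  # null dataset: no lfc anywhere, screening p-values approximately uniform
  scNull <- defaultScenario(nGenes = 1000, nSubjectsPerGroup = 6,
                            totalCells = 3000,
                            proportions = c(NK = 0.9, B = 0.02, CD4 = 0.02,
                                            CD8 = 0.02, Mono = 0.02, DC = 0.02),
                            lfcDEMean = 0, lfcDESd = 0, lfcNullSd = 0,
                            subjectEffectSd = 0)
  sceN <- simulateDataset(scNull, seed = 10)
  pb <- logNormalize(aggregateCounts(sceN))
  scr <- screenDE(pb, method = "ols_t")
  pv <- screenPvals(scr)[, "NK"]
  ks <- suppressWarnings(ks.test(pv[!is.na(pv)], "punif"))
  expect_gt(ks$p.value, 0.01)
})
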