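pbForFit <- function(Y, A, C = NULL) {
  subjects <- colnames(Y)
  design <- data.frame(A = A, row.names = subjects)
  covn <- character(0)
  if (!is.null(C)) { design$C1 <- C; covn <- "C1" }
  new("PseudoBulkSet",
      raw = list(t1 = matrix(1, nrow(Y), ncol(Y), dimnames = dimnames(Y))),
      norm = list(t1 = Y), subjects = list(t1 = subjects), design = design,
      factorName = "A", covariateNames = covn, geneIds = rownames(Y),
      missingPairs = data.frame(subject = character(0), cell_type = character(0)))
}

test_that("gene model fits solve the normal equations with MLE variances", {
  set.seed(31)
  G <- 20; n <- 15
  Y <- matrix(rnorm(G * n), G, n,
              dimnames = list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:n)))
  A <- rep(c(0, 1), length.out = n)
  C <- rnorm(n)
  fits <- fitGeneModels(pbForFit(Y, A, C))
  X1 <- cbind(1, C, A)
  X0 <- cbind(1, C)
  for (g in c(1, 7, 20)) {
    y <- Y[g, ]
    beta1 <- solve(t(X1) %*% X1, t(X1) %*% y)
    r1 <- y - X1 %*% beta1
    s21 <- sum(r1^2) / n
    expect_equal(unname(fits$delta[g, "t1"]), beta1[3], tolerance = 1e-10)
    expect_equal(unname(fits$sigma2_1[g, "t1"]), s21, tolerance = 1e-10)
    expect_equal(unname(fits$ll1[g, "t1"]),
                 sum(dnorm(y, X1 %*% beta1, sqrt(s21), log = TRUE)),
                 tolerance = 1e-8)
    beta0 <- solve(t(X0) %*% X0, t(X0) %*% y)
    s20 <- sum((y - X0 %*% beta0)^2) / n
    expect_equal(unname(fits$ll0[g, "t1"]),
                 sum(dnorm(y, X0 %*% beta0, sqrt(s20), log = TRUE)),
                 tolerance = 1e-8)
  }
  # nesting: alternative never fits worse
  expect_true(all(fits$ll1 >= fits$ll0))
})

test_that("degenerate fits hit the variance floor or collapse to the null", {
  n <- 10
  A <- rep(c(0, 1), each = n / 2)
  subj <- sprintf("s%02d", 1:n)
  # exactly linear in A: floored variance, finite capped log-likelihood
  Y <- matrix(2 + 3 * A, 1, n, dimnames = list("g1", subj))
  fits <- fitGeneModels(pbForFit(Y, A))
  expect_equal(unname(fits$delta["g1", "t1"]), 3, tolerance = 1e-8)
  expect_equal(unname(fits$sigma2_1["g1", "t1"]), 1e-8)
  expect_true(is.finite(fits$ll1["g1", "t1"]))

  # factor orthogonal to the response: zero effect, equal likelihoods
  set.seed(32)
  y <- rnorm(n); y <- y - mean(y)
  Ac <- A - mean(A)
  y <- y - sum(y * Ac) / sum(Ac^2) * Ac   # orthogonalize against A
  Y2 <- matrix(y, 1, n, dimnames = list("g1", subj))
  fits2 <- fitGeneModels(pbForFit(Y2, A))
  expect_equal(unname(fits2$delta["g1", "t1"]), 0, tolerance = 1e-10)
  expect_equal(fits2$ll1["g1", "t1"], fits2$ll0["g1", "t1"], tolerance = 1e-10)
})

test_that("configuration log-likelihood is additive over cell types", {
  set.seed(33)
  fits <- randomFits(5, c("a", "b", "c"))
  z0 <- c(0, 0, 0)
  expect_equal(configLogLik(fits, 2, z0), sum(fits$ll0[2, ]))
  z1 <- c(0, 1, 0)
  expect_equal(configLogLik(fits, 2, z1),
               configLogLik(fits, 2, z0) + fits$ll1[2, "b"] - fits$ll0[2, "b"])
  # direct density-product style recomputation for an arbitrary configuration
  z <- c(1, 0, 1)
  expect_equal(configLogLik(fits, 4, z),
               fits$ll1[4, "a"] + fits$ll0[4, "b"] + fits$ll1[4, "c"])
})

test_that("posteriors match Bayes' rule for a single leaf", {
  tr <- buildTree(matrix(0, 1, 1, dimnames = list("a", "a"))) |>
    suppressWarnings()
  tr@nodes$pi <- c(0.3, 0.3)
  tr@nodes$p <- c(1, NA)
  set.seed(34)
  fits <- randomFits(20, "a")
  post <- computePosteriors(fits, tr)
  L1 <- exp(fits$ll1[, "a"]); L0 <- exp(fits$ll0[, "a"])
  expect_equal(unname(posteriorProb(post)[, "a"]),
               unname(0.3 * L1 / (0.3 * L1 + 0.7 * L0)), tolerance = 1e-10)
})

test_that("posterior enumeration matches the brute-force oracle", {
  set.seed(35)
  pair <- chainTreePair(piRoot = 0.35, pAB = 0.8, p1 = 0.55, p2 = 0.65, p3 = 0.75)
  fits <- randomFits(30, c("L1", "L2", "L3"))
  post <- computePosteriors(fits, pair$tree)
  for (g in seq_len(30)) {
    oracle <- bruteForcePosterior(pair$spec, fits$ll0[g, ], fits$ll1[g, ])
    expect_equal(unname(posteriorProb(post)[g, c("L1", "L2", "L3")]),
                 oracle$posterior, tolerance = 1e-10)
    expect_equal(sum(oracle$configProb), 1, tolerance = 1e-10)
  }
})

test_that("flat likelihoods return the renormalized prior marginals", {
  pair <- chainTreePair()
  types <- c("L1", "L2", "L3")
  ll <- matrix(-5, 4, 3, dimnames = list(sprintf("g%d", 1:4), types))
  fits <- structure(list(ll0 = ll, ll1 = ll, delta = ll * 0,
                         sigma2_0 = ll * 0 + 1, sigma2_1 = ll * 0 + 1,
                         nsub = setNames(rep(10L, 3), types),
                         cellTypes = types, geneIds = rownames(ll)),
                    class = "GeneModelFits")
  post <- computePosteriors(fits, pair$tree)
  cfg <- treeDE:::.enumerateConfigs(pair$tree)
  pri <- exp(cfg$logPrior) / sum(exp(cfg$logPrior))
  for (k in types)
    expect_equal(unname(posteriorProb(post)[1, k]),
                 sum(pri[cfg$Z[, k] == 1]), tolerance = 1e-10)
})

test_that("posteriors are monotone in the evidence and numerically stable", {
  pair <- chainTreePair()
  types <- c("L1", "L2", "L3")
  base <- matrix(0, 1, 3, dimnames = list("g1", types))
  mkFits <- function(d1) {
    ll1 <- base; ll1[1, "L1"] <- d1
    structure(list(ll0 = base, ll1 = ll1, delta = base,
                   sigma2_0 = base + 1, sigma2_1 = base + 1,
                   nsub = setNames(rep(10L, 3), types),
                   cellTypes = types, geneIds = "g1"),
              class = "GeneModelFits")
  }
  ds <- c(0, 1, 3, 10, 100, 1e4)
  ps <- vapply(ds, function(d)
    posteriorProb(computePosteriors(mkFits(d), pair$tree))[1, "L1"], numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
  expect_true(all(is.finite(ps)))
  expect_equal(ps[length(ps)], 1, tolerance = 1e-10)
  # extreme negative evidence underflows gracefully to 0
  pneg <- posteriorProb(computePosteriors(mkFits(-1e4), pair$tree))[1, "L1"]
  expect_equal(unname(pneg), 0, tolerance = 1e-10)
})

test_that("enumeration refuses trees beyond the configured leaf budget", {
  lab <- sprintf("t%02d", 1:5)
  nw <- paste0("(", paste(lab, collapse = ","), ");")
  tr <- readCellTypeTree(nw)
  tr@nodes$pi <- c(rep(0.2, 5), 0.5)
  tr@nodes$p <- c(rep(0.4, 5), NA)
  fits <- randomFits(3, lab)
  expect_error(computePosteriors(fits, tr, kMax = 4), "refused")
  expect_s4_class(computePosteriors(fits, tr, kMax = 8), "DEPosterior")
})

test_that("DE calls respect the strict cutoff and ranking rules", {
  post <- new("DEPosterior",
              posterior = matrix(c(0.951, 0.95, 0.4, 0.96), 4, 1,
                                 dimnames = list(c("g1", "g2", "g3", "g4"), "a")),
              logMarginal = rep(0, 4),
              delta = matrix(0, 4, 1, dimnames = list(c("g1", "g2", "g3", "g4"), "a")),
              tree = chainTreePair()$tree)
  calls <- callDEGenes(post, cutoff = 0.95)
  expect_equal(calls$a$gene[calls$a$called], c("g4", "g1"))  # strict >, ranked
  expect_false(calls$a$called[calls$a$gene == "g2"])         # boundary excluded
  callsAll <- callDEGenes(post, cutoff = 1e-6)
  expect_true(all(callsAll$a$called))
})

test_that("the model recovers its own effects and power grows with effect size", {
  set.seed(36)
  n <- 24; G <- 120
  A <- rep(c(0, 1), each = n / 2)
  subj <- sprintf("s%02d", 1:n)
  deltas <- rep(c(0, 0.5, 1, 2), each = G / 4)
  Y <- matrix(rnorm(G * n, sd = 1), G, n, dimnames = list(sprintf("g%03d", 1:G), subj))
  Y <- Y + outer(deltas, A)
  pb <- pbForFit(Y, A)
  fits <- fitGeneModels(pb)
  # effect recovery: unbiased within Monte-Carlo error per block
  for (d in unique(deltas)) {
    est <- fits$delta[deltas == d, "t1"]
    expect_lt(abs(mean(est) - d), 4 * sd(est) / sqrt(length(est)))
  }
  tr <- suppressWarnings(buildTree(matrix(0, 1, 1, dimnames = list("t1", "t1"))))
  tr@nodes$pi <- c(0.25, 0.25); tr@nodes$p <- c(1, NA)
  post <- posteriorProb(computePosteriors(fits, tr))[, "t1"]
  meanPost <- tapply(post, deltas, mean)
  expect_true(all(diff(meanPost) > 0))   # power monotone in |delta|/sigma
  expect_gt(meanPost["2"], 0.95)
  expect_lt(meanPost["0"], 0.5)
})
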