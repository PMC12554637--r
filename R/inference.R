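#' Fit per-gene null and alternative Gaussian models
#'
#' For every gene and cell type two nested linear models are fitted to the
#' log-normalized pseudo-bulk values of that cell type's subjects: the
#' null (intercept and covariates) and the alternative (plus the tested
#' factor). Coefficients are ordinary least squares; the variance is the
#' maximum-likelihood estimate RSS/N per hypothesis, floored at
#' `varFloor` so that perfect fits cannot contribute unbounded likelihood.
#' The per-hypothesis Gaussian log-likelihood of the cell type's data is
#' stored; since the models are nested and both maximized, the alternative
#' log-likelihood is never below the null.
#'
#' @param pb a normalized [PseudoBulkSet-class]. Each cell type must have
#'   more subjects than model parameters.
#' @param varFloor lower bound on the variance estimates (default 1e-8).
#'
#' @return an object of class `GeneModelFits`: a list with genes x types
#'   matrices `ll0`, `ll1` (log-likelihoods), `delta` (tested-factor
#'   effect under the alternative), `sigma2_0`, `sigma2_1`, and `nsub`
#'   (subjects per type).
#' @export
fitGeneModels <- function(pb, varFloor = 1e-8) {
  stopifnot(is(pb, "PseudoBulkSet"))
  if (!length(pb@norm)) stop("run logNormalize() first")
  types <- names(pb@raw)
  G <- length(pb@geneIds)
  mk <- function() matrix(NA_real_, G, length(types),
                          dimnames = list(pb@geneIds, types))
  ll0 <- mk(); ll1 <- mk(); delta <- mk(); s20 <- mk(); s21 <- mk()
  nsub <- setNames(integer(length(types)), types)
  for (k in types) {
    subj <- pb@subjects[[k]]
    n <- length(subj)
    nsub[k] <- n
    X1 <- .designMatrix(pb, subj)
    acol <- attr(X1, "acol")
    X0 <- X1[, -acol, drop = FALSE]
    if (n <= ncol(X1))
      stop(sprintf("cell type '%s' has %d subjects for %d parameters", k, n, ncol(X1)))
    tY <- t(pb@norm[[k]])                     # n x G
    f0 <- .olsLoglik(X0, tY, n, varFloor)
    q1 <- qr(X1)
    if (q1$rank < ncol(X1)) {
      warning(sprintf("rank-deficient alternative design for '%s'; using null fit", k))
      f1 <- f0
      d <- rep(0, G)
    } else {
      f1 <- .olsLoglik(X1, tY, n, varFloor)
      d <- qr.coef(q1, tY)[acol[1L], ]
    }
    ll0[, k] <- f0$ll; s20[, k] <- f0$s2
    ll1[, k] <- pmax(f1$ll, f0$ll); s21[, k] <- f1$s2
    delta[, k] <- d
  }
  structure(list(ll0 = ll0, ll1 = ll1, delta = delta,
                 sigma2_0 = s20, sigma2_1 = s21, nsub = nsub,
                 cellTypes = types, geneIds = pb@geneIds),
            class = "GeneModelFits")
}

.olsLoglik <- function(X, tY, n, varFloor) {
  rss <- colSums(qr.resid(qr(X), tY)^2)
  s2 <- pmax(rss / n, varFloor)
  ll <- -n / 2 * log(2 * pi * s2) - rss / (2 * s2)
  list(ll = ll, s2 = s2)
}

#' Configuration log-likelihood
#'
#' Log-likelihood of one gene's data under a given leaf DE-state
#' configuration: the likelihood factorizes over cell types (and subjects
#' within each type), so it is the sum over types of the stored null or
#' alternative log-likelihood according to `Z`.
#'
#' @param fits a `GeneModelFits` object from [fitGeneModels()].
#' @param gene gene identifier or index.
#' @param Z binary vector over cell types (ordered like
#'   `fits$cellTypes`, or named).
#' @return the log-likelihood value.
#' @export
configLogLik <- function(fits, gene, Z) {
  stopifnot(inherits(fits, "GeneModelFits"))
  if (length(Z) != length(fits$cellTypes))
    stop("Z must have length ", length(fits$cellTypes))
  if (!is.null(names(Z))) Z <- Z[fits$cellTypes]
  l0 <- fits$ll0[gene, ]; l1 <- fits$ll1[gene, ]
  sum(ifelse(Z == 1, l1, l0))
}

#' Posterior DE probabilities by exact enumeration
#'
#' For each gene, the joint log-probability of the data and every one of
#' the 2^K leaf DE-state configurations is assembled as configuration
#' log-likelihood plus tree-prior log-probability; the log marginal
#' likelihood is the log-sum-exp over configurations, and each cell type's
#' posterior DE probability is the log-sum-exp over configurations with
#' that leaf in state 1, minus the log marginal. The enumeration is exact;
#' trees with more than `kMax` leaves are refused rather than
#' approximated.
#'
#' @param fits a `GeneModelFits` object from [fitGeneModels()].
#' @param tree a [CellTypeTree-class] with priors filled, leaves matching
#'   the fitted cell types.
#' @param kMax refuse enumeration beyond this many leaves (default 16).
#' @return a [DEPosterior-class].
#' @export
computePosteriors <- function(fits, tree, kMax = 16) {
  stopifnot(inherits(fits, "GeneModelFits"), is(tree, "CellTypeTree"))
  leaves <- leafLabels(tree)
  if (!setequal(leaves, fits$cellTypes))
    stop("tree leaves and fitted cell types differ")
  K <- length(leaves)
  if (K > kMax)
    stop("exact enumeration over 2^", K, " configurations refused; ",
         "supply a smaller tree or raise kMax explicitly")
  cfg <- .enumerateConfigs(tree)
  ll0 <- fits$ll0[, leaves, drop = FALSE]
  ll1 <- fits$ll1[, leaves, drop = FALSE]
  bad <- is.na(ll0) | is.na(ll1)
  if (any(bad)) {
    warning(sum(bad), " gene-type fits missing; they contribute no evidence")
    ll0[bad] <- 0; ll1[bad] <- 0
  }
  G <- nrow(ll0)
  base <- rowSums(ll0)
  diff <- ll1 - ll0
  post <- matrix(NA_real_, G, K, dimnames = list(fits$geneIds, leaves))
  logMarg <- numeric(G)
  nconf <- nrow(cfg$Z)
  chunk <- max(1L, min(G, as.integer(2^22 / nconf)))
  for (start in seq(1L, G, by = chunk)) {
    idx <- start:min(start + chunk - 1L, G)
    lj <- base[idx] + diff[idx, , drop = FALSE] %*% t(cfg$Z)
    lj <- sweep(lj, 2, cfg$logPrior, "+")
    lm <- rowLogSumExp(lj)
    logMarg[idx] <- lm
    for (k in seq_len(K)) {
      on <- cfg$Z[, k] == 1
      post[idx, k] <- exp(rowLogSumExp(lj[, on, drop = FALSE]) - lm)
    }
  }
  new("DEPosterior", posterior = post, logMarginal = logMarg,
      delta = fits$delta[, leaves, drop = FALSE], tree = tree)
}

#' Call DE genes from posterior probabilities
#'
#' A gene is called DE in a cell type when its posterior probability
#' strictly exceeds `cutoff` (default 0.95). Per cell type, genes are
#' returned ranked by decreasing posterior, ties broken by gene
#' identifier.
#'
#' @param post a [DEPosterior-class].
#' @param cutoff posterior probability cutoff in (0, 1).
#' @return named list (per cell type) of data.frames with columns `gene`,
#'   `posterior`, `delta`, `called`.
#' @export
callDEGenes <- function(post, cutoff = 0.95) {
  stopifnot(is(post, "DEPosterior"))
  .assertScalarNumber(cutoff, "cutoff", lower = 1e-12, upper = 1 - 1e-12)
  out <- list()
  for (k in cellTypes(post)) {
    df <- data.frame(gene = geneIds(post),
                     posterior = post@posterior[, k],
                     delta = post@delta[, k],
                     stringsAsFactors = FALSE)
    df$called <- df$posterior > cutoff
    df <- df[order(-df$posterior, df$gene), ]
    rownames(df) <- NULL
    out[[k]] <- df
  }
  out
}
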