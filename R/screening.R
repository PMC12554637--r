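#' First-pass per-cell-type differential expression screen
#'
#' Produces one signed statistic and two-sided p-value per gene per cell
#' type, testing the effect of the factor of interest. These feed the tree
#' construction ([buildTree()]) and prior estimation ([estimatePriors()]).
#' Two backends are available:
#'
#' * `"nb_wald"` (default): a negative-binomial GLM Wald test on the raw
#'   pseudo-bulk counts with a log library-size offset, per cell type. The
#'   NB dispersion is estimated per gene by method of moments (floored at
#'   1e-8) and held fixed during the GLM fit; no shrinkage is applied.
#' * `"ols_t"`: the t statistic of the tested-factor coefficient from an
#'   ordinary least-squares fit of the log-normalized pseudo-bulk values on
#'   intercept, covariates and the factor. With no covariates and a binary
#'   factor this is the classical pooled-variance two-sample t statistic.
#'
#' The sign convention is the same for both: a positive statistic means a
#' positive coefficient of the tested factor.
#'
#' @param pb a normalized [PseudoBulkSet-class].
#' @param method `"nb_wald"` or `"ols_t"`.
#'
#' @return a [ScreenResult-class]. Cell types whose design is degenerate
#'   (constant factor among that type's subjects) get all-`NA` columns with
#'   a warning; individual failed fits are `NA` with a reported count.
#' @export
screenDE <- function(pb, method = c("nb_wald", "ols_t")) {
  stopifnot(is(pb, "PseudoBulkSet"))
  method <- match.arg(method)
  types <- names(pb@raw)
  G <- length(pb@geneIds)
  tstat <- matrix(NA_real_, G, length(types),
                  dimnames = list(pb@geneIds, types))
  pval <- tstat
  nfail <- 0L
  for (k in types) {
    subj <- pb@subjects[[k]]
    X <- .designMatrix(pb, subj)
    a <- attr(X, "acol")[1L]
    if (length(unique(X[, a])) < 2 || nrow(X) <= ncol(X)) {
      warning(sprintf("degenerate design for cell type '%s'; statistics set missing", k))
      next
    }
    res <- if (method == "ols_t") {
      .screenOLS(normExpr(pb, k), X, a)
    } else {
      .screenNBWald(rawCounts(pb, k), X, a)
    }
    tstat[, k] <- res$stat
    pval[, k] <- res$p
    nfail <- nfail + sum(is.na(res$stat))
  }
  if (nfail > 0)
    message(sprintf("screenDE: %d gene-by-type fits failed or were degenerate (NA)", nfail))
  new("ScreenResult", tstat = tstat, pval = pval, method = method)
}

# design matrix (intercept, covariates, tested factor) for a subject subset;
# attribute "acol" marks the tested-factor column(s)
.designMatrix <- function(pb, subjects) {
  d <- pb@design[subjects, , drop = FALSE]
  C <- if (length(pb@covariateNames))
    as.matrix(d[, pb@covariateNames, drop = FALSE]) else NULL
  A <- as.matrix(d[, pb@factorName, drop = FALSE])
  X <- cbind("(Intercept)" = 1, C, A)
  attr(X, "acol") <- seq.int(ncol(X) - ncol(A) + 1L, ncol(X))
  X
}

# vectorized OLS t-statistics for all genes of one cell type
.screenOLS <- function(Y, X, a) {
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  tY <- t(Y)                       # n x G
  resid <- qr.resid(qrX, tY)
  rss <- colSums(resid^2)
  cf <- qr.coef(qrX, tY)           # p x G
  xtxinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  df <- n - p
  s2 <- rss / df
  se <- sqrt(pmax(s2 * xtxinv[a, a], 1e-300))
  stat <- cf[a, ] / se
  # no-variation genes: zero residuals and zero effect => no signal
  flat <- rss < 1e-12 & abs(cf[a, ]) < 1e-8
  stat[flat] <- 0
  p <- 2 * pt(-abs(stat), df = df)
  list(stat = unname(stat), p = unname(p))
}

# per-gene NB GLM Wald z with fixed method-of-moments dispersion
.screenNBWald <- function(raw, X, a) {
  n <- nrow(X)
  lib <- colSums(raw)
  off <- log(lib)
  G <- nrow(raw)
  stat <- rep(NA_real_, G); p <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    y <- raw[g, ]
    if (sum(y) == 0) next
    mu0 <- lib * (sum(y) / sum(lib))
    phi <- (sum((y - mu0)^2) - sum(mu0)) / sum(mu0^2)
    phi <- max(phi, 1e-8)
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, offset = off,
        family = MASS::negative.binomial(theta = 1 / phi))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) next
    w <- fit$weights
    cov <- tryCatch(chol2inv(chol(crossprod(X * sqrt(w)))), error = function(e) NULL)
    if (is.null(cov)) next
    se <- sqrt(cov[a, a])
    if (!is.finite(se) || se <= 0) next
    z <- fit$coefficients[a] / se
    stat[g] <- z
    p[g] <- 2 * pnorm(-abs(z))
  }
  list(stat = stat, p = p)
}
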