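#' Precision-recall curve and area under it
#'
#' Genes are ranked by decreasing score; at every distinct score value the
#' precision and recall of calling all genes at or above it are recorded
#' (tied scores are grouped, so ties enter the curve together). The AUC is
#' the trapezoidal integral of precision over recall, starting from recall
#' 0 at the precision of the top-scoring group.
#'
#' @param scores per-gene ranking values (larger = more likely DE).
#' @param truth binary vector of the same length (1 = truly DE).
#' @return list with `curve` (data.frame of `recall`, `precision`,
#'   `threshold`) and `auc`.
#' @export
prAUC <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]; truth <- as.numeric(truth[keep])
  P <- sum(truth == 1)
  if (P == 0 || P == length(truth))
    stop("truth must contain at least one positive and one negative")
  if (length(unique(scores)) == 1L) {
    warning("all scores identical; single-point PR curve, AUC = prevalence")
    prev <- P / length(truth)
    return(list(curve = data.frame(recall = 1, precision = prev,
                                   threshold = scores[1]),
                auc = prev))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tied group
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / P
  precision <- tp / (tp + fp)
  auc <- sum(diff(c(0, recall)) * (precision + c(precision[1], head(precision, -1))) / 2)
  list(curve = data.frame(recall = recall, precision = precision,
                          threshold = s[last]),
       auc = auc)
}

#' Observed false discovery rate against simulation truth
#'
#' Fraction of called genes that are truly null. An empty call set has
#' observed FDR 0 by convention.
#'
#' @param called character vector (or logical/integer index) of called
#'   genes.
#' @param truth named binary vector over the gene universe (1 = truly DE).
#' @return a number in \[0, 1\].
#' @export
observedFDR <- function(called, truth) {
  if (is.logical(called)) called <- which(called)
  if (length(called) == 0) return(0)
  tv <- if (is.character(called)) truth[called] else truth[called]
  if (anyNA(tv)) stop("called genes missing from truth")
  sum(tv == 0) / length(called)
}

#' Overlap rate of two DE gene sets
#'
#' `|A intersect B| / |A|`, with `setA` the reference set (e.g. calls on
#' the original data when comparing against a permuted or subsampled
#' re-analysis); 0 when the reference is empty.
#'
#' @param setA,setB character vectors of gene identifiers.
#' @return a number in \[0, 1\].
#' @export
overlapRate <- function(setA, setB) {
  if (length(setA) == 0) return(0)
  length(intersect(setA, setB)) / length(unique(setA))
}

#' Rediscovery rate between a training and a validation analysis
#'
#' The fraction of DE genes called in the training dataset that are called
#' again in an independent validation dataset: `R_v / R_t` where `R_t` is
#' the training call count and `R_v` the number of those re-detected.
#'
#' @param trainCalled,validationCalled character vectors of gene
#'   identifiers.
#' @return a number in \[0, 1\] (0 when no training calls).
#' @export
rediscoveryRate <- function(trainCalled, validationCalled) {
  trainCalled <- unique(trainCalled)
  if (length(trainCalled) == 0) return(0)
  length(intersect(trainCalled, validationCalled)) / length(trainCalled)
}

#' Permute subject outcome labels
#'
#' Uniformly permutes the tested factor across subjects (covariates are
#' left untouched), as used for type-I-error permutation analyses.
#'
#' @param design per-subject data.frame.
#' @param factorName column(s) to permute (default `"A"`).
#' @param seed optional integer seed for reproducibility.
#' @return the design with permuted factor column(s).
#' @export
permuteLabels <- function(design, factorName = "A", seed = NULL) {
  if (nrow(design) < 2) stop("need at least two subjects")
  if (!all(factorName %in% colnames(design))) stop("unknown factor column")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(nrow(design))
  design[, factorName] <- design[perm, factorName]
  design
}

#' Two-sample t-test comparators
#'
#' The benchmark straw-man tests: a per-gene pooled-variance two-sample t
#' of log-normalized expression between the outcome groups, run per cell
#' type either on pseudo-bulk subjects (`level = "pseudobulk"`) or on
#' individual cells pooled across subjects (`level = "cell"` —
#' deliberately ignoring the subject structure, which makes the test
#' pseudo-replicated when subjects differ in baseline). P-values are
#' Benjamini-Hochberg adjusted per cell type and genes are called at
#' adjusted p < `alpha`.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with colData
#'   `subject`, `cell_type`, `group` (e.g. from [simulateDataset()]).
#' @param level `"cell"` or `"pseudobulk"`.
#' @param alpha adjusted-p call threshold (default 0.05).
#' @param scaleFactor passed to the log-normalization.
#' @return named list (per cell type) of data.frames with columns `gene`,
#'   `stat`, `pval`, `padj`, `called`.
#' @export
comparatorTTest <- function(sce, level = c("cell", "pseudobulk"),
                            alpha = 0.05, scaleFactor = 1e4) {
  level <- match.arg(level)
  cd <- as.data.frame(colData(sce))
  if (!all(c("subject", "cell_type") %in% colnames(cd)))
    stop("colData must contain subject and cell_type")
  if (!"group" %in% colnames(cd)) {
    des <- metadata(sce)$design
    if (is.null(des) || !"A" %in% colnames(des))
      stop("no 'group' colData column and no design table with factor 'A'")
    cd$group <- des[cd$subject, "A"]
  }
  out <- list()
  if (level == "pseudobulk") {
    pb <- aggregateCounts(sce)
    pb <- logNormalize(pb, scaleFactor = scaleFactor)
    for (k in cellTypes(pb)) {
      grp <- pb@design[pb@subjects[[k]], "A"]
      out[[k]] <- .pooledT(normExpr(pb, k), grp == min(grp), alpha)
    }
  } else {
    counts <- .getCounts(sce)
    lib <- Matrix::colSums(counts)
    ok <- lib > 0
    Y <- normalizeCells(counts[, ok, drop = FALSE], scaleFactor = scaleFactor)
    cd <- cd[ok, , drop = FALSE]
    for (k in sort(unique(cd$cell_type))) {
      sel <- cd$cell_type == k
      out[[k]] <- .pooledT(Y[, sel, drop = FALSE],
                           cd$group[sel] == sort(unique(cd$group))[1], alpha)
    }
  }
  out
}

# vectorized pooled-variance two-sample t over the rows of Y
.pooledT <- function(Y, inG1, alpha) {
  n1 <- sum(inG1); n2 <- sum(!inG1)
  genes <- rownames(Y)
  if (n1 < 2 || n2 < 2) {
    return(data.frame(gene = genes, stat = NA_real_, pval = NA_real_,
                      padj = NA_real_, called = FALSE,
                      stringsAsFactors = FALSE))
  }
  Y1 <- Y[, inG1, drop = FALSE]; Y2 <- Y[, !inG1, drop = FALSE]
  m1 <- Matrix::rowSums(Y1) / n1
  m2 <- Matrix::rowSums(Y2) / n2
  ss1 <- Matrix::rowSums(Y1^2) - n1 * m1^2
  ss2 <- Matrix::rowSums(Y2^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(pmax(sp2 * (1 / n1 + 1 / n2), 1e-300))
  stat <- (m2 - m1) / se     # positive = higher in group 2
  flat <- (ss1 + ss2) < 1e-12 & abs(m2 - m1) < 1e-10
  stat[flat] <- 0
  pval <- 2 * pt(-abs(stat), df = n1 + n2 - 2)
  padj <- p.adjust(pval, method = "BH")
  data.frame(gene = genes, stat = as.numeric(stat), pval = as.numeric(pval),
             padj = as.numeric(padj), called = !is.na(padj) & padj < alpha,
             stringsAsFactors = FALSE)
}
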