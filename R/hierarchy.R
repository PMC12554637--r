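#' Select informative genes for tree construction
#'
#' Keeps the genes whose screening statistic exceeds `threshold` in
#' magnitude in at least one cell type, reducing the noise non-DE genes
#' contribute to the cell-type correlation estimates. The default 2.58 is
#' the two-sided standard-normal critical value at p = 0.01.
#'
#' @param screen a [ScreenResult-class].
#' @param threshold positive magnitude cutoff on the statistics.
#' @return integer indices of the selected genes.
#' @export
selectInformativeGenes <- function(screen, threshold = 2.58) {
  stopifnot(is(screen, "ScreenResult"))
  .assertScalarNumber(threshold, "threshold", lower = .Machine$double.eps)
  hit <- abs(screen@tstat) > threshold
  idx <- which(rowSums(hit, na.rm = TRUE) > 0)
  if (!length(idx))
    stop("no gene exceeds |stat| > ", threshold,
         "; lower the threshold to obtain informative genes")
  idx
}

#' Correlation distance between cell types
#'
#' Pairwise distance `d(k1, k2) = (1 - cor(stat_k1, stat_k2)) / 2` over the
#' selected genes, with Pearson correlation computed on pairwise-complete
#' observations. Identical DE behaviour gives distance 0, perfectly
#' opposite behaviour 1, uncorrelated 0.5.
#'
#' @param screen a [ScreenResult-class].
#' @param genes indices of the informative genes (from
#'   [selectInformativeGenes()]); at least 3.
#' @return symmetric K x K distance matrix with zero diagonal.
#' @export
computeDistanceMatrix <- function(screen, genes) {
  stopifnot(is(screen, "ScreenResult"))
  if (length(genes) < 3) stop("need at least 3 genes to correlate cell types")
  ts <- screen@tstat[genes, , drop = FALSE]
  sds <- apply(ts, 2, sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0))
    stop("zero variance of statistics over selected genes in cell type(s): ",
         paste(colnames(ts)[is.na(sds) | sds == 0], collapse = ", "))
  r <- cor(ts, use = "pairwise.complete.obs")
  d <- (1 - r) / 2
  diag(d) <- 0
  d
}

#' Build the cell-type tree by agglomerative clustering
#'
#' Hierarchical clustering of the correlation distance matrix; the rooted
#' dendrogram (leaves = cell types) is the hierarchy over which DE-state
#' priors are defined. Labels are sorted before clustering so that ties in
#' merge heights are broken deterministically.
#'
#' @param d symmetric distance matrix with cell-type dimnames (from
#'   [computeDistanceMatrix()]), or a `dist` object.
#' @param linkage agglomeration method: `"average"` (default),
#'   `"complete"` or `"single"`.
#' @return a [CellTypeTree-class] (topology only; priors unset).
#' @export
buildTree <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs cell-type dimnames")
  if (nrow(d) == 1L) {
    warning("single cell type: returning a degenerate one-leaf tree")
    phy <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = rownames(d),
                Nnode = 1L, edge.length = 1)
    class(phy) <- "phylo"
    nodes <- data.frame(id = 1:2, parent = c(2L, NA), label = c(rownames(d), rownames(d)),
                        leaf = c(TRUE, FALSE), pi = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
    return(new("CellTypeTree", phylo = phy, nodes = nodes,
               members = list(1L, 1L)))
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = linkage)
  phy <- ape::as.phylo(hc)
  .treeFromPhylo(phy)
}

#' Read and write cell-type trees in newick format
#'
#' `readCellTypeTree()` parses a newick string or file into a
#' [CellTypeTree-class]; branch lengths are ignored and multifurcations are
#' allowed. When `cellTypes` is given, the leaf labels must match it
#' exactly (each cell type once). `writeCellTypeTree()` serializes a tree
#' back to newick; a write/read round trip preserves topology and labels.
#'
#' @param x a newick string, or a path to a newick file.
#' @param cellTypes optional character vector of expected leaf labels.
#' @param tree a [CellTypeTree-class].
#' @param file optional output path; if `NULL` the newick string is
#'   returned.
#' @return `readCellTypeTree()`: a `CellTypeTree`; `writeCellTypeTree()`:
#'   the newick string (invisibly if written to file).
#' @export
readCellTypeTree <- function(x, cellTypes = NULL) {
  phy <- if (length(x) == 1L && grepl("[();]", x))
    ape::read.tree(text = x)
  else ape::read.tree(file = x)
  if (is.null(phy)) stop("could not parse newick input")
  if (!is.null(cellTypes)) {
    extra <- setdiff(phy$tip.label, cellTypes)
    missing <- setdiff(cellTypes, phy$tip.label)
    if (length(extra) || length(missing) || anyDuplicated(phy$tip.label))
      stop("tree leaves must match cell types exactly;",
           if (length(missing)) paste(" missing:", paste(missing, collapse = ", ")),
           if (length(extra)) paste(" unknown:", paste(extra, collapse = ", ")),
           if (anyDuplicated(phy$tip.label)) " (duplicated leaf labels)")
  } else if (anyDuplicated(phy$tip.label)) {
    stop("duplicated leaf labels in newick tree")
  }
  .treeFromPhylo(phy)
}

#' @rdname readCellTypeTree
#' @export
writeCellTypeTree <- function(tree, file = NULL) {
  stopifnot(is(tree, "CellTypeTree"))
  txt <- ape::write.tree(tree@phylo)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# build the node-table representation from an ape phylo.
# Node ids follow ape numbering: tips 1..K (tip.label order), internals
# K+1..K+Nnode with K+1 the root.
.treeFromPhylo <- function(phy) {
  K <- length(phy$tip.label)
  M <- K + phy$Nnode
  parent <- rep(NA_integer_, M)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  members <- vector("list", M)
  for (k in seq_len(K)) members[[k]] <- k
  if (K > 1) {
    po <- ape::reorder.phylo(phy, "postorder")$edge
    for (e in seq_len(nrow(po))) {
      ch <- po[e, 2]; pa <- po[e, 1]
      members[[pa]] <- c(members[[pa]], members[[ch]])
    }
    members <- lapply(members, function(m) sort(unique(m)))
  }
  label <- c(phy$tip.label,
             vapply(members[seq.int(K + 1, length.out = phy$Nnode)],
                    function(m) paste(sort(phy$tip.label[m]), collapse = "+"),
                    character(1)))
  nodes <- data.frame(
    id = seq_len(M), parent = parent, label = label,
    leaf = c(rep(TRUE, K), rep(FALSE, phy$Nnode)),
    pi = NA_real_, p = NA_real_, stringsAsFactors = FALSE
  )
  new("CellTypeTree", phylo = phy, nodes = nodes, members = members)
}

.rootNode <- function(tree) which(is.na(tree@nodes$parent))

#' Set generative priors on a cell-type tree
#'
#' Assigns a root marginal DE probability and per-node conditional
#' inheritance probabilities, then fills every node's marginal by
#' root-to-leaf propagation (`pi_node = pi_parent * p_node`). Nodes are
#' addressed by their member sets: leaves by their label, internal nodes
#' by the sorted `+`-joined labels of their descendant leaves (e.g.
#' `"CD4+CD8"`). Used to parameterize simulation scenarios and
#' mis-specified-tree experiments; for data analysis, priors are instead
#' estimated with [estimatePriors()].
#'
#' @param tree a [CellTypeTree-class].
#' @param piRoot root marginal DE probability.
#' @param p named numeric vector of inheritance probabilities covering
#'   every non-root node.
#' @return the tree with `pi` and `p` filled.
#' @export
setTreePriors <- function(tree, piRoot, p) {
  nd <- tree@nodes
  root <- .rootNode(tree)
  key <- vapply(tree@members, function(m)
    paste(sort(nd$label[m]), collapse = "+"), character(1))
  nd$p <- NA_real_
  for (nm in names(p)) {
    hit <- which(key == nm)
    if (!length(hit)) stop("no tree node with members '", nm, "'")
    nd$p[hit] <- p[[nm]]
  }
  if (anyNA(nd$p[-root])) stop("missing inheritance probability for some node")
  nd$pi[root] <- piRoot
  ord <- .preorder(tree)
  for (n in ord[-1]) nd$pi[n] <- nd$pi[nd$parent[n]] * nd$p[n]
  tree@nodes <- nd
  validObject(tree)
  tree
}

# node ids in root-first (pre-)order
.preorder <- function(tree) {
  nd <- tree@nodes
  ord <- .rootNode(tree)
  i <- 1L
  while (i <= length(ord)) {
    ch <- nd$id[!is.na(nd$parent) & nd$parent == ord[i]]
    ord <- c(ord, ch)
    i <- i + 1L
  }
  ord
}
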