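#' Soft-thresholded correlation adjacency
#'
#' Unsigned weighted-network adjacency
#' \code{a_ij = |Pearson r(i, j)|^softPower} with unit diagonal.
#'
#' @param mat numeric matrix, nodes (proteins) in rows, samples in
#'   columns; every node non-constant; at least 3 nodes and 4 samples.
#' @param softPower soft-thresholding exponent (>= 1).
#' @return symmetric adjacency matrix in [0,1].
#' @export
correlationAdjacency <- function(mat, softPower = 5L) {
  if (nrow(mat) < 3L || ncol(mat) < 4L)
    stop("need at least 3 nodes and 4 samples")
  sdv <- apply(mat, 1L, sd)
  if (any(sdv == 0))
    stop("constant node(s): ",
         paste(rownames(mat)[sdv == 0], collapse = ", "))
  a <- abs(cor(t(mat)))^softPower
  a[a > 1] <- 1
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' For i != j,
#' \code{TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} with
#' \code{l_ij = sum_u a_iu a_uj} over u distinct from i and j and
#' \code{k_i = sum_u a_iu} over u != i; the diagonal is 1. Nodes sharing
#' strong neighbourhoods overlap even when their direct adjacency is
#' modest.
#'
#' @param adj symmetric adjacency in [0,1] with unit diagonal.
#' @return symmetric TOM in [0,1] with unit diagonal.
#' @export
topologicalOverlap <- function(adj) {
  if (min(adj) < 0 || max(adj) > 1)
    stop("adjacency values must lie in [0,1]")
  if (max(abs(adj - t(adj))) > 1e-10) stop("adjacency must be symmetric")
  a <- adj
  diag(a) <- 0
  l <- a %*% a                       # l_ij = sum_{u != i,j} a_iu a_uj
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tomM <- (l + a) / denom
  diag(tomM) <- 1
  tomM[tomM > 1] <- 1
  tomM[tomM < 0] <- 0
  dimnames(tomM) <- dimnames(adj)
  tomM
}

#' Cut the TOM dendrogram into a fixed number of modules
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' \code{1 - TOM}, cut to exactly \code{nModules} clusters. Labels are
#' renumbered by decreasing module size (1 = largest).
#'
#' @param tomM a TOM matrix.
#' @param nModules number of modules (1..n nodes).
#' @return integer module label per node (named when the TOM has
#'   dimnames).
#' @export
cutModules <- function(tomM, nModules = 2L) {
  n <- nrow(tomM)
  if (nModules < 1L || nModules > n)
    stop("'nModules' must lie in 1..n nodes")
  hc <- hclust(as.dist(1 - tomM), method = "average")
  raw <- cutree(hc, k = nModules)
  sizes <- table(raw)
  newLab <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                            names(sizes))
  out <- as.integer(newLab[as.character(raw)])
  names(out) <- rownames(tomM)
  out
}

#' Intramodular TOM connectivity ("centrality")
#'
#' Centrality of node i = sum of TOM to the other nodes of its own module.
#' Nodes above \code{centralityCut} are the hub candidates.
#'
#' @param tomM a TOM matrix.
#' @param modules integer module label per node.
#' @return named numeric centrality per node.
#' @export
moduleCentrality <- function(tomM, modules) {
  n <- nrow(tomM)
  if (length(modules) != n) stop("one module label per node is required")
  ct <- vapply(seq_len(n), function(i) {
    same <- which(modules == modules[i])
    same <- setdiff(same, i)
    if (!length(same)) 0 else sum(tomM[i, same])
  }, numeric(1))
  names(ct) <- rownames(tomM)
  ct
}

#' Per-protein contribution to principal components
#'
#' Correlation PCA (nodes standardized, used as variables over samples).
#' The contribution of variable v to component c is
#' \code{100 * loading_vc^2} (loadings are unit-norm per component, so
#' contributions sum to 100); the aggregate is the eigenvalue-weighted mean
#' over the top \code{nComponents} components.
#'
#' @param mat numeric matrix, nodes in rows, samples in columns.
#' @param nComponents number of leading components to aggregate over
#'   (default 5).
#' @return data.frame with \code{protein}, one \code{PC<i>} contribution
#'   column per component, and \code{aggregate}; attribute
#'   \code{eigenvalues} records the component variances.
#' @export
pcaContributions <- function(mat, nComponents = 5L) {
  sdv <- apply(mat, 1L, sd)
  if (any(sdv == 0))
    stop("constant node(s): ",
         paste(rownames(mat)[sdv == 0], collapse = ", "))
  nComponents <- as.integer(min(nComponents, nrow(mat), ncol(mat) - 1L))
  if (nComponents < 1L) stop("no usable principal component")
  pc <- prcomp(t(mat), center = TRUE, scale. = TRUE)
  load <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  ev <- pc$sdev[seq_len(nComponents)]^2
  contrib <- 100 * sweep(load^2, 2L, colSums(load^2), "/")
  agg <- as.numeric(contrib %*% (ev / sum(ev)))
  out <- data.frame(protein = rownames(mat), contrib, aggregate = agg,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[1L + seq_len(nComponents)] <-
    paste0("PC", seq_len(nComponents))
  attr(out, "eigenvalues") <- ev
  out
}

#' Consensus hub ranking from centrality and PCA contribution
#'
#' Nodes are ranked separately by decreasing centrality and decreasing
#' aggregate PCA contribution; the consensus orders nodes by the sum of
#' the two ranks, ties broken lexicographically by id.
#'
#' @param centrality named numeric vector (TOM intramodular connectivity).
#' @param contributions data.frame from \code{\link{pcaContributions}}
#'   (or any with \code{protein} and \code{aggregate} columns).
#' @param topK number of hubs to return (capped at the shared node count).
#' @return data.frame: \code{protein}, \code{centralityRank},
#'   \code{contributionRank}, \code{rankSum}, \code{consensusRank}.
#' @export
hubConsensus <- function(centrality, contributions, topK = 10L) {
  shared <- intersect(names(centrality), contributions$protein)
  if (!length(shared)) stop("centrality and contribution ids are disjoint")
  ct <- centrality[shared]
  ag <- contributions$aggregate[match(shared, contributions$protein)]
  rc <- rank(-ct, ties.method = "min")
  ra <- rank(-ag, ties.method = "min")
  rs <- rc + ra
  ord <- order(rs, shared, method = "radix")
  out <- data.frame(protein = shared[ord],
                    centralityRank = as.integer(rc[ord]),
                    contributionRank = as.integer(ra[ord]),
                    rankSum = as.integer(rs[ord]),
                    consensusRank = seq_along(ord),
                    row.names = NULL, stringsAsFactors = FALSE)
  utils::head(out, min(topK, nrow(out)))
}

#' Build the full TOM network over selected proteins
#'
#' Adjacency, TOM, module cut and intramodular centrality in one call.
#'
#' @param x a completed \linkS4class{ProteinAbundance} or
#'   \linkS4class{ImputationResult}.
#' @param nodeIds protein ids to include (e.g. the DEP list).
#' @param config a \linkS4class{PipelineConfig} (soft power, module count).
#' @return a \linkS4class{TomNetwork}.
#' @export
buildTomNetwork <- function(x, nodeIds, config = pipelineConfig()) {
  m <- abundances(x)
  missing <- setdiff(nodeIds, rownames(m))
  if (length(missing))
    stop("node id(s) absent from matrix: ", paste(missing, collapse = ", "))
  sub <- m[nodeIds, , drop = FALSE]
  adj <- correlationAdjacency(sub, config@softPower)
  tm <- topologicalOverlap(adj)
  mods <- cutModules(tm, config@nModules)
  ct <- moduleCentrality(tm, mods)
  new("TomNetwork", nodeIds = nodeIds, adjacency = adj, tom = tm,
      moduleOf = as.integer(mods), centrality = unname(ct),
      softPower = as.integer(config@softPower))
}

#' @importFrom stats cor hclust cutree as.dist prcomp
NULL
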