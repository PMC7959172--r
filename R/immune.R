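#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Ranks all measured identifiers by descending expression (average ranks
#' for ties) and walks the ranked list: at an in-set identifier the running
#' sum rises by its rank weight\code{^alpha} normalised by the in-set
#' weight total; at an out-of-set identifier it falls by
#' \code{1/(N - setSize)}. The score is the integrated running sum over all
#' positions (ssGSEA convention), so it is invariant under strictly
#' monotone transforms of the sample's values.
#'
#' @param values named numeric vector: one sample's expression by
#'   identifier.
#' @param geneSet character vector of identifiers.
#' @param alpha rank-weight exponent (0 = unweighted; ssGSEA convention
#'   0.25).
#' @return numeric enrichment score.
#' @examples
#' v <- c(A = 1, B = 2, C = 3, D = 4)
#' ssgseaSample(v, "D", alpha = 0)  # 2
#' @export
ssgseaSample <- function(values, geneSet, alpha = 0.25) {
  if (is.null(names(values))) stop("'values' must be named by identifier")
  if (alpha < 0) stop("'alpha' must be >= 0")
  inSet <- names(values) %in% geneSet
  nIn <- sum(inSet)
  N <- length(values)
  if (nIn == 0L)
    stop("gene set shares no identifiers with the measured sample")
  if (nIn == N)
    stop("gene set covers every measured identifier; score undefined")
  rk <- rank(values, ties.method = "average")   # highest value -> rank N
  ord <- order(rk, decreasing = TRUE)
  w <- rk[ord]^alpha
  io <- inSet[ord]
  step <- ifelse(io, w / sum(w[io]), -1 / (N - nIn))
  sum(cumsum(step))
}

#' Score a gene-set collection across all samples
#'
#' @param x a completed \linkS4class{ProteinAbundance} or
#'   \linkS4class{ImputationResult}.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param alpha rank-weight exponent.
#' @return a raw \linkS4class{ScoreMatrix}, sets x samples.
#' @export
scoreGeneSets <- function(x, sets, alpha = 0.25) {
  m <- abundances(x)
  if (anyNA(m)) stop("scoring requires a completed (gap-free) matrix")
  sl <- geneSets(sets)
  bad <- names(sl)[vapply(sl, function(s) {
    k <- sum(rownames(m) %in% s)
    k == 0L || k == nrow(m)
  }, logical(1))]
  if (length(bad))
    stop("set(s) with empty or complete overlap with measured ids: ",
         paste(bad, collapse = ", "))
  sc <- matrix(NA_real_, length(sl), ncol(m),
               dimnames = list(names(sl), colnames(m)))
  for (j in seq_len(ncol(m))) {
    v <- stats::setNames(m[, j], rownames(m))
    for (i in seq_along(sl)) sc[i, j] <- ssgseaSample(v, sl[[i]], alpha)
  }
  new("ScoreMatrix", scores = sc, normalization = "raw")
}

#' Aggregate immune score per sample
#'
#' Sum of the named signature sets' ssGSEA scores in each sample, proxying
#' overall immune-cell admixture.
#'
#' @param scoreMatrix a \linkS4class{ScoreMatrix}.
#' @param signatureSets character vector of set names to sum.
#' @return named numeric vector, one score per sample.
#' @export
immuneScore <- function(scoreMatrix, signatureSets) {
  sc <- scores(scoreMatrix)
  unknown <- setdiff(signatureSets, rownames(sc))
  if (length(unknown))
    stop("unknown signature set(s): ", paste(unknown, collapse = ", "))
  colSums(sc[signatureSets, , drop = FALSE])
}

#' Compare per-sample scores between the two groups
#'
#' Two-sided Mann-Whitney U test plus group means and the direction of the
#' difference.
#'
#' @param sampleScores named numeric vector (names = sample ids).
#' @param groups group label per sample (named, or aligned with
#'   \code{sampleScores}).
#' @return list with \code{pValue}, \code{means} (named by group) and
#'   \code{higher} (the group with the larger mean, \code{NA} on ties).
#' @export
compareScoreGroups <- function(sampleScores, groups) {
  if (!is.null(names(groups)) && !is.null(names(sampleScores)))
    groups <- groups[names(sampleScores)]
  g <- factor(as.character(groups))
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) < 3L)) stop("each group needs at least 3 samples")
  a <- sampleScores[g == levels(g)[1]]
  b <- sampleScores[g == levels(g)[2]]
  p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  if (is.na(p)) p <- 1
  means <- c(mean(a), mean(b))
  names(means) <- levels(g)
  higher <- if (means[1] == means[2]) NA_character_
            else names(means)[which.max(means)]
  list(pValue = p, means = means, higher = higher)
}

#' Within-group correlation of anti- and pro-tumor immunity
#'
#' For each group and sample, the mean score of anti-tumor sets and the
#' mean score of pro-tumor sets are computed; the returned value per group
#' is the Pearson correlation of those two per-sample vectors.
#'
#' @param scoreMatrix a \linkS4class{ScoreMatrix}.
#' @param roles named character vector mapping set name to
#'   \code{"anti_tumor"}, \code{"pro_tumor"} or \code{"other"}.
#' @param groups group label per sample.
#' @return named numeric vector of Pearson r, one per group.
#' @export
antiProCorrelation <- function(scoreMatrix, roles, groups) {
  sc <- scores(scoreMatrix)
  anti <- intersect(rownames(sc), names(roles)[roles == "anti_tumor"])
  pro <- intersect(rownames(sc), names(roles)[roles == "pro_tumor"])
  if (length(anti) < 2L || length(pro) < 2L)
    stop("need at least 2 anti_tumor and 2 pro_tumor sets")
  if (!is.null(names(groups))) groups <- groups[colnames(sc)]
  g <- factor(as.character(groups))
  antiMean <- colMeans(sc[anti, , drop = FALSE])
  proMean <- colMeans(sc[pro, , drop = FALSE])
  out <- vapply(levels(g), function(lv) {
    sel <- g == lv
    if (sum(sel) < 3L) stop("each group needs at least 3 samples")
    if (sd(antiMean[sel]) == 0 || sd(proMean[sel]) == 0)
      stop("zero-variance score vector in group ", lv)
    cor(antiMean[sel], proMean[sel], method = "pearson")
  }, numeric(1))
  out
}

#' Z-score each set's scores across samples
#'
#' @param scoreMatrix a raw \linkS4class{ScoreMatrix}.
#' @return a \linkS4class{ScoreMatrix} with \code{normalization =
#'   "zscore"}; each row standardized to mean 0, sample sd 1.
#' @export
zscoreRows <- function(scoreMatrix) {
  sc <- scores(scoreMatrix)
  sdv <- apply(sc, 1L, sd)
  if (any(sdv == 0))
    stop("constant score row(s): ",
         paste(rownames(sc)[sdv == 0], collapse = ", "))
  z <- (sc - rowMeans(sc)) / sdv
  new("ScoreMatrix", scores = z, normalization = "zscore")
}

#' Fisher-exact over-representation analysis
#'
#' For each annotation set, the 2x2 table of hit/non-hit by in-set/out-set
#' over the universe is tested one-sided for enrichment with Fisher's
#' exact test; a Benjamini-Hochberg column is appended.
#'
#' @param hits character vector of significant identifiers (subset of
#'   \code{universe}).
#' @param universe character vector of all tested identifiers.
#' @param sets a \linkS4class{GeneSetCollection}; each set is intersected
#'   with the universe.
#' @return data.frame ordered by set name: \code{set}, \code{nHitInSet},
#'   \code{nSet}, \code{nHits}, \code{nUniverse}, \code{oddsRatio},
#'   \code{pValue}, \code{pAdjBH}.
#' @export
fisherOra <- function(hits, universe, sets) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  hits <- unique(as.character(hits))
  if (length(setdiff(hits, universe)))
    stop("hits must be a subset of the universe")
  sl <- geneSets(sets)
  rows <- lapply(names(sl), function(nm) {
    s <- intersect(sl[[nm]], universe)
    a <- length(intersect(hits, s))
    b <- length(hits) - a
    c_ <- length(s) - a
    d <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                      alternative = "greater")
    data.frame(set = nm, nHitInSet = a, nSet = length(s),
               nHits = length(hits), nUniverse = length(universe),
               oddsRatio = unname(ft$estimate), pValue = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$set, method = "radix"), , drop = FALSE]
  out$pAdjBH <- p.adjust(out$pValue, method = "BH")
  rownames(out) <- NULL
  out
}

#' @importFrom stats cor fisher.test
NULL
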