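#' Generate a complete (gap-free) synthetic two-group abundance matrix
#'
#' Per protein i a mean is drawn uniformly from the spec's
#' \code{baseMeanRange} and an sd from \code{proteinSdRange}; cells are
#' Gaussian around them. A fraction \code{fracDe} of proteins receives a
#' planted mean shift of \code{effectLog2} added to group A (the first
#' group). Truth (complete values, DE labels) is stored in the object's
#' metadata under \code{$truth}.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param groupNames labels for the two groups (group 1 = shifted group,
#'   fold-change numerator).
#' @return a \linkS4class{ProteinAbundance} without missing cells;
#'   \code{metadata(x)$truth} holds \code{completeValues}, \code{deLabels}.
#' @export
simulateCompleteAbundance <- function(spec = syntheticSpec(),
                                      groupNames = c("COAD", "READ")) {
  validObject(spec)
  set.seed(spec@seed)
  np <- spec@nProteins
  ns <- 2L * spec@nPerGroup
  mu <- runif(np, spec@baseMeanRange[1], spec@baseMeanRange[2])
  sg <- runif(np, spec@proteinSdRange[1], spec@proteinSdRange[2])
  de <- rep(FALSE, np)
  nDe <- round(spec@fracDe * np)
  if (nDe > 0L) de[sample.int(np, nDe)] <- TRUE
  vals <- matrix(rnorm(np * ns, mean = mu, sd = sg), nrow = np, ncol = ns)
  idxA <- seq_len(spec@nPerGroup)
  vals[de, idxA] <- vals[de, idxA] + spec@effectLog2
  rownames(vals) <- sprintf("P%05d", seq_len(np))
  colnames(vals) <- c(sprintf("%s_%02d", groupNames[1], idxA),
                      sprintf("%s_%02d", groupNames[2], idxA))
  groups <- rep(groupNames, each = spec@nPerGroup)
  names(de) <- rownames(vals)
  ProteinAbundance(vals, stats::setNames(groups, colnames(vals)),
                   metadata = list(truth = list(completeValues = vals,
                                                deLabels = de),
                                   spec = spec))
}

#' Hide cells under a two-part MCAR + left-censoring mechanism
#'
#' Each cell independently: with probability \code{mcarRate} it goes
#' missing completely at random; otherwise, if its true value lies below
#' the global \code{mnarQuantile} of all values, it is censored with
#' probability \code{mnarRate}. The per-cell mechanism label
#' (\code{observed} / \code{mcar} / \code{mnar}) is recorded in the truth.
#'
#' @param x a complete \linkS4class{ProteinAbundance} (no missing cells),
#'   typically from \code{\link{simulateCompleteAbundance}}.
#' @param spec the \linkS4class{SyntheticSpec} holding the missingness
#'   rates.
#' @param seed integer seed for the masking draws; defaults to
#'   \code{spec@seed + 1} so generation and masking use distinct streams.
#' @return a \linkS4class{ProteinAbundance} with \code{NA} in hidden cells;
#'   \code{metadata(x)$truth$mechanism} holds the per-cell labels.
#' @export
applyMissingness <- function(x, spec, seed = spec@seed + 1L) {
  validObject(spec)
  m <- abundances(x)
  if (anyNA(m)) stop("input matrix must be complete (no missing cells)")
  set.seed(as.integer(seed))
  n <- length(m)
  mcar <- matrix(runif(n) < spec@mcarRate, nrow = nrow(m))
  q <- quantile(m, spec@mnarQuantile, names = FALSE)
  mnar <- !mcar & (m < q) & matrix(runif(n) < spec@mnarRate, nrow = nrow(m))
  mech <- matrix("observed", nrow(m), ncol(m), dimnames = dimnames(m))
  mech[mcar] <- "mcar"
  mech[mnar] <- "mnar"
  masked <- m
  masked[mcar | mnar] <- NA_real_
  truth <- metadata(x)$truth
  if (is.null(truth)) truth <- list(completeValues = m)
  truth$mechanism <- mech
  ProteinAbundance(masked, sampleGroups(x),
                   metadata = modifyList(metadata(x), list(truth = truth)))
}

#' Simulate a two-group LFQ experiment with known truth
#'
#' Convenience wrapper: \code{\link{simulateCompleteAbundance}} followed by
#' \code{\link{applyMissingness}}.
#'
#' @inheritParams simulateCompleteAbundance
#' @return a \linkS4class{ProteinAbundance} with missing cells and full
#'   truth in \code{metadata(x)$truth}.
#' @examples
#' x <- simulateLfqExperiment(syntheticSpec(nProteins = 200, seed = 7))
#' mean(missingMask(x))
#' @export
simulateLfqExperiment <- function(spec = syntheticSpec(),
                                  groupNames = c("COAD", "READ")) {
  applyMissingness(simulateCompleteAbundance(spec, groupNames), spec)
}

#' @importFrom stats runif rnorm quantile setNames
#' @importFrom utils modifyList
NULL
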