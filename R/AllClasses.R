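#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors metadata DataFrame SimpleList
NULL

#' Protein-by-sample LFQ abundance container
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment} holding a single
#' \code{"abundance"} assay of log2-scale LFQ intensities with \code{NA}
#' marking missing (not-quantified) cells, and a two-level \code{group}
#' factor in \code{colData}. Reading a masked cell therefore always yields
#' \code{NA}, never a silent number.
#'
#' @slot .Data inherited \code{SummarizedExperiment} internals.
#' @export
setClass("ProteinAbundance", contains = "SummarizedExperiment")

.validProteinAbundance <- function(object) {
  msg <- NULL
  if (!"abundance" %in% names(assays(object)))
    msg <- c(msg, "assay 'abundance' is required")
  rn <- rownames(object)
  cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "protein ids (rownames) must be present and unique")
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!"group" %in% names(colData(object))) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    g <- colData(object)$group
    if (length(unique(as.character(g))) != 2L)
      msg <- c(msg, "exactly two sample groups are required")
    else if (any(table(as.character(g)) < 2L))
      msg <- c(msg, "each group needs at least 2 samples")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("ProteinAbundance", .validProteinAbundance)

#' Construct a ProteinAbundance object
#'
#' @param values numeric matrix, proteins in rows, samples in columns;
#'   log2-scale abundances with \code{NA} for missing cells. Rownames and
#'   colnames are mandatory and must be unique.
#' @param groups group label per sample: either a named vector (names =
#'   sample ids) or a vector aligned with \code{colnames(values)}. Exactly
#'   two distinct labels.
#' @param metadata optional list stored in the object metadata.
#' @return a validated \linkS4class{ProteinAbundance}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' pa <- ProteinAbundance(m, groups = c(S1 = "A", S2 = "A", S3 = "B", S4 = "B"))
#' @export
ProteinAbundance <- function(values, groups, metadata = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(values), names(groups))
    if (length(miss))
      stop("samples absent from annotation: ", paste(miss, collapse = ", "))
    groups <- groups[colnames(values)]
  } else if (length(groups) != ncol(values)) {
    stop("'groups' must be named or have one label per sample")
  }
  g <- factor(as.character(groups))
  se <- SummarizedExperiment(
    assays = SimpleList(abundance = values),
    colData = DataFrame(group = g, row.names = colnames(values)),
    metadata = metadata)
  new("ProteinAbundance", se)
}

#' Pipeline configuration
#'
#' Holds every tunable constant of the analysis pipeline. Defaults are the
#' published conventions of the sectionalized-imputation workflow: the
#' global routing threshold \code{mean + thresholdMultiplier * sd} over all
#' observed cells, per-sample down-shift imputation from
#' \code{Normal(mean - shiftFactor * sd, shrinkFactor * sd)}, missingness
#' filter counts for 20+20 designs, fold-change cutoffs 1.5 / 0.67 at raw
#' p < 0.05, normality/variance gates at 0.1, soft-thresholding power 5,
#' two network modules, and an intramodular-connectivity hub cut of 30.
#'
#' @export
setClass("PipelineConfig",
  representation(
    thresholdMultiplier = "numeric",
    shiftFactor = "numeric",
    shrinkFactor = "numeric",
    knnK = "integer",
    discardCount = "integer",
    flagHighCount = "integer",
    flagLowCount = "integer",
    fcUp = "numeric",
    fcDown = "numeric",
    alphaDep = "numeric",
    alphaGate = "numeric",
    softPower = "integer",
    nModules = "integer",
    centralityCut = "numeric",
    ssgseaAlpha = "numeric",
    rngSeed = "integer"),
  prototype(
    thresholdMultiplier = 2.0,
    shiftFactor = 1.8,
    shrinkFactor = 0.3,
    knnK = 10L,
    discardCount = 16L,
    flagHighCount = 18L,
    flagLowCount = 8L,
    fcUp = 1.5,
    fcDown = 0.67,
    alphaDep = 0.05,
    alphaGate = 0.1,
    softPower = 5L,
    nModules = 2L,
    centralityCut = 30,
    ssgseaAlpha = 0.25,
    rngSeed = 1L))

.validPipelineConfig <- function(object) {
  msg <- NULL
  chk1 <- function(x, nm) {
    if (length(slot(object, x)) != 1L || !is.finite(slot(object, x)))
      msg <<- c(msg, sprintf("'%s' must be a single finite value", nm))
  }
  for (s in slotNames(object)) chk1(s, s)
  if (!is.null(msg)) return(msg)
  if (!(object@fcDown < 1 && 1 < object@fcUp))
    msg <- c(msg, "'fcDown' must be < 1 < 'fcUp'")
  for (a in c("alphaDep", "alphaGate")) {
    v <- slot(object, a)
    if (v <= 0 || v >= 1) msg <- c(msg, sprintf("'%s' must lie in (0,1)", a))
  }
  if (object@softPower < 1L) msg <- c(msg, "'softPower' must be >= 1")
  if (object@knnK < 1L) msg <- c(msg, "'knnK' must be >= 1")
  if (object@nModules < 1L) msg <- c(msg, "'nModules' must be >= 1")
  if (object@shrinkFactor < 0) msg <- c(msg, "'shrinkFactor' must be >= 0")
  if (object@ssgseaAlpha < 0) msg <- c(msg, "'ssgseaAlpha' must be >= 0")
  if (is.null(msg)) TRUE else msg
}
setValidity("PipelineConfig", .validPipelineConfig)

#' Named collection of gene/protein sets
#'
#' @slot sets named list of character vectors (deduplicated, non-empty).
#' @slot description named character vector, one per set.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", description = "character"))

.validGeneSetCollection <- function(object) {
  msg <- NULL
  nm <- names(object@sets)
  if (length(object@sets) && (is.null(nm) || anyDuplicated(nm)))
    msg <- c(msg, "set names must be present and unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "every set must be non-empty")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "identifiers must be deduplicated within a set")
  if (length(object@description) != length(object@sets))
    msg <- c(msg, "one description per set is required")
  if (is.null(msg)) TRUE else msg
}
setValidity("GeneSetCollection", .validGeneSetCollection)

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors.
#' @param description optional named character vector of descriptions.
#' @export
GeneSetCollection <- function(sets, description = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(description)) {
    description <- rep("", length(sets))
  }
  names(description) <- names(sets)
  new("GeneSetCollection", sets = sets, description = description)
}

#' Result of sectionalized imputation
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{abundance}
#' (the completed, gap-free matrix) and \code{provenance} (per-cell label:
#' \code{"observed"}, \code{"downshift"} or \code{"knn"}). Metadata carries
#' \code{threshold1}, the per-sample down-shift parameters and the
#' missingness census of the input.
#' @export
setClass("ImputationResult", contains = "SummarizedExperiment")

.validImputationResult <- function(object) {
  msg <- NULL
  if (!all(c("abundance", "provenance") %in% names(assays(object))))
    msg <- c(msg, "assays 'abundance' and 'provenance' are required")
  else {
    if (anyNA(assay(object, "abundance")))
      msg <- c(msg, "completed matrix must contain no missing cells")
    pv <- assay(object, "provenance")
    if (!all(pv %in% c("observed", "downshift", "knn")))
      msg <- c(msg, "provenance labels must be observed/downshift/knn")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("ImputationResult", .validImputationResult)

#' Gene-set score matrix (ssGSEA)
#'
#' @slot scores numeric matrix, sets in rows, samples in columns.
#' @slot normalization \code{"raw"} or \code{"zscore"}.
#' @export
setClass("ScoreMatrix",
  representation(scores = "matrix", normalization = "character"))

.validScoreMatrix <- function(object) {
  msg <- NULL
  if (!object@normalization %in% c("raw", "zscore"))
    msg <- c(msg, "normalization must be 'raw' or 'zscore'")
  if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
    msg <- c(msg, "scores must carry set (row) and sample (column) names")
  if (identical(object@normalization, "zscore") && nrow(object@scores)) {
    mu <- rowMeans(object@scores)
    sdv <- apply(object@scores, 1L, sd)
    if (any(abs(mu) > 1e-8) || any(abs(sdv - 1) > 1e-8))
      msg <- c(msg, "zscore rows must have mean 0 and sd 1")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("ScoreMatrix", .validScoreMatrix)

#' Topological-overlap network over differential proteins
#'
#' @slot nodeIds character vector of protein ids.
#' @slot adjacency soft-thresholded |correlation|^power matrix in [0,1].
#' @slot tom topological overlap matrix in [0,1], unit diagonal.
#' @slot moduleOf integer module label per node (1 = largest module).
#' @slot centrality intramodular TOM connectivity per node.
#' @slot softPower the soft-thresholding exponent used.
#' @export
setClass("TomNetwork",
  representation(nodeIds = "character", adjacency = "matrix", tom = "matrix",
                 moduleOf = "integer", centrality = "numeric",
                 softPower = "integer"))

.validTomNetwork <- function(object) {
  msg <- NULL
  n <- length(object@nodeIds)
  for (nm in c("adjacency", "tom")) {
    m <- slot(object, nm)
    if (!all(dim(m) == n)) msg <- c(msg, sprintf("'%s' must be %d x %d", nm, n, n))
    else {
      if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, sprintf("'%s' must be symmetric", nm))
      if (min(m) < -1e-12 || max(m) > 1 + 1e-12)
        msg <- c(msg, sprintf("'%s' must lie in [0,1]", nm))
      if (any(abs(diag(m) - 1) > 1e-12))
        msg <- c(msg, sprintf("'%s' must have unit diagonal", nm))
    }
  }
  if (length(object@moduleOf) != n || length(object@centrality) != n)
    msg <- c(msg, "moduleOf and centrality must cover every node")
  if (is.null(msg)) TRUE else msg
}
setValidity("TomNetwork", .validTomNetwork)

#' Specification of a synthetic two-group LFQ experiment
#'
#' Defines the generative model for matrices with known truth: per-protein
#' mean drawn uniformly from \code{baseMeanRange} (log2 units), per-protein
#' sd from \code{proteinSdRange}, Gaussian cell noise, a planted mean shift
#' of \code{effectLog2} added to group A for a fraction \code{fracDe} of
#' proteins, and a two-part missingness mechanism: MCAR at rate
#' \code{mcarRate}, then left-censoring which hides cells whose true value
#' lies below the global \code{mnarQuantile} with probability
#' \code{mnarRate}.
#'
#' @export
setClass("SyntheticSpec",
  representation(
    nProteins = "integer",
    nPerGroup = "integer",
    baseMeanRange = "numeric",
    proteinSdRange = "numeric",
    fracDe = "numeric",
    effectLog2 = "numeric",
    mcarRate = "numeric",
    mnarQuantile = "numeric",
    mnarRate = "numeric",
    seed = "integer"),
  prototype(
    nProteins = 4000L,
    nPerGroup = 20L,
    baseMeanRange = c(20, 30),
    proteinSdRange = c(1.5, 4.0),
    fracDe = 0.1,
    effectLog2 = 1,
    mcarRate = 0.02,
    mnarQuantile = 0.25,
    mnarRate = 0.5,
    seed = 1L))

.validSyntheticSpec <- function(object) {
  msg <- NULL
  for (r in c("fracDe", "mcarRate", "mnarRate")) {
    v <- slot(object, r)
    if (length(v) != 1L || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must lie in [0,1]", r))
  }
  if (object@mnarQuantile <= 0 || object@mnarQuantile >= 1)
    msg <- c(msg, "'mnarQuantile' must lie in (0,1)")
  if (object@nPerGroup < 2L) msg <- c(msg, "'nPerGroup' must be >= 2")
  if (object@nProteins < 1L) msg <- c(msg, "'nProteins' must be >= 1")
  if (!is.finite(object@effectLog2)) msg <- c(msg, "'effectLog2' must be finite")
  for (r in c("baseMeanRange", "proteinSdRange")) {
    v <- slot(object, r)
    if (length(v) != 2L || any(!is.finite(v)) || v[1] > v[2])
      msg <- c(msg, sprintf("'%s' must be an increasing pair", r))
  }
  if (object@proteinSdRange[1] < 0)
    msg <- c(msg, "'proteinSdRange' must be non-negative")
  if (is.null(msg)) TRUE else msg
}
setValidity("SyntheticSpec", .validSyntheticSpec)

#' @rdname SyntheticSpec-class
#' @param nProteins,nPerGroup matrix dimensions (two groups of
#'   \code{nPerGroup} samples).
#' @param baseMeanRange,proteinSdRange uniform ranges for per-protein mean
#'   and sd, log2 units.
#' @param fracDe fraction of proteins given a planted group-A shift.
#' @param effectLog2 size of the planted shift (log2 units).
#' @param mcarRate per-cell completely-at-random missingness probability.
#' @param mnarQuantile global abundance quantile below which censoring acts.
#' @param mnarRate censoring probability below that quantile.
#' @param seed integer seed; all generator randomness flows from it.
#' @export
syntheticSpec <- function(nProteins = 4000L, nPerGroup = 20L,
                          baseMeanRange = c(20, 30),
                          proteinSdRange = c(1.5, 4.0),
                          fracDe = 0.1, effectLog2 = 1,
                          mcarRate = 0.02, mnarQuantile = 0.25,
                          mnarRate = 0.5, seed = 1L) {
  new("SyntheticSpec",
      nProteins = as.integer(nProteins), nPerGroup = as.integer(nPerGroup),
      baseMeanRange = as.numeric(baseMeanRange),
      proteinSdRange = as.numeric(proteinSdRange),
      fracDe = as.numeric(fracDe), effectLog2 = as.numeric(effectLog2),
      mcarRate = as.numeric(mcarRate), mnarQuantile = as.numeric(mnarQuantile),
      mnarRate = as.numeric(mnarRate), seed = as.integer(seed))
}
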