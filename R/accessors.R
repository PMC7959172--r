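#' @importFrom stats sd
NULL

#' Re-exported generics
#'
#' \code{metadata} (from S4Vectors) gives access to the truth records the
#' synthetic generator stores and to imputation run details; \code{assay}
#' (from SummarizedExperiment) to the raw assay matrices.
#' @name reexports
#' @importFrom S4Vectors metadata
#' @export metadata
#' @importFrom SummarizedExperiment assay
#' @export assay
NULL

#' Accessors for ProteoSect containers
#'
#' \code{abundances} returns the abundance assay (with \code{NA} for missing
#' cells of a \code{ProteinAbundance}; gap-free for an
#' \code{ImputationResult}); \code{missingMask} the logical missing-cell
#' mask; \code{sampleGroups} the two-level group factor named by sample;
#' \code{groupLevels} the two labels, first level = numerator group of fold
#' changes.
#'
#' @param x a \linkS4class{ProteinAbundance} or
#'   \linkS4class{ImputationResult}.
#' @return see description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setMethod("abundances", "SummarizedExperiment",
          function(x) assay(x, "abundance"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setMethod("missingMask", "SummarizedExperiment",
          function(x) is.na(assay(x, "abundance")))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setMethod("sampleGroups", "SummarizedExperiment", function(x) {
  g <- colData(x)$group
  names(g) <- colnames(x)
  g
})

#' @rdname accessors
#' @export
setGeneric("groupLevels", function(x) standardGeneric("groupLevels"))
#' @rdname accessors
#' @export
setMethod("groupLevels", "SummarizedExperiment",
          function(x) levels(colData(x)$group))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "ImputationResult",
          function(x) assay(x, "provenance"))

#' @rdname accessors
#' @export
setGeneric("threshold1", function(x) standardGeneric("threshold1"))
#' @rdname accessors
#' @export
setMethod("threshold1", "ImputationResult",
          function(x) metadata(x)$threshold1)

#' @rdname accessors
#' @export
setGeneric("sampleParams", function(x) standardGeneric("sampleParams"))
#' @rdname accessors
#' @export
setMethod("sampleParams", "ImputationResult",
          function(x) metadata(x)$perSampleParams)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))
#' @rdname accessors
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) x@description)

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setMethod("scores", "ScoreMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("scoreNormalization", function(x) standardGeneric("scoreNormalization"))
#' @rdname accessors
#' @export
setMethod("scoreNormalization", "ScoreMatrix", function(x) x@normalization)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "TomNetwork", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("tom", function(x) standardGeneric("tom"))
#' @rdname accessors
#' @export
setMethod("tom", "TomNetwork", function(x) x@tom)

#' @rdname accessors
#' @export
setGeneric("moduleOf", function(x) standardGeneric("moduleOf"))
#' @rdname accessors
#' @export
setMethod("moduleOf", "TomNetwork", function(x) {
  m <- x@moduleOf
  names(m) <- x@nodeIds
  m
})

#' @rdname accessors
#' @export
setGeneric("nodeCentrality", function(x) standardGeneric("nodeCentrality"))
#' @rdname accessors
#' @export
setMethod("nodeCentrality", "TomNetwork", function(x) {
  ct <- x@centrality
  names(ct) <- x@nodeIds
  ct
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection with %d set(s)\n", length(object@sets)))
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat(sprintf("  set sizes: %d .. %d (median %.0f)\n",
                min(sz), max(sz), median(sz)))
  }
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d set(s) x %d sample(s), normalization = %s\n",
              nrow(object@scores), ncol(object@scores), object@normalization))
})

setMethod("show", "TomNetwork", function(object) {
  cat(sprintf("TomNetwork: %d nodes, soft power %d, %d module(s)\n",
              length(object@nodeIds), object@softPower,
              length(unique(object@moduleOf))))
  tab <- table(object@moduleOf)
  cat("  module sizes:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-20s %s\n", s, format(slot(object, s))))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d proteins x 2x%d samples, fracDe=%.2f (effect %.2f log2)\n",
    object@nProteins, object@nPerGroup, object@fracDe, object@effectLog2))
  cat(sprintf("  missingness: MCAR %.3f; MNAR rate %.2f below quantile %.2f; seed %d\n",
              object@mcarRate, object@mnarRate, object@mnarQuantile, object@seed))
})

#' @importFrom stats median
NULL
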