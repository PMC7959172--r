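#' Build and validate a pipeline configuration
#'
#' Applies the published defaults, overlays the supplied values, checks
#' every invariant and rejects unknown keys (suggesting the nearest valid
#' name).
#'
#' @param ... named configuration values; see
#'   \linkS4class{PipelineConfig} for the fields and defaults.
#' @return a validated \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(softPower = 6, rngSeed = 42)
#' @export
pipelineConfig <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && is.null(names(args)))
    args <- args[[1L]]
  valid <- slotNames("PipelineConfig")
  if (length(args)) {
    if (is.null(names(args)) || any(!nzchar(names(args))))
      stop("all configuration values must be named")
    unknown <- setdiff(names(args), valid)
    if (length(unknown)) {
      hints <- vapply(unknown, function(u) {
        d <- utils::adist(u, valid, partial = TRUE, ignore.case = TRUE) +
          utils::adist(u, valid, ignore.case = TRUE) / 10
        valid[which.min(d)]
      }, character(1))
      stop("unknown configuration key(s): ",
           paste(sprintf("'%s' (did you mean '%s'?)", unknown, hints),
                 collapse = ", "))
    }
  }
  obj <- new("PipelineConfig")
  intSlots <- c("knnK", "discardCount", "flagHighCount", "flagLowCount",
                "softPower", "nModules", "rngSeed")
  for (nm in names(args)) {
    v <- args[[nm]]
    slot(obj, nm) <- if (nm %in% intSlots) as.integer(v) else as.numeric(v)
  }
  validObject(obj)
  obj
}

.fileDigest <- function(path) {
  # order-insensitive content fingerprint; no external digest dependency
  bytes <- readBin(path, "raw", file.info(path)$size)
  sprintf("size=%d;sum=%.0f", length(bytes), sum(as.integer(bytes)))
}

#' Run the full comparative pipeline
#'
#' Orchestrates simulate/read, sectionalized imputation, the DEP screen,
#' ssGSEA immune scoring and the TOM hub analysis, writing every stage
#' table plus a JSON reproducibility manifest to \code{outdir}. Stages
#' communicate through the returned in-memory objects; the written TSVs
#' are deterministic for a fixed config seed.
#'
#' If no gene sets are supplied, toy immune signatures are derived
#' deterministically from the imputed matrix (random protein subsets under
#' the config seed) so the scoring stage remains exercisable on synthetic
#' data.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param outdir output directory (created if needed).
#' @param input either a \linkS4class{SyntheticSpec} (simulate) or a list
#'   with \code{matrixPath} and \code{annotationPath} (read from disk).
#' @param sets optional \linkS4class{GeneSetCollection} for immune scoring.
#' @param signatureSets names of sets summed into the immune score
#'   (default: all sets).
#' @return invisibly, a list with the stage objects (\code{matrix},
#'   \code{imputation}, \code{deps}, \code{scores}, \code{network},
#'   \code{hubs}, \code{manifestPath}).
#' @export
runPipeline <- function(config = pipelineConfig(), outdir,
                        input = syntheticSpec(seed = config@rngSeed),
                        sets = NULL, signatureSets = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- c()
  stage <- function(name, expr) {
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(as.numeric(Sys.time() - st, units = "secs"), 3)
    out
  }
  x <- stage("io", {
    if (is(input, "SyntheticSpec")) simulateLfqExperiment(input)
    else readAbundanceMatrix(input$matrixPath, input$annotationPath,
                             linearScale = isTRUE(input$linearScale))
  })
  imp <- stage("impute", sectionalizedImpute(x, config, seed = config@rngSeed))
  census <- metadata(imp)$census
  writeResultTable(census, file.path(outdir, "missingness_census.tsv"))
  writeAbundanceMatrix(imp, file.path(outdir, "completed_matrix.tsv"))
  provDf <- data.frame(protein = rownames(provenance(imp)),
                       provenance(imp), check.names = FALSE,
                       stringsAsFactors = FALSE)
  writeResultTable(provDf, file.path(outdir, "provenance.tsv"))
  deps <- stage("dep", screenDeps(imp, config))
  writeResultTable(deps, file.path(outdir, "dep_table.tsv"))
  depIds <- deps$protein[deps$call != "ns"]
  if (is.null(sets)) {
    set.seed(config@rngSeed)
    ids <- rownames(imp)
    sets <- GeneSetCollection(list(
      sig_immune_a = sample(ids, min(25L, max(2L, length(ids) %/% 4L))),
      sig_immune_b = sample(ids, min(25L, max(2L, length(ids) %/% 4L))),
      sig_immune_c = sample(ids, min(25L, max(2L, length(ids) %/% 4L)))))
  }
  sm <- stage("immune", scoreGeneSets(imp, sets, config@ssgseaAlpha))
  if (is.null(signatureSets)) signatureSets <- rownames(scores(sm))
  iscore <- immuneScore(sm, signatureSets)
  cmp <- compareScoreGroups(iscore, sampleGroups(imp))
  scoreDf <- data.frame(set = rownames(scores(sm)), scores(sm),
                        check.names = FALSE, stringsAsFactors = FALSE)
  writeResultTable(scoreDf, file.path(outdir, "immune_scores.tsv"))
  net <- NULL
  hubs <- NULL
  if (length(depIds) >= 3L) {
    net <- stage("network", buildTomNetwork(imp, depIds, config))
    contrib <- pcaContributions(abundances(imp)[depIds, , drop = FALSE])
    hubs <- hubConsensus(nodeCentrality(net), contrib,
                         topK = length(depIds))
    hubTab <- merge(hubs,
                    data.frame(protein = depIds,
                               module = as.integer(moduleOf(net)),
                               centrality = as.numeric(nodeCentrality(net)),
                               isHub = as.numeric(nodeCentrality(net)) >
                                 config@centralityCut,
                               stringsAsFactors = FALSE),
                    by = "protein")
    writeResultTable(hubTab, file.path(outdir, "network_hubs.tsv"))
  } else {
    writeResultTable(data.frame(protein = character(),
                                consensusRank = integer()),
                     file.path(outdir, "network_hubs.tsv"))
  }
  cfgList <- sapply(slotNames(config), function(s) slot(config, s),
                    simplify = FALSE)
  tables <- c("missingness_census.tsv", "completed_matrix.tsv",
              "provenance.tsv", "dep_table.tsv", "immune_scores.tsv",
              "network_hubs.tsv")
  manifest <- list(
    config = cfgList,
    seed = config@rngSeed,
    input = if (is(input, "SyntheticSpec"))
      list(type = "synthetic",
           spec = sapply(slotNames(input), function(s) slot(input, s),
                         simplify = FALSE))
      else list(type = "files", matrixPath = input$matrixPath,
                annotationPath = input$annotationPath),
    conventions = list(
      scale = "log2",
      knn = "protein neighbours, RMS distance over shared samples, 1/d weights",
      imputationOrder = "downshift first, then KNN on filled matrix",
      levene = "Brown-Forsythe (median-centred)",
      studentVariant = "pooled variance",
      ssgseaScore = "integrated running sum",
      centrality = "intramodular TOM connectivity"),
    depCounts = as.list(attr(deps, "counts")),
    immuneComparison = list(pValue = cmp$pValue,
                            means = as.list(cmp$means),
                            higher = cmp$higher),
    stageSeconds = as.list(timings),
    totalSeconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
    outputs = sapply(tables, function(f)
      .fileDigest(file.path(outdir, f)), simplify = FALSE),
    versions = list(R = as.character(getRversion()),
                    ProteoSect = tryCatch(
                      as.character(utils::packageVersion("ProteoSect")),
                      error = function(e) NA_character_)))
  manifestPath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(matrix = x, imputation = imp, deps = deps, scores = sm,
                 immuneScore = iscore, comparison = cmp, network = net,
                 hubs = hubs, manifestPath = manifestPath))
}
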