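#' Read a protein abundance matrix and its sample annotation
#'
#' Parses a tab-delimited matrix (first column = protein id, header row =
#' sample ids) together with a two-column annotation table mapping sample id
#' to group label. Blank cells, \code{NA}, \code{NaN} and (by MaxQuant
#' convention) literal \code{0} are treated as missing.
#'
#' @param path path to the tab-delimited abundance matrix.
#' @param annotationPath path to a tab-delimited two-column table
#'   (header \code{sample}, \code{group}, or any two columns in that order).
#' @param linearScale if \code{TRUE} the file stores linear-scale LFQ
#'   intensities and values are log2-transformed on read; if \code{FALSE}
#'   (default) values are taken as already log2.
#' @param zeroIsMissing treat literal 0 as a missing cell (default
#'   \code{TRUE}; MaxQuant emits 0 for not-quantified).
#' @return a validated \linkS4class{ProteinAbundance}.
#' @examples
#' pa <- readAbundanceMatrix(
#'   system.file("extdata", "example_lfq_synthetic.tsv",
#'               package = "ProteoSect"),
#'   system.file("extdata", "example_annotation_synthetic.tsv",
#'               package = "ProteoSect"))
#' sum(missingMask(pa))
#' @export
readAbundanceMatrix <- function(path, annotationPath, linearScale = FALSE,
                                zeroIsMissing = TRUE) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (!file.exists(annotationPath))
    stop("annotation file not found: ", annotationPath)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA", "NaN"))
  if (ncol(raw) < 2L) stop("matrix file needs a protein-id column and samples")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate protein ids in matrix file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sampleIds <- colnames(raw)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids in matrix header: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(ids, sampleIds)
  if (zeroIsMissing) vals[!is.na(vals) & vals == 0] <- NA_real_
  if (linearScale) {
    if (any(vals <= 0, na.rm = TRUE))
      stop("non-positive values cannot be log2-transformed")
    vals <- log2(vals)
  }
  ann <- utils::read.delim(annotationPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(ann) < 2L) stop("annotation file needs sample and group columns")
  groups <- stats::setNames(as.character(ann[[2L]]), as.character(ann[[1L]]))
  ProteinAbundance(vals, groups)
}

#' Read a GMT gene-set file
#'
#' One set per line: \code{name<TAB>description<TAB>member...}. Duplicate
#' members within a line are collapsed; duplicate set names are an error.
#'
#' @param path path to a GMT file.
#' @return a \linkS4class{GeneSetCollection}.
#' @examples
#' gsc <- readGmt(system.file("extdata", "example_sets_toy.gmt",
#'                            package = "ProteoSect"))
#' lengths(geneSets(gsc))
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(GeneSetCollection(sets = structure(list(), names = character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("GMT line %d has fewer than 3 fields", bad[1L]))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  names(desc) <- nm
  GeneSetCollection(sets = sets, description = desc)
}

#' Write a result table deterministically
#'
#' Tab-delimited output with a header row; rows sorted by the first column
#' (the primary key) so repeated writes of the same records are
#' byte-identical.
#'
#' @param records a data.frame (possibly empty but with columns).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeResultTable <- function(records, path) {
  records <- as.data.frame(records)
  if (!ncol(records)) stop("records must carry at least one column")
  if (nrow(records))
    records <- records[order(records[[1L]], method = "radix"), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write a ProteinAbundance (or completed matrix) to TSV
#'
#' Missing cells are written as \code{NA}. Inverse of
#' \code{\link{readAbundanceMatrix}} with \code{linearScale = FALSE,
#' zeroIsMissing = FALSE}.
#'
#' @param x a \linkS4class{ProteinAbundance} or
#'   \linkS4class{ImputationResult}.
#' @param path matrix output path.
#' @param annotationPath optional path for the sample-group annotation.
#' @return invisibly, \code{path}.
#' @export
writeAbundanceMatrix <- function(x, path, annotationPath = NULL) {
  m <- abundances(x)
  df <- data.frame(protein = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  close(con)
  if (!is.null(annotationPath)) {
    g <- sampleGroups(x)
    writeResultTable(data.frame(sample = names(g), group = as.character(g),
                                stringsAsFactors = FALSE), annotationPath)
  }
  invisible(path)
}

#' Median-center each sample
#'
#' Subtracts the per-sample median of observed cells, the normalization
#' under which the bulk of observed abundances sits near 0 and the
#' left-censored missing mass below 0.
#'
#' @param x a \linkS4class{ProteinAbundance}.
#' @return a \linkS4class{ProteinAbundance} with centered values.
#' @export
centerSamples <- function(x) {
  m <- abundances(x)
  med <- apply(m, 2L, median, na.rm = TRUE)
  ProteinAbundance(sweep(m, 2L, med, "-"), sampleGroups(x),
                   metadata = metadata(x))
}
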