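#' Gated two-sample test
#'
#' Applies the test-selection gate: Brown-Forsythe Levene (median-centred)
#' across the two groups and Shapiro-Wilk within each. When all three gate
#' p-values exceed \code{alphaGate} the groups are compared with a
#' two-sided pooled-variance Student t test; otherwise with a two-sided
#' Mann-Whitney U test (normal approximation with tie correction).
#'
#' @param xa,xb numeric vectors, group A and group B values (log2 scale),
#'   each of length >= 3.
#' @param alphaGate gate level (default 0.1).
#' @return list with \code{testUsed} ("student_t" or "mann_whitney"),
#'   \code{pValue}, and the gate p-values \code{gateLevene},
#'   \code{gateShapiroA}, \code{gateShapiroB}.
#' @export
gateAndTest <- function(xa, xb, alphaGate = 0.1) {
  if (length(xa) < 3L || length(xb) < 3L)
    stop("each group needs at least 3 values")
  if (any(!is.finite(c(xa, xb)))) stop("values must be finite")
  if (sd(xa) == 0 && sd(xb) == 0 && xa[1L] == xb[1L]) {
    warning("both groups constant and identical; p set to 1")
    return(list(testUsed = "mann_whitney", pValue = 1,
                gateLevene = NA_real_, gateShapiroA = NA_real_,
                gateShapiroB = NA_real_))
  }
  lev <- tryCatch({
    grp <- factor(rep(c("A", "B"), c(length(xa), length(xb))))
    tab <- car::leveneTest(c(xa, xb), grp, center = median)
    tab[["Pr(>F)"]][1L]
  }, error = function(e) 0)
  shA <- tryCatch(shapiro.test(xa)$p.value, error = function(e) 0)
  shB <- tryCatch(shapiro.test(xb)$p.value, error = function(e) 0)
  if (!is.na(lev) && lev > alphaGate && shA > alphaGate && shB > alphaGate) {
    p <- t.test(xa, xb, var.equal = TRUE)$p.value
    test <- "student_t"
  } else {
    p <- suppressWarnings(
      wilcox.test(xa, xb, exact = FALSE, correct = TRUE)$p.value)
    if (is.na(p)) p <- 1
    test <- "mann_whitney"
  }
  list(testUsed = test, pValue = p, gateLevene = lev,
       gateShapiroA = shA, gateShapiroB = shB)
}

#' Linear fold change from log2 values
#'
#' \code{2^(mean(xa) - mean(xb))}, group A in the numerator.
#'
#' @inheritParams gateAndTest
#' @return positive linear ratio.
#' @export
foldChange <- function(xa, xb) 2^(mean(xa) - mean(xb))

#' Screen differentially expressed proteins
#'
#' One gated test and fold change per protein; a protein is called
#' \code{up} when \code{ratio > fcUp} and \code{p < alphaDep}, \code{down}
#' when \code{ratio < fcDown} and \code{p < alphaDep}, otherwise \code{ns}
#' (strict inequalities; no multiple-testing correction in the call, a
#' Benjamini-Hochberg column is appended for reference).
#'
#' @param x a completed \linkS4class{ProteinAbundance} or
#'   \linkS4class{ImputationResult} (no missing cells).
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame ordered by protein id: \code{protein}, \code{meanA},
#'   \code{meanB}, \code{ratio}, \code{pValue}, \code{pAdjBH},
#'   \code{testUsed}, \code{gateLevene}, \code{gateShapiroA},
#'   \code{gateShapiroB}, \code{call}. Attribute \code{counts} holds the
#'   up/down/ns tally, attribute \code{groupLevels} the numerator group.
#' @examples
#' x <- simulateLfqExperiment(syntheticSpec(nProteins = 60, seed = 2,
#'                                          mcarRate = 0, mnarRate = 0))
#' deps <- screenDeps(x)
#' attr(deps, "counts")
#' @export
screenDeps <- function(x, config = pipelineConfig()) {
  m <- abundances(x)
  if (anyNA(m)) stop("screenDeps requires a completed (gap-free) matrix")
  g <- as.character(sampleGroups(x))
  lev <- groupLevels(x)
  ia <- which(g == lev[1])
  ib <- which(g == lev[2])
  n <- nrow(m)
  res <- data.frame(protein = rownames(m),
                    meanA = rowMeans(m[, ia, drop = FALSE]),
                    meanB = rowMeans(m[, ib, drop = FALSE]),
                    ratio = NA_real_, pValue = NA_real_, pAdjBH = NA_real_,
                    testUsed = NA_character_, gateLevene = NA_real_,
                    gateShapiroA = NA_real_, gateShapiroB = NA_real_,
                    call = "ns", row.names = NULL, stringsAsFactors = FALSE)
  res$ratio <- 2^(res$meanA - res$meanB)
  for (i in seq_len(n)) {
    gt <- gateAndTest(m[i, ia], m[i, ib], config@alphaGate)
    res$pValue[i] <- gt$pValue
    res$testUsed[i] <- gt$testUsed
    res$gateLevene[i] <- gt$gateLevene
    res$gateShapiroA[i] <- gt$gateShapiroA
    res$gateShapiroB[i] <- gt$gateShapiroB
  }
  res$pAdjBH <- p.adjust(res$pValue, method = "BH")
  sig <- res$pValue < config@alphaDep
  res$call[sig & res$ratio > config@fcUp] <- "up"
  res$call[sig & res$ratio < config@fcDown] <- "down"
  res <- res[order(res$protein, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "counts") <- c(up = sum(res$call == "up"),
                           down = sum(res$call == "down"),
                           ns = sum(res$call == "ns"))
  attr(res, "groupLevels") <- lev
  res
}

#' @importFrom stats shapiro.test t.test wilcox.test p.adjust
NULL
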