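# Independent brute-force oracles and small fixture builders.

# quick two-group ProteinAbundance from a plain matrix
makePa <- function(values, nA = NULL, groups = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  if (is.null(groups)) {
    if (is.null(nA)) nA <- ncol(values) %/% 2L
    groups <- rep(c("A", "B"), c(nA, ncol(values) - nA))
  }
  ProteinAbundance(values, stats::setNames(groups, colnames(values)))
}

# KNN imputation straight from the definition: all-pairs loops, no reuse of
# package internals.
bruteKnn <- function(m, row, col, k) {
  n <- nrow(m)
  d <- rep(Inf, n)
  for (j in seq_len(n)) {
    if (j == row) next
    shared <- which(!is.na(m[row, ]) & !is.na(m[j, ]))
    if (!length(shared)) next
    d[j] <- sqrt(sum((m[row, shared] - m[j, shared])^2) / length(shared))
  }
  elig <- which(is.finite(d) & !is.na(m[, col]))
  if (!length(elig)) return(NA_real_)
  elig <- elig[order(d[elig])]
  nb <- elig[seq_len(min(k, length(elig)))]
  dv <- d[nb]
  if (any(dv < 1e-12)) return(mean(m[nb[dv < 1e-12], col]))
  sum(m[nb, col] / dv) / sum(1 / dv)
}

# TOM from the triple-loop definition
bruteTom <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# ssGSEA integrated running sum, written as an explicit position walk
bruteSsgsea <- function(values, geneSet, alpha) {
  rk <- rank(values, ties.method = "average")
  ord <- names(sort(rk, decreasing = TRUE))
  inSet <- ord %in% geneSet
  wTot <- sum(rk[ord][inSet]^alpha)
  N <- length(values)
  m <- sum(inSet)
  rs <- 0
  total <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (inSet[i]) rk[ord[i]]^alpha / wTot else -1 / (N - m)
    total <- total + rs
  }
  as.numeric(total)
}

# one-sided enrichment p by exhaustive hypergeometric summation
bruteFisherP <- function(a, nHits, nSet, nUniv) {
  kMax <- min(nHits, nSet)
  p <- 0
  for (k in a:kMax)
    p <- p + choose(nSet, k) * choose(nUniv - nSet, nHits - k) /
      choose(nUniv, nHits)
  p
}

# protein with prescribed per-group missing counts inside a 20+20 matrix
censusFixture <- function(counts) {
  np <- nrow(counts)
  set.seed(99)
  m <- matrix(rnorm(np * 40, mean = 25), np, 40)
  for (i in seq_len(np)) {
    if (counts[i, 1] > 0) m[i, seq_len(counts[i, 1])] <- NA
    if (counts[i, 2] > 0) m[i, 20 + seq_len(counts[i, 2])] <- NA
  }
  makePa(m, nA = 20L)
}
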