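test_that("census verdicts follow the strict count rules", {
  counts <- rbind(c(17, 17), c(16, 20), c(19, 5), c(5, 19), c(0, 0))
  pa <- censusFixture(counts)
  cs <- censusMissing(pa)
  expect_identical(cs$verdict,
                   c("discard", "retain", "flag_one_group",
                     "flag_one_group", "retain"))
  expect_identical(cs$missA, as.integer(counts[, 1]))
  expect_identical(cs$missB, as.integer(counts[, 2]))
})

test_that("census verdicts are invariant to sample permutation within groups", {
  set.seed(3)
  m <- matrix(rnorm(40 * 40, 25, 2), 40, 40)
  m[runif(length(m)) < 0.4] <- NA
  pa <- makePa(m, nA = 20L)
  cs1 <- censusMissing(pa)
  perm <- c(sample(1:20), sample(21:40))
  cs2 <- censusMissing(makePa(m[, perm], groups = rep(c("A", "B"), each = 20)))
  expect_identical(cs1$verdict, cs2$verdict)
})

test_that("threshold1 matches the hand formula", {
  m <- matrix(c(0, 0, 2, 2), 1, 4)
  pa <- makePa(rbind(m, m), nA = 2L)   # duplicated row keeps it 2-protein
  # observed cells {0,0,2,2,0,0,2,2}: mean 1, sample sd sqrt(8/7)
  expect_equal(computeThreshold1(pa), 1 + 2 * sqrt(8 / 7), tolerance = 1e-12)

  cst <- makePa(matrix(5, 3, 4), nA = 2L)
  expect_equal(computeThreshold1(cst), 5)

  allNa <- makePa(matrix(NA_real_, 2, 4), nA = 2L)
  expect_error(computeThreshold1(allNa), "at least 2 observed")
})

test_that("routing uses the strict threshold on the protein observed mean", {
  m <- rbind(c(10, 10, 10, NA),   # mean 10
             c(2, 2, 2, NA),      # mean 2
             c(4, 4, 4, 4))
  pa <- makePa(m, nA = 2L)
  cs <- suppressWarnings(censusMissing(pa))
  cells <- classifyMissingCells(pa, cs, thr = 5)
  routes <- setNames(cells$route, cells$protein)
  expect_identical(unname(routes["P001"]), "knn")
  expect_identical(unname(routes["P002"]), "downshift")
  # boundary: observed mean exactly equal to threshold -> downshift
  cellsEq <- classifyMissingCells(pa, cs, thr = 10)
  expect_identical(cellsEq$route[cellsEq$protein == "P001"], "downshift")
  # degenerate -Inf threshold -> everything knn
  cellsInf <- classifyMissingCells(pa, cs, thr = -Inf)
  expect_true(all(cellsInf$route == "knn"))
})

test_that("flag_one_group near-empty cells are forced to downshift", {
  counts <- rbind(c(19, 5), c(0, 0))
  pa <- censusFixture(counts)
  cs <- suppressWarnings(censusMissing(pa))
  cells <- classifyMissingCells(pa, cs, thr = -Inf)  # would all be knn
  g <- as.character(sampleGroups(pa))
  flagCells <- cells[cells$protein == "P001", ]
  inA <- g[flagCells$col] == "A"
  expect_true(all(flagCells$route[inA] == "downshift"))
  expect_true(all(flagCells$route[!inA] == "knn"))
})

test_that("downshift draws follow Normal(mean - 1.8 sd, 0.3 sd)", {
  # sample 1 observed cells standardized to mean exactly 0, sd exactly 1
  set.seed(8)
  nFill <- 6000L
  obs <- rnorm(6000)
  obs <- (obs - mean(obs)) / sd(obs)
  m <- matrix(rnorm(12000 * 4), 12000, 4)
  m[seq_len(nFill), 1] <- NA
  m[nFill + seq_len(6000), 1] <- obs
  pa <- makePa(m, nA = 2L)
  cells <- data.frame(row = seq_len(nFill), col = 1L)
  fills <- imputeDownshift(pa, cells, seed = 17)
  expect_equal(mean(fills), -1.8, tolerance = 0.02)
  expect_equal(sd(fills), 0.3, tolerance = 0.02)

  # shrink 0 makes every fill exactly the shifted mean
  cfg0 <- pipelineConfig(shrinkFactor = 0)
  f0 <- imputeDownshift(pa, cells, cfg0, seed = 17)
  pars <- downshiftParams(pa, cfg0)
  expect_true(all(abs(f0 - pars$adjMean[1]) < 1e-12))

  # determinism
  expect_identical(fills, imputeDownshift(pa, cells, seed = 17))
  expect_false(identical(fills, imputeDownshift(pa, cells, seed = 18)))
})

test_that("downshift refuses samples with under 2 observed cells", {
  m <- matrix(rnorm(12), 3, 4)
  m[, 1] <- NA
  m[1, 1] <- 5
  pa <- makePa(m, nA = 2L)
  expect_error(imputeDownshift(pa, data.frame(row = 2L, col = 1L)),
               "fewer than 2 observed")
})

test_that("KNN imputation matches the brute-force oracle", {
  set.seed(31)
  for (rep in 1:6) {
    m <- matrix(rnorm(30 * 10, 20, 2), 30, 10)
    m[runif(length(m)) < 0.2] <- NA
    cells <- which(is.na(m), arr.ind = TRUE)
    if (!nrow(cells)) next
    cdf <- data.frame(row = as.integer(cells[, 1]),
                      col = as.integer(cells[, 2]))
    got <- suppressWarnings(imputeKnn(m, cdf, k = 4L))$fill
    want <- vapply(seq_len(nrow(cdf)), function(i)
      bruteKnn(m, cdf$row[i], cdf$col[i], 4L), numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("KNN handles identical and equidistant neighbours as defined", {
  # identical neighbour at zero distance: copy its value
  m <- rbind(c(1, 2, 3, NA),
             c(1, 2, 3, 7),
             c(9, 9, 9, 9))
  got <- imputeKnn(m, data.frame(row = 1L, col = 4L), k = 1L)
  expect_equal(got$fill, 7)

  # two equidistant neighbours with values 1 and 3: plain mean 2
  m2 <- rbind(c(0, 0, NA),
              c(1, 1, 1),
              c(-1, -1, 3))
  got2 <- imputeKnn(m2, data.frame(row = 1L, col = 3L), k = 2L)
  expect_equal(got2$fill, 2)

  # single-protein matrix: no neighbour exists, fallback flagged
  m3 <- matrix(c(1, NA, 3, 4), 1, 4)
  expect_warning(got3 <- imputeKnn(m3, data.frame(row = 1L, col = 2L), k = 3L),
                 "no eligible")
  expect_true(got3$fallback)
})

test_that("sectionalized imputation completes the matrix with full provenance", {
  sp <- syntheticSpec(nProteins = 250, seed = 6)
  x <- simulateLfqExperiment(sp)
  res <- sectionalizedImpute(x, seed = 3)
  expect_s4_class(res, "ImputationResult")
  expect_false(anyNA(abundances(res)))
  prov <- provenance(res)
  keep <- metadata(res)$census$verdict != "discard"
  expect_identical(unname(prov == "observed"),
                   unname(!missingMask(x)[keep, ]))
  expect_true(all(prov %in% c("observed", "downshift", "knn")))

  # no missing cells: identity with all-observed provenance
  comp <- simulateCompleteAbundance(syntheticSpec(nProteins = 40, seed = 2))
  resC <- sectionalizedImpute(comp)
  expect_identical(abundances(resC), abundances(comp))
  expect_true(all(provenance(resC) == "observed"))
})

test_that("high-abundance missing proteins route entirely to KNN", {
  set.seed(12)
  base <- matrix(rnorm(50 * 10, 0, 1), 50, 10)
  high <- matrix(rnorm(2 * 10, 40, 0.5), 2, 10)
  m <- rbind(base, high)
  m[51, 3] <- NA
  m[52, 8] <- NA
  pa <- makePa(m, nA = 5L)
  res <- suppressWarnings(sectionalizedImpute(pa, seed = 5))
  expect_identical(unname(provenance(res)[51, 3]), "knn")
  expect_identical(unname(provenance(res)[52, 8]), "knn")
  expect_false(any(provenance(res) == "downshift"))
})

test_that("RMSE matches its definition", {
  t1 <- matrix(0, 1, 2); i1 <- matrix(c(1, -1), 1, 2)
  expect_equal(evaluateRmse(t1, i1, matrix(TRUE, 1, 2)), 1)
  expect_equal(evaluateRmse(t1, t1, matrix(TRUE, 1, 2)), 0)
  one <- matrix(3, 1, 1)
  expect_equal(evaluateRmse(matrix(0, 1, 1), one, matrix(TRUE, 1, 1)), 3)
  expect_error(evaluateRmse(t1, i1, matrix(FALSE, 1, 2)), "no cells")
})

test_that("benchmark reproduces the routing-driven method behaviour", {
  # pure MNAR: censored truth sits in the left tail KNN cannot reach
  spMnar <- syntheticSpec(nProteins = 600, seed = 14, mcarRate = 0,
                          mnarRate = 1, mnarQuantile = 0.2)
  xm <- simulateLfqExperiment(spMnar)
  bm <- benchmarkImputation(xm, seeds = 1:2)
  sect <- bm$rmse[bm$method == "sectionalized"]
  knn <- bm$rmse[bm$method == "knn_only"]
  expect_true(all(sect < knn))

  # pure MCAR at uniformly high abundance relative to the threshold:
  # every cell is KNN-routed, so the two methods coincide
  set.seed(44)
  m <- matrix(rnorm(80 * 12, 0, 1), 80, 12)
  m <- rbind(m, matrix(rnorm(3 * 12, 50, 0.5), 3, 12))
  msk <- matrix(FALSE, 83, 12)
  msk[cbind(81:83, c(2, 5, 9))] <- TRUE
  full <- m
  m[msk] <- NA
  pa <- ProteinAbundance(`dimnames<-`(m, list(sprintf("P%03d", 1:83),
                                              sprintf("S%02d", 1:12))),
                         rep(c("A", "B"), each = 6),
                         metadata = list(truth = list(completeValues = full)))
  bm2 <- suppressWarnings(benchmarkImputation(pa, seeds = 1:2))
  s2 <- bm2$rmse[bm2$method == "sectionalized"]
  k2 <- bm2$rmse[bm2$method == "knn_only"]
  expect_equal(s2, k2, tolerance = 1e-12)
})
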