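test_that("ssGSEA reproduces the hand-walked example and its symmetries", {
  v <- c(A = 1, B = 2, C = 3, D = 4)
  # set {D}: running sum 1, 2/3, 1/3, 0 -> integrated score 2
  expect_equal(ssgseaSample(v, "D", alpha = 0), 2, tolerance = 1e-12)
  # the bottom-ranked singleton mirrors to -2
  expect_equal(ssgseaSample(v, "A", alpha = 0), -2, tolerance = 1e-12)
  expect_lt(ssgseaSample(v, c("A", "B"), alpha = 0.25), 0)

  # rank invariance under strictly increasing transforms
  set.seed(60)
  w <- setNames(rnorm(30), paste0("g", 1:30))
  st <- c("g3", "g7", "g21", "g28")
  for (a in c(0, 0.25, 1)) {
    s0 <- ssgseaSample(w, st, alpha = a)
    expect_equal(ssgseaSample(exp(w), st, alpha = a), s0, tolerance = 1e-12)
    expect_equal(ssgseaSample(2 * w + 5, st, alpha = a), s0, tolerance = 1e-12)
  }
  # sign flip under ranking reversal (alpha = 0)
  expect_equal(ssgseaSample(-w, st, alpha = 0),
               -ssgseaSample(w, st, alpha = 0), tolerance = 1e-12)

  expect_error(ssgseaSample(w, "nope", 0.25), "no identifiers")
  expect_error(ssgseaSample(w, names(w), 0.25), "every measured")
})

test_that("the ssGSEA running sum returns to zero at the final position", {
  set.seed(61)
  for (rep in 1:5) {
    v <- setNames(rnorm(20), paste0("g", 1:20))
    st <- sample(names(v), 6)
    rk <- rank(v)
    ord <- order(rk, decreasing = TRUE)
    inSet <- names(v)[ord] %in% st
    w <- rk[ord]^0.25
    step <- ifelse(inSet, w / sum(w[inSet]), -1 / (20 - 6))
    expect_equal(sum(step), 0, tolerance = 1e-12)
  }
})

test_that("collection scoring matches an independent per-sample walk", {
  set.seed(62)
  m <- matrix(rnorm(8 * 3), 8, 3,
              dimnames = list(paste0("g", 1:8), paste0("S", 1:3)))
  gsc <- GeneSetCollection(list(s1 = c("g1", "g4", "g7"),
                                s2 = c("g2", "g3")))
  pa4 <- makePa(cbind(m, S4 = rnorm(8)), nA = 2L)
  sm <- scoreGeneSets(pa4, gsc, alpha = 0.25)
  for (j in 1:4) for (s in 1:2) {
    want <- bruteSsgsea(setNames(abundances(pa4)[, j], rownames(m)),
                        geneSets(gsc)[[s]], 0.25)
    expect_equal(scores(sm)[s, j], want, tolerance = 1e-12)
  }
  # duplicated sample column gives a duplicated score column
  pa5 <- makePa(cbind(m, S4 = m[, 1]), nA = 2L)
  sm5 <- scoreGeneSets(pa5, gsc, alpha = 0.25)
  expect_equal(scores(sm5)[, 4], scores(sm5)[, 1],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("immune scores sum signature sets and separate hot samples", {
  sc <- matrix(c(0.2, 0.4, 0.3, 0.1), 2, 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("A1", "B1")))
  sm <- new("ScoreMatrix", scores = sc, normalization = "raw")
  expect_equal(unname(immuneScore(sm, c("s1", "s2"))), c(0.5, 0.5))
  expect_equal(unname(immuneScore(sm, "s1")), unname(sc[1, ]))
  expect_error(immuneScore(sm, "s3"), "unknown")

  # planted immune-hot group: signature proteins up-shifted in group A
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(rnorm(60 * 12), 60, 12,
                dimnames = list(sprintf("g%02d", 1:60), sprintf("S%02d", 1:12)))
    sig <- sprintf("g%02d", 1:12)
    m[sig, 1:6] <- m[sig, 1:6] + 2.5
    pa <- makePa(m, nA = 6L)
    gsc <- GeneSetCollection(list(sigA = sig[1:6], sigB = sig[7:12]))
    sm2 <- scoreGeneSets(pa, gsc, 0.25)
    isc <- immuneScore(sm2, c("sigA", "sigB"))
    hot <- mean(isc[1:6]); cold <- mean(isc[7:12])
    if (hot > cold) hits <- hits + 1L
    if (seed == 1L) {
      cmp <- compareScoreGroups(isc, sampleGroups(pa))
      expect_lt(cmp$pValue, 0.01)
      expect_identical(cmp$higher, "A")
      # label swap flips direction, keeps p
      cmp2 <- compareScoreGroups(isc, setNames(
        rep(c("B", "A"), each = 6), names(isc)))
      expect_equal(cmp2$pValue, cmp$pValue, tolerance = 1e-12)
      expect_identical(cmp2$higher, "B")
    }
  }
  expect_identical(hits, 10L)
})

test_that("identical group scores give no signal", {
  s <- setNames(rep(c(1, 2, 3), 2), paste0("S", 1:6))
  cmp <- compareScoreGroups(s, rep(c("A", "B"), each = 3))
  expect_gt(cmp$pValue, 0.9)
  expect_true(is.na(cmp$higher))
})

test_that("anti/pro correlation recovers exact and latent-factor structure", {
  sc <- matrix(rnorm(4 * 12), 4, 12,
               dimnames = list(c("a1", "a2", "p1", "p2"), sprintf("S%02d", 1:12)))
  sc[3, ] <- sc[1, ]; sc[4, ] <- sc[2, ]   # pro == anti
  sm <- new("ScoreMatrix", scores = sc, normalization = "raw")
  roles <- c(a1 = "anti_tumor", a2 = "anti_tumor",
             p1 = "pro_tumor", p2 = "pro_tumor")
  g <- rep(c("A", "B"), each = 6)
  r <- antiProCorrelation(sm, roles, g)
  expect_equal(unname(r), c(1, 1), tolerance = 1e-12)

  sc2 <- sc; sc2[3:4, ] <- -sc[1:2, ]      # pro == -anti
  r2 <- antiProCorrelation(new("ScoreMatrix", scores = sc2,
                               normalization = "raw"), roles, g)
  expect_equal(unname(r2), c(-1, -1), tolerance = 1e-12)

  # shared latent infiltration factor loading both roles
  set.seed(77)
  lat <- rnorm(12, sd = 2)
  sc3 <- rbind(a1 = lat + rnorm(12, sd = 0.4),
               a2 = lat + rnorm(12, sd = 0.4),
               p1 = lat + rnorm(12, sd = 0.4),
               p2 = lat + rnorm(12, sd = 0.4))
  colnames(sc3) <- sprintf("S%02d", 1:12)
  r3 <- antiProCorrelation(new("ScoreMatrix", scores = sc3,
                               normalization = "raw"), roles, g)
  expect_true(all(r3 > 0.8))

  scc <- sc; scc[1:2, 1:6] <- 1            # constant anti in group A
  expect_error(antiProCorrelation(new("ScoreMatrix", scores = scc,
                                      normalization = "raw"), roles, g),
               "zero-variance")
})

test_that("row z-scoring standardizes exactly and is idempotent", {
  sc <- matrix(c(1, 2, 3, 5, 5, 8), 2, 3, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("S1", "S2", "S3")))
  sm <- new("ScoreMatrix", scores = sc, normalization = "raw")
  z <- zscoreRows(sm)
  expect_equal(unname(scores(z)[1, ]), c(-1, 0, 1), tolerance = 1e-12)
  expect_identical(scoreNormalization(z), "zscore")
  z2 <- zscoreRows(z)
  expect_equal(scores(z2), scores(z), tolerance = 1e-12)
  expect_true(all(abs(rowMeans(scores(z))) < 1e-12))
  expect_true(all(abs(apply(scores(z), 1, sd) - 1) < 1e-12))

  cst <- new("ScoreMatrix", scores = matrix(1, 1, 3,
             dimnames = list("s1", paste0("S", 1:3))), normalization = "raw")
  expect_error(zscoreRows(cst), "s1")
})

test_that("Fisher ORA agrees with the hypergeometric closed form and oracle", {
  univ <- paste0("g", 1:20)
  st <- univ[1:10]
  gsc <- GeneSetCollection(list(half = st))
  res <- fisherOra(hits = st, universe = univ, sets = gsc)
  expect_equal(res$pValue, 1 / choose(20, 10), tolerance = 1e-12)

  # disjoint hits: no enrichment
  res0 <- fisherOra(hits = univ[11:15], universe = univ, sets = gsc)
  expect_equal(res0$pValue, 1, tolerance = 1e-12)

  # exhaustive hypergeometric oracle over small random universes
  set.seed(88)
  for (rep in 1:20) {
    nU <- sample(5:15, 1)
    u <- paste0("x", seq_len(nU))
    s <- sample(u, sample(1:(nU - 1), 1))
    h <- sample(u, sample(1:nU, 1))
    got <- fisherOra(h, u, GeneSetCollection(list(s = s)))$pValue
    a <- length(intersect(h, s))
    want <- bruteFisherP(a, length(h), length(s), nU)
    expect_equal(got, want, tolerance = 1e-12)
  }

  expect_error(fisherOra(c("a"), character(), gsc), "non-empty")
  expect_error(fisherOra(c("zz"), univ, gsc), "subset")
})
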