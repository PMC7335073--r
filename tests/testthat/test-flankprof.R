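## Hand-written molecule set reused by several oracles: a tiny CG pool with
## known per-strand states.
handMolecules <- function(cfg, n = 20, seed = 101) {
  pool <- generatePool(n, cfg, seed = seed)
  tops <- as.character(topSequences(pool))
  set.seed(seed + 1)
  st <- sample(c("methylated", "unmethylated"), n, replace = TRUE)
  sb <- sample(c("methylated", "unmethylated"), n, replace = TRUE)
  list(pool = pool,
       mol = moleculesFromTruth(tops, st, sb),
       stateTop = st, stateBottom = sb)
}

## Independent brute-force oracle: per-strand events via aggregate().
bruteForceTable <- function(tops, stateTop, stateBottom, k, off) {
  ctxTop <- paste0(substr(tops, off - k + 1, off),
                   substr(tops, off + 3, off + 2 + k))
  win <- substr(tops, off - k + 1, off + 2 + k)
  rcw <- rcOracle(win)
  ctxBot <- paste0(substr(rcw, 1, k), substr(rcw, k + 3, 2 * k + 2))
  ev <- data.frame(context = c(ctxTop, ctxBot),
                   meth = c(stateTop, stateBottom) == "methylated")
  agg <- aggregate(meth ~ context, ev, function(x) c(n = length(x),
                                                     m = sum(x)))
  data.frame(context = agg$context, nTotal = agg$meth[, "n"],
             nMeth = agg$meth[, "m"], stringsAsFactors = FALSE)
}

test_that("context tables equal an independent brute-force group-by", {
  cfg <- testConfig()
  h <- handMolecules(cfg)
  off <- nchar(cfg$arm5) + cfg$flankLen
  for (k in 1:2) {
    tb <- buildContextTable(h$mol, k, "CG", cfg)
    bf <- bruteForceTable(as.character(topSequences(h$pool)), h$stateTop,
                          h$stateBottom, k, off)
    bf <- bf[order(bf$context), ]
    cc <- contextCounts(tb)
    expect_equal(cc$context, bf$context)
    expect_equal(cc$nTotal, bf$nTotal)
    expect_equal(cc$nMeth, bf$nMeth)
    expect_equal(cc$levelRaw, bf$nMeth / bf$nTotal)
    expect_equal(cc$levelSmoothed, (bf$nMeth + 0.5) / (bf$nTotal + 1))
    ## conservation: events counted once each
    expect_equal(sum(cc$nTotal), 2L * poolSize(h$pool))
  }
  ## single methylated molecule: its context row is 1/1
  one <- moleculesFromTruth(as.character(topSequences(h$pool))[1],
                            "methylated", "absent")
  t1 <- buildContextTable(one, 2L, "CG", cfg)
  expect_equal(contextCounts(t1)$nTotal, 1L)
  expect_equal(contextCounts(t1)$levelRaw, 1)
  expect_error(buildContextTable(h$mol, cfg$flankLen + 1L, "CG", cfg),
               "exceeds")
})

test_that("dinucleotide split partitions events and matches subset tables", {
  cfg <- testConfig()
  ## mixed pool: half CG, half CA molecules
  pCG <- generatePool(30, cfg, seed = 110)
  pCA <- generatePool(30, cfg, centralMotif = "CA", seed = 111)
  tops <- c(as.character(topSequences(pCG)), as.character(topSequences(pCA)))
  set.seed(112)
  st <- sample(c("methylated", "unmethylated"), 60, replace = TRUE)
  sb <- c(sample(c("methylated", "unmethylated"), 30, replace = TRUE),
          rep("absent", 30))
  mol <- moleculesFromTruth(tops, st, sb)
  split <- splitByDinucleotide(mol, 2L, cfg)
  ## CG-only pools leave the other tables empty
  splitCG <- splitByDinucleotide(moleculesFromTruth(
    as.character(topSequences(pCG)), st[1:30], sb[1:30]), 2L, cfg)
  expect_equal(nrow(contextCounts(splitCG$CA)), 0L)
  expect_equal(nrow(contextCounts(splitCG$CT)), 0L)
  ## conservation: four tables partition all strand events
  total <- sum(vapply(split, function(t) sum(contextCounts(t)$nTotal),
                      numeric(1)))
  expect_equal(total, 30 * 2 + 30)   # CG contributes 2 strands, CA one
  ## each split table equals buildContextTable on the subset
  for (d in c("CG", "CA")) {
    sub <- buildContextTable(mol, 2L, d, cfg)
    expect_equal(contextCounts(split[[d]]), contextCounts(sub))
  }
})

test_that("positional enrichment peaks where the preference acts", {
  cfg <- testConfig(flankLen = 4L)
  ## methylation determined solely by G at +1, pool uniform
  pool <- generatePool(2000, cfg, seed = 120)
  tops <- as.character(topSequences(pool))
  off <- nchar(cfg$arm5) + cfg$flankLen
  plus1 <- substr(tops, off + 3, off + 3)
  st <- ifelse(plus1 == "G", "methylated", "unmethylated")
  mol <- moleculesFromTruth(tops, st, rep("absent", length(tops)))
  prof <- positionalEnrichment(mol, central = "CG", config = cfg)
  expect_equal(prof$position, c("-4", "-3", "-2", "-1",
                                "+1", "+2", "+3", "+4"))
  expect_equal(prof$normalized[prof$position == "+1"], 1)
  expect_true(all(prof$normalized[prof$position != "+1"] < 0.2))
  ## errors on degenerate inputs
  none <- moleculesFromTruth(tops[1:5], rep("unmethylated", 5),
                             rep("absent", 5))
  expect_error(positionalEnrichment(none, central = "CG", config = cfg),
               "no methylated")
})

test_that("sequence-independent methylation stays below the permutation null", {
  cfg <- testConfig()
  pool <- generatePool(2500, cfg, seed = 130)
  oc <- simulateMethylation(pool, constantModel(0.3), seed = 131)
  mol <- moleculesFromOutcomes(pool, oc)
  prof <- positionalEnrichment(mol, central = "CG", config = cfg)
  null <- enrichmentPermutationNull(mol, n = 200L, central = "CG",
                                    config = cfg, seed = 132)
  thr <- quantile(null, 0.99)
  expect_true(all(prof$rawSD[prof$valid] < thr))
})

test_that("top-site matrices summarize the most preferred contexts", {
  ## hand table: 4 contexts with distinct levels
  tb <- makeTable(c("AAGG", "CCTT", "GGAA", "TTCC"),
                  nTotal = c(50, 50, 50, 50), nMeth = c(45, 30, 20, 10))
  ## topK = 1: one-hot matrix of the single best context
  pfm <- topSiteMatrix(tb, 1L, minCoverage = 10L)
  expect_equal(dim(pfm), c(4L, 4L))
  expect_equal(colSums(pfm), setNames(rep(1, 4), c("-2", "-1", "+1", "+2")))
  expect_equal(pfm["A", "-2"], 1)
  expect_equal(pfm["G", "+1"], 1)
  expect_error(topSiteMatrix(tb, 5L, minCoverage = 10L), "exceeds")
  ## uniform preference: all entries near 0.25 when every context is taken
  cfg <- testConfig()
  pool <- generatePool(4000, cfg, seed = 140)
  oc <- simulateMethylation(pool, constantModel(0.5), seed = 141)
  tbl <- buildContextTable(moleculesFromOutcomes(pool, oc), 2L, "CG", cfg)
  pfmU <- topSiteMatrix(tbl, nrow(contextCounts(tbl)), minCoverage = 0L)
  expect_true(all(abs(pfmU - 0.25) < 0.05))
})

test_that("table correlation matches the closed form and its invariances", {
  t1 <- makeTable(c("AA", "CC", "GG"), nTotal = rep(100, 3),
                  nMeth = c(10, 20, 30), k = 1)
  t2 <- makeTable(c("AA", "CC", "GG"), nTotal = rep(100, 3),
                  nMeth = c(20, 40, 70), k = 1)
  ## closed-form Pearson of levels {.1,.2,.3} vs {.2,.4,.7}
  ## r = Sxy / sqrt(Sxx Syy) = 5 / sqrt(2 * 114/9) = 0.99339927
  expect_equal(correlateTables(t1, t2, minCoverage = 10)$estimate,
               0.99339927, tolerance = 1e-6)
  ## self-correlation 1, perfect anticorrelation -1
  expect_equal(correlateTables(t1, t1, minCoverage = 0)$estimate, 1.0)
  t3 <- makeTable(c("AA", "CC", "GG"), nTotal = rep(100, 3),
                  nMeth = c(30, 20, 10), k = 1)
  expect_equal(correlateTables(t1, t3, minCoverage = 0)$estimate, -1.0)
  ## symmetric
  expect_equal(correlateTables(t1, t2, 0)$estimate,
               correlateTables(t2, t1, 0)$estimate)
  ## errors: too few shared rows, zero variance
  t4 <- makeTable(c("AA", "CC"), nTotal = c(100, 100), nMeth = c(1, 2),
                  k = 1)
  expect_error(correlateTables(t1, t4, 0), "fewer than 3")
  t5 <- makeTable(c("AA", "CC", "GG"), nTotal = rep(100, 3),
                  nMeth = c(10, 10, 10), k = 1)
  expect_error(correlateTables(t1, t5, 0), "zero variance")
})

test_that("+1 summaries equal brute-force means and marginalization", {
  cfg <- testConfig()
  h <- handMolecules(cfg, n = 40, seed = 150)
  tb <- buildContextTable(h$mol, 2L, "CG", cfg)
  s <- plus1Summary(list(CG = tb))
  ## brute-force group-by over the +1 base of each strand event
  cc <- contextCounts(tb)
  p1 <- substr(cc$context, 3, 3)
  for (b in c("A", "C", "G", "T")) {
    n <- sum(cc$nTotal[p1 == b]); m <- sum(cc$nMeth[p1 == b])
    row <- s[s$central == "CG" & s$plus1 == b, ]
    expect_equal(row$nEvents, n)
    if (n > 0) expect_equal(row$level, m / n) else expect_true(is.na(row$level))
  }
  ## all events methylated: every defined cell 1.0
  molAll <- moleculesFromTruth(as.character(topSequences(h$pool)),
                               rep("methylated", 40), rep("methylated", 40))
  sAll <- plus1Summary(list(CG = buildContextTable(molAll, 2L, "CG", cfg)))
  expect_true(all(sAll$level[sAll$nEvents > 0] == 1.0))
})

test_that("CpN/CpG specificity ratios recover known ratios", {
  ## identical tables -> ratios 1; halved levels -> 0.5 (smoothed estimator)
  ctx <- allContexts(1)
  tCG <- makeTable(ctx, nTotal = rep(1000, 16),
                   nMeth = round(seq(100, 700, length.out = 16)), k = 1)
  tables <- list(CG = tCG, CA = tCG, CT = tCG)
  r <- cpnSpecificity(tables, c("CA", "CT"))
  expect_true(all(abs(r$CA$ratios$ratio - 1) < 1e-12))
  expect_equal(r$CA$median, 1)
  cc <- contextCounts(tCG)
  tHalf <- makeTable(cc$context, cc$nTotal, round(cc$nMeth / 2), "CA", k = 1)
  rHalf <- cpnSpecificity(list(CG = tCG, CA = tHalf), "CA")
  expect_true(all(abs(rHalf$CA$ratios$ratio - 0.5) < 0.02))
  ## simulation: CpA rate 0.3x the CpG rate, median recovered within 10%
  cfg <- testConfig()
  base <- randomPreferenceModel(2L, baseRate = 0.5, sdlog = 0.2, seed = 160)
  poolCG <- generatePool(6000, cfg, seed = 161)
  poolCA <- generatePool(6000, cfg, centralMotif = "CA", seed = 162)
  ocCG <- simulateMethylation(poolCG, base, seed = 163)
  ctxCA <- strandContexts(poolCA, cfg$flankLen, "top")
  pCA <- 0.3 * methylationProb(base, unname(ctxCA))
  set.seed(164)
  stCA <- ifelse(runif(6000) < pCA, "methylated", "unmethylated")
  mols <- rbind(moleculesFromOutcomes(poolCG, ocCG),
                moleculesFromTruth(as.character(topSequences(poolCA)),
                                   stCA, rep("absent", 6000),
                                   ids = sprintf("ca%04d", 1:6000)))
  tabs <- splitByDinucleotide(mols, 2L, cfg)
  rSim <- cpnSpecificity(tabs, "CA", minCoverage = 10L)
  expect_lt(abs(rSim$CA$median - 0.3), 0.03)
})
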