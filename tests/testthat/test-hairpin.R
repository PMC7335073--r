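test_that("quality trimming removes exactly the low-quality suffix", {
  r <- makeReads(c("ACGT", "ACGT", "ACGT", "ACGT"),
                 list(c(40, 40, 40, 40),   # untouched
                      c(40, 40, 10, 10),   # last two removed
                      c(40, 10, 40, 10),   # internal low base retained
                      c(10, 10, 10, 10)))  # fully removed
  t <- trimQuality(r, 20L)
  expect_equal(as.character(t),
               c(r01 = "ACGT", r02 = "AC", r03 = "ACG", r04 = ""))
  ## idempotent
  expect_identical(as.character(trimQuality(t, 20L)), as.character(t))
  ## empty input allowed
  expect_length(trimQuality(r[0], 20L), 0L)
})

test_that("full-length selection accepts the designed layout and types rejections", {
  cfg <- perfectConfig()
  pool <- generatePool(6, cfg, seed = 21)
  tops <- as.character(topSequences(pool))
  good <- vapply(tops, perfectRead, character(1), cfg = cfg)
  D <- nchar(tops[1]); lk <- nchar(cfg$linker)

  reads <- c(good[1],
             substr(good[2], 1, D + 3),              # cut inside the linker
             substr(good[3], 1, D + lk + D - 5),     # antisense truncated
             good[4], good[5], good[6])
  ## one substitution in the linker: tolerated at allowance 1
  substr(reads[4], D + 2, D + 2) <- "T"
  ## two substitutions in the linker (G->T, A->T): rejected
  substr(reads[5], D + 1, D + 2) <- "TT"
  ## two substitutions at non-C arm positions (A, G): arm-mismatch
  ## (a read T over a reference C would match, being the bisulfite image)
  substr(reads[6], 7, 8) <- "TT"

  sel <- selectFullLength(Biostrings::DNAStringSet(reads), cfg)
  expect_equal(sel$reason,
               c("ok", "no-linker", "truncated-antisense", "ok",
                 "no-linker", "arm-mismatch"))
  expect_equal(sel$accepted, sel$reason == "ok")
  ## accepted reads carry the exact designed spans
  expect_equal(sel$sense[1], unname(tops[1]))
  expect_equal(sel$antisense[1], rcOracle(tops[1]))
})

test_that("arm anchors are matched bisulfite-aware (C reads as T)", {
  cfg <- perfectConfig()
  pool <- generatePool(10, cfg, seed = 22)
  oc <- simulateMethylation(pool, constantModel(1), seed = 1)
  f <- tempfile(fileext = ".fastq")
  ## full conversion turns every unmethylated arm C into T on both segments
  emitHairpinFastq(pool, oc, f, config = cfg, seed = 2)
  sel <- selectFullLength(readHairpinFastq(f), cfg)
  expect_true(all(sel$accepted))
})

test_that("the reconstruction decision table is total over its 6 legal pairs", {
  cfg <- perfectConfig()
  D <- nchar(cfg$arm5) + 2 * cfg$flankLen + 2 + nchar(cfg$arm3)
  legal <- list(AT = "A", TA = "T", GC = "G", GT = "G", CG = "C", TG = "C")
  bases <- c("A", "C", "G", "T")
  ## probe every ordered pair at a fixed arm position, on an otherwise
  ## perfect molecule
  pool <- generatePool(1, cfg, seed = 23)
  top <- as.character(topSequences(pool))
  bottomOriented <- chartr("ACGT", "TGCA", top)  # bottom base per duplex pos
  probe <- 3L  # inside the 5' arm
  for (s in bases) for (a in bases) {
    sense <- top; antiOr <- bottomOriented
    substr(sense, probe, probe) <- s
    substr(antiOr, probe, probe) <- a
    ## reconstructMolecules takes the antisense as read (reverse of oriented)
    anti <- vapply(antiOr, function(x)
      paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
      USE.NAMES = FALSE)
    mol <- reconstructMolecules(sense, anti, cfg)
    pair <- paste0(s, a)
    got <- substr(mol$originalTop, probe, probe)
    if (pair %in% names(legal)) {
      expect_identical(got, legal[[pair]])
      expect_equal(mol$nPairMismatches, 0L)
    } else {
      expect_identical(got, "N")
      expect_equal(mol$nPairMismatches, 1L)
    }
    ## output alphabet is always {A,C,G,T,N}
    expect_true(grepl("^[ACGTN]+$", mol$originalTop))
  }
})

test_that("central pairs decide the per-strand methylation states", {
  cfg <- perfectConfig()
  pool <- generatePool(1, cfg, seed = 24)
  top <- as.character(topSequences(pool))
  off <- nchar(cfg$arm5) + cfg$flankLen    # 0-based central C
  bottomOriented <- chartr("ACGT", "TGCA", top)
  rev1 <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  cases <- list(
    ## senseC, antiG (methylated top), senseG pair for bottom
    list(sC = "C", aC = "G", sG = "G", aG = "C",
         top = "methylated", bottom = "methylated"),
    list(sC = "T", aC = "G", sG = "G", aG = "T",
         top = "unmethylated", bottom = "unmethylated"),
    list(sC = "C", aC = "G", sG = "G", aG = "T",
         top = "methylated", bottom = "unmethylated"))
  for (cs in cases) {
    sense <- top; antiOr <- bottomOriented
    substr(sense, off + 1, off + 1) <- cs$sC
    substr(antiOr, off + 1, off + 1) <- cs$aC
    substr(sense, off + 2, off + 2) <- cs$sG
    substr(antiOr, off + 2, off + 2) <- cs$aG
    mol <- reconstructMolecules(sense, rev1(antiOr), cfg)
    expect_equal(mol$stateTop, cs$top)
    expect_equal(mol$stateBottom, cs$bottom)
    expect_true(mol$qcPass)
  }
  ## non-CpG target: bottom state is absent
  poolCA <- generatePool(1, cfg, centralMotif = "CA", seed = 25)
  topCA <- as.character(topSequences(poolCA))
  sense <- topCA
  substr(sense, off + 1, off + 1) <- "T"  # unmethylated converted C
  mol <- reconstructMolecules(sense, rev1(chartr("ACGT", "TGCA", topCA)), cfg)
  expect_equal(mol$stateTop, "unmethylated")
  expect_equal(mol$stateBottom, "absent")
  expect_true(mol$qcPass)
})

test_that("perfect-simulation round trip recovers sequence and states exactly", {
  cfg <- perfectConfig()
  n <- 400
  pool <- generatePool(n, cfg, seed = 26)
  oc <- simulateMethylation(pool, constantModel(0.5), seed = 27)
  f <- tempfile(fileext = ".fastq")
  emitHairpinFastq(pool, oc, f, config = cfg, seed = 28)
  res <- processHairpinReads(f, cfg)
  mol <- res$molecules
  expect_equal(nrow(mol), n)
  expect_true(all(mol$qcPass))
  expect_true(all(mol$nPairMismatches == 0L))
  expect_identical(mol$originalTop,
                   unname(as.character(topSequences(pool))[mol$readId]))
  truth <- moleculesFromOutcomes(pool, oc)
  expect_identical(mol$stateTop, truth[mol$readId, "stateTop"])
  expect_identical(mol$stateBottom, truth[mol$readId, "stateBottom"])
  ## manifest-style counts reconcile
  expect_equal(unname(res$counts[["readsIn"]]),
               unname(res$counts[["accepted"]] + res$counts[["no-linker"]] +
                      res$counts[["truncated-antisense"]] +
                      res$counts[["arm-mismatch"]]))
})

test_that("conversion QC counts fixed-arm cytosines correctly", {
  cfg <- perfectConfig()
  pool <- generatePool(200, cfg, seed = 29)
  oc <- simulateMethylation(pool, constantModel(0.5), seed = 30)
  ## all control cytosines converted -> rate 1.0
  f <- tempfile(fileext = ".fastq")
  emitHairpinFastq(pool, oc, f, config = cfg, seed = 31)
  qc <- estimateConversion(processHairpinReads(f, cfg)$molecules,
                           config = cfg)
  expect_equal(qc$conversionRate, 1.0)
  expect_equal(qc$nConverted, qc$nControl)
  ## simple arithmetic: 995 of 1000
  expect_equal(995 / 1000, 0.995)

  ## partial conversion estimates the simulated rate (binomial envelope)
  cfg2 <- testConfig(seqError = 0, lowTailFrac = 0, conversionRate = 0.998,
                     inappropriateConversion = 0)
  pool2 <- generatePool(3000, cfg2, seed = 32)
  oc2 <- simulateMethylation(pool2, constantModel(0.5), seed = 33)
  f2 <- tempfile(fileext = ".fastq")
  emitHairpinFastq(pool2, oc2, f2, config = cfg2, seed = 34)
  qc2 <- estimateConversion(processHairpinReads(f2, cfg2)$molecules,
                            config = cfg2)
  se3 <- 3 * sqrt(0.998 * 0.002 / qc2$nControl)
  expect_lt(abs(qc2$conversionRate - 0.998), se3)
  ## zero observations is an error
  empty <- reconstructMolecules(character(0), character(0), cfg)
  expect_error(estimateConversion(empty, config = cfg), "undefined")
})
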