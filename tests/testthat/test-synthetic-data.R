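# Planted-signal generator: determinism, planted structure, and the
# statistical properties the downstream filters rely on.

test_that("locus simulation is deterministic and plants what it promises", {
  cfg <- simulationConfig(seed = 1)
  a <- simulateLocus(cfg)
  b <- simulateLocus(cfg)
  expect_identical(as.character(a$seq[[1]]), as.character(b$seq[[1]]))

  gt <- a$groundTruth
  expect_equal(length(creRegions(gt)), 7)
  expect_equal(sum(S4Vectors::mcols(creRegions(gt))$creClass == "promoter"), 1)
  expect_equal(length(plantedSites(gt)), 7 * 2)

  # every planted substring is the consensus or its reverse complement
  cons <- trueConsensus(gt)
  s <- as.character(a$seq[[1]])
  for (i in seq_along(plantedSites(gt))) {
    site <- plantedSites(gt)[i]
    sub <- substr(s, GenomicRanges::start(site), GenomicRanges::end(site))
    expected <- if (as.character(GenomicRanges::strand(site)) == "+") cons
                else revcompStr(cons)
    expect_identical(sub, expected)
  }

  # CREs all within 20 kb of the TSS; sites inside exactly one CRE
  tssPos <- GenomicRanges::start(tssSite(gt))
  expect_true(all(abs(GenomicRanges::start(creRegions(gt)) - tssPos) <= 20000))
  expect_true(all(GenomicRanges::countOverlaps(plantedSites(gt),
                                               creRegions(gt),
                                               type = "within") == 1))
})

test_that("different seeds give different loci; changing nSamples leaves the locus untouched", {
  s1 <- simulateLocus(simulationConfig(seed = 1))
  s2 <- simulateLocus(simulationConfig(seed = 2))
  expect_false(identical(as.character(s1$seq[[1]]), as.character(s2$seq[[1]])))
  s3 <- simulateLocus(simulationConfig(seed = 1, nSamples = 100))
  expect_identical(as.character(s1$seq[[1]]), as.character(s3$seq[[1]]))
})

test_that("noise-free tracks are strongest for the intended mark/class pairing", {
  cfg <- simulationConfig(seed = 2, trackNoiseSd = 0)
  loc <- simulateLocus(cfg)
  trk <- simulateTracks(loc, cfg)
  gt <- loc$groundTruth
  cres <- creRegions(gt)
  cls <- S4Vectors::mcols(cres)$creClass
  prom <- cres[cls == "promoter"][1]
  enh <- cres[cls == "enhancer"]
  mProm <- aggregateSignal(trk$tracks$H3K4me3, prom)
  mEnh <- max(vapply(seq_along(enh), function(i)
    aggregateSignal(trk$tracks$H3K4me3, enh[i]), 0))
  expect_gt(mProm, mEnh)
  dProm <- aggregateSignal(trk$tracks$DNase, prom)
  dEnh <- max(vapply(seq_along(enh), function(i)
    aggregateSignal(trk$tracks$DNase, enh[i]), 0))
  expect_gt(dProm, dEnh)

  # peak BEDs are the bump supports per covered class
  expect_equal(length(trk$peaks$H3K27ac), 7)
  expect_equal(length(trk$peaks$DNase), 7)
  expect_equal(length(trk$peaks$H3K4me3), 1)
  expect_equal(length(trk$peaks$H3K4me1), 6)

  # with a fixed seed, summed noisy signal is bit-reproducible
  cfgN <- simulationConfig(seed = 2)
  t1 <- simulateTracks(loc, cfgN)
  t2 <- simulateTracks(loc, cfgN)
  expect_identical(
    sum(S4Vectors::mcols(trackRegions(t1$tracks$H3K27ac))$score),
    sum(S4Vectors::mcols(trackRegions(t2$tracks$H3K27ac))$score))
})

test_that("planted expression correlation is recovered at large n", {
  cfg <- simulationConfig(seed = 7, nSamples = 10000, targetTfCorrelation = 0.7)
  loc <- simulateLocus(cfg)
  expr <- simulateExpression(loc, cfg)
  gt <- loc$groundTruth
  r <- cor(log2(expr[trueTf(gt), ] + 1), log2(expr[targetGene(gt), ] + 1))
  expect_lt(abs(r - 0.7), 0.03)
  expect_true(all(expr >= 0))
})

test_that("decoy TFs are uncorrelated with the target on average", {
  cfg <- simulationConfig(seed = 8)  # n = 40 samples, 50 decoys
  loc <- simulateLocus(cfg)
  expr <- simulateExpression(loc, cfg)
  gt <- loc$groundTruth
  decoys <- setdiff(simGenes(gt), c(targetGene(gt), trueTf(gt)))
  rs <- vapply(decoys, function(g)
    cor(log2(expr[g, ] + 1), log2(expr[targetGene(gt), ] + 1)), 0)
  expect_lt(mean(abs(rs)), 0.2)
})

test_that("null correlations have approximately correct Fisher-z behavior", {
  # at planted r = 0, |r| should exceed 2/sqrt(n) only ~5% of the time
  n <- 40
  hits <- 0
  for (seed in 1:100) {
    cfg <- simulationConfig(seed = seed, targetTfCorrelation = 0,
                            nTfDecoys = 4)
    loc <- simulateLocus(cfg)
    expr <- simulateExpression(loc, cfg)
    gt <- loc$groundTruth
    r <- cor(log2(expr[trueTf(gt), ] + 1), log2(expr[targetGene(gt), ] + 1))
    if (abs(r) > 2 / sqrt(n)) hits <- hits + 1
  }
  expect_lt(hits, 15)  # ~5 expected from the normal approximation
})

test_that("DE tables hit the planted fractions exactly under the strict thresholds", {
  genes <- sprintf("G%03d", 1:100)
  cfg <- simulationConfig(seed = 4, deUpFraction = 0.1, deDownFraction = 0.1,
                          trueTfDe = FALSE)
  de <- simulateDeTable(genes, cfg)
  cls <- classifyDe(de)                     # FDR < 0.05, FC > 1.5
  expect_equal(sum(cls == "UP"), 10)
  expect_equal(sum(cls == "DOWN"), 10)
  expect_equal(sum(cls == "NDE"), 80)

  zero <- simulateDeTable(genes, simulationConfig(seed = 4, deUpFraction = 0,
                                                  deDownFraction = 0))
  expect_true(all(classifyDe(zero) == "NDE"))

  expect_identical(simulateDeTable(genes, cfg), simulateDeTable(genes, cfg))

  # the true TF lands in the UP set when requested
  cfgT <- simulationConfig(seed = 4, trueTfDe = TRUE)
  deT <- simulateDeTable(c(genes, "TF_TRUE"), cfgT)
  expect_identical(unname(classifyDe(deT)["TF_TRUE"]), "UP")
})

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(nCres = 100, creWidth = 600,
                                locusLength = 50000), "locusLength")
  expect_error(simulationConfig(targetTfCorrelation = 1), "strictly inside")
  expect_error(simulationConfig(deUpFraction = 0.7, deDownFraction = 0.5),
               "deUpFraction")
  # infeasible placement is a clean configuration error
  expect_error(simulateLocus(simulationConfig(seed = 1, locusLength = 9000,
                                              nCres = 8, creWidth = 1000)))
})

test_that("ChIP peak simulation binds the requested fraction, always including the target", {
  cfg <- simulationConfig(seed = 6)
  genes <- c("GENE_TARGET", sprintf("TF_%02d", 1:49))
  chip <- simulateChipPeaks(genes, cfg, boundFraction = 0.3)
  expect_equal(length(chip$bound), 15)
  expect_true("GENE_TARGET" %in% chip$bound)
  asg <- assignTargets(chip$peaks, chip$tss, windowBp = 2000)
  expect_setequal(asg$gene, chip$bound)
})

test_that("a full study writes readable files with consistent ground truth", {
  dir <- file.path(tempdir(), "study1")
  study <- simulateStudy(simulationConfig(seed = 9, nCellTypes = 1), dir = dir)
  expect_true(all(file.exists(study$files)))
  seqs <- readFastaSeqs(study$files["fasta"])
  expect_identical(as.character(seqs[[1]]), as.character(study$locus$seq[[1]]))
  pfms <- readJasparPfm(study$files["pfms"])
  expect_equal(length(pfms), 51)
  expect_identical(motifCounts(pfms$TF_TRUE),
                   motifCounts(study$locus$pfms$TF_TRUE))
  de <- readDeTable(study$files["de"])
  expect_equal(nrow(de), length(simGenes(study$groundTruth)))
  unlink(dir, recursive = TRUE)
})
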