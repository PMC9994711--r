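# CRE calling: signal aggregation, peak union/merge/classification,
# numbering along the gene strand, core-promoter selection, and TSS
# profile matrices.

mkTrack <- function(starts, ends, values, chrom = "chrT", mark = "sig") {
  SignalTrack(GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                                     score = values), mark)
}

test_that("aggregateSignal computes length-weighted means with zero fill", {
  trk <- mkTrack(1, 100, 2.0)
  iv <- GenomicRanges::GRanges("chrT", IRanges::IRanges(11, 40))
  expect_equal(aggregateSignal(trk, iv), 2.0)

  # half covered at 4.0, half uncovered -> 2.0
  trk2 <- mkTrack(1, 50, 4.0)
  iv2 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(26, 75))
  expect_equal(aggregateSignal(trk2, iv2), 2.0)

  # no overlap -> 0
  iv3 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(200, 300))
  expect_equal(aggregateSignal(trk2, iv3), 0)

  # unknown chromosome -> lookup error
  iv4 <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10))
  expect_error(aggregateSignal(trk2, iv4), "absent")
})

test_that("callCres merges nearby peaks and classifies by mark precedence", {
  tss <- GenomicRanges::GRanges("chrT", IRanges::IRanges(10000, 10000),
                                strand = "+")
  # two H3K4me1 peaks 100 bp apart merge into one enhancer at gap 200
  me1 <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(12000, 12401), c(12300, 12700)))
  cres <- callCres(list(H3K4me1 = me1), tss, mergeGapBp = 200)
  expect_equal(length(cres), 1)
  expect_identical(S4Vectors::mcols(cres)$creClass, "enhancer")
  expect_equal(GenomicRanges::start(cres), 12000)
  expect_equal(GenomicRanges::end(cres), 12700)

  # same two peaks with a small merge gap stay separate
  cres2 <- callCres(list(H3K4me1 = me1), tss, mergeGapBp = 50)
  expect_equal(length(cres2), 2)

  # H3K4me3 wins over H3K4me1 when both overlap
  me3 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(12100, 12200))
  cres3 <- callCres(list(H3K4me1 = me1, H3K4me3 = me3), tss, mergeGapBp = 200)
  expect_identical(S4Vectors::mcols(cres3)$creClass, "promoter")

  # DNase alone -> accessible_only
  cres4 <- callCres(list(DNase = me1), tss, mergeGapBp = 200)
  expect_identical(S4Vectors::mcols(cres4)$creClass, "accessible_only")

  # nothing in the window -> empty, not an error
  far <- GenomicRanges::GRanges("chrT", IRanges::IRanges(50000, 50500))
  expect_equal(length(callCres(list(H3K4me1 = far), tss)), 0)
})

test_that("peaks outside the TSS window are clipped away and output is sorted and disjoint", {
  tss <- GenomicRanges::GRanges("chrT", IRanges::IRanges(30000, 30000),
                                strand = "+")
  pks <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(5000, 15000, 29000, 49000, 60000),
                     c(5400, 15400, 29400, 49400, 60400)))
  cres <- callCres(list(H3K27ac = pks), tss, windowBp = 20000)
  expect_equal(length(cres), 3)   # 5000 and 60000 fall outside +/- 20 kb
  expect_true(all(GenomicRanges::start(cres) >= 10000 &
                    GenomicRanges::end(cres) <= 50000))
  expect_true(!is.unsorted(GenomicRanges::start(cres)))
  expect_equal(length(GenomicRanges::findOverlaps(cres, drop.self = TRUE)), 0)

  # enlarging the window keeps every previously called element
  cresWide <- callCres(list(H3K27ac = pks), tss, windowBp = 30000)
  expect_true(all(IRanges::overlapsAny(cres, cresWide)))
  expect_gte(length(cresWide), length(cres))
})

test_that("numbering follows the gene strand with the promoter cluster first", {
  # minus-strand gene: numbering descends along genomic coordinates
  tssM <- GenomicRanges::GRanges("chrT", IRanges::IRanges(20000, 20000),
                                 strand = "-")
  me3 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(20050, 20500))
  me1 <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(12000, 16000), c(12400, 16400)))
  cres <- callCres(list(H3K4me3 = me3, H3K4me1 = me1), tssM)
  n <- S4Vectors::mcols(cres)$number
  # the promoter (highest genomic coordinate, upstream of a minus gene) is CRE1
  expect_equal(n[S4Vectors::mcols(cres)$creClass == "promoter"], 1)
  expect_equal(sort(n), 1:3)
  expect_equal(n[order(GenomicRanges::start(cres), decreasing = TRUE)], 1:3)

  # multi-cell-type support counting
  cts <- list(ct1 = me1, ct2 = me1[1])
  cresCt <- callCres(list(H3K4me1 = cts), tssM, minCellTypes = 2)
  expect_equal(length(cresCt), 1)  # only the peak seen in both cell types
  expect_equal(GenomicRanges::start(cresCt), 12000)
})

test_that("the synthetic locus is recovered perfectly at zero noise", {
  cfg <- simulationConfig(seed = 11, trackNoiseSd = 0)
  study <- simulateStudy(cfg)
  gt <- study$groundTruth
  cres <- callCres(study$tracks$peaks, tssSite(gt))
  truth <- creRegions(gt)
  expect_equal(length(cres), length(truth))

  # reciprocal overlap >= 50% in both directions, classes matching
  ov <- GenomicRanges::findOverlaps(cres, truth)
  expect_equal(length(ov), length(truth))
  inter <- IRanges::pintersect(cres[S4Vectors::queryHits(ov)],
                               truth[S4Vectors::subjectHits(ov)])
  recip <- IRanges::width(inter) /
    pmax(IRanges::width(cres[S4Vectors::queryHits(ov)]),
         IRanges::width(truth[S4Vectors::subjectHits(ov)]))
  expect_true(all(recip >= 0.5))
  expect_identical(
    S4Vectors::mcols(cres)$creClass[S4Vectors::queryHits(ov)],
    S4Vectors::mcols(truth)$creClass[S4Vectors::subjectHits(ov)])

  # renumbering after filtering stays consecutive from 1
  keep <- cres[S4Vectors::mcols(cres)$creClass == "enhancer"]
  renum <- callCres(list(H3K27ac = GenomicRanges::granges(keep)), tssSite(gt))
  expect_equal(sort(S4Vectors::mcols(renum)$number),
               seq_along(renum))
})

test_that("core-promoter selection maximizes DNase and honors the tie-break", {
  cfg <- simulationConfig(seed = 12, trackNoiseSd = 0)
  study <- simulateStudy(cfg)
  gt <- study$groundTruth
  cres <- callCres(study$tracks$peaks, tssSite(gt))
  core <- selectCorePromoter(cres, study$tracks$tracks$DNase, tssSite(gt))
  truthProm <- creRegions(gt)[S4Vectors::mcols(creRegions(gt))$creClass ==
                                "promoter"]
  expect_true(IRanges::overlapsAny(core, truthProm))

  # single promoter CRE is returned regardless of signal
  one <- cres[S4Vectors::mcols(cres)$creClass == "promoter"]
  expect_equal(GenomicRanges::start(
    selectCorePromoter(one, study$tracks$tracks$DNase, tssSite(gt))),
    GenomicRanges::start(one))

  # equal signal -> smallest start wins
  tss <- GenomicRanges::GRanges("chrT", IRanges::IRanges(5000, 5000),
                                strand = "+")
  two <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(4000, 4500), c(4300, 4800)),
    number = 1:2, creClass = "promoter")
  flat <- mkTrack(1, 10000, 1.0)
  expect_equal(GenomicRanges::start(selectCorePromoter(two, flat, tss)), 4000)

  # no promoter-class CRE -> NULL with diagnostic
  enh <- GenomicRanges::GRanges("chrT", IRanges::IRanges(4000, 4300),
                                number = 1L, creClass = "enhancer")
  expect_warning(res <- selectCorePromoter(enh, flat, tss), "no promoter")
  expect_null(res)
})

test_that("TSS profile matrices bin, orient and average correctly", {
  flat <- mkTrack(1, 10000, 3.0)
  tss <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(3000, 7000),
                                                         c(3000, 7000)),
                                strand = c("+", "+"))
  prof <- tssProfileMatrix(flat, tss, flankBp = 2000, nBins = 100)
  expect_equal(dim(prof$matrix), c(2, 100))
  expect_true(all(abs(prof$matrix - 3.0) < 1e-12))
  expect_equal(prof$mean, rep(3.0, 100), ignore_attr = TRUE)

  # single sharp peak at the TSS -> maximal central bins
  peak <- mkTrack(2990, 3010, 10)
  p2 <- tssProfileMatrix(peak, tss[1], flankBp = 2000, nBins = 100)
  expect_true(which.max(p2$mean) %in% 50:51)

  # asymmetric signal mirrors between strands
  asym <- mkTrack(3000, 3500, 5)   # downstream of the + TSS
  plus <- tssProfileMatrix(asym, tss[1], flankBp = 2000, nBins = 100)
  tssMinus <- tss[1]
  GenomicRanges::strand(tssMinus) <- "-"
  minus <- tssProfileMatrix(asym, tssMinus, flankBp = 2000, nBins = 100)
  expect_equal(unname(minus$matrix[1, ]), unname(rev(plus$matrix[1, ])))
  expect_false(isTRUE(all.equal(plus$matrix[1, ], minus$matrix[1, ],
                                check.attributes = FALSE)))

  expect_error(tssProfileMatrix(flat, tss[0]), "empty")
})
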