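# PWM construction, exact score-distribution p-values (against an
# exhaustive k-mer enumeration oracle), double-strand scanning and
# Bumscore counting.

test_that("log-odds construction matches the closed form", {
  # uniform counts + uniform background -> all entries 0
  uni <- buildPwm(PFM("U", matrix(5, 4, 5, dimnames = list(c("A","C","G","T"), NULL))))
  expect_true(all(abs(motifMatrix(uni)) < 1e-12))

  # one-hot column: count 10 for A, pseudocount 0.5, uniform background
  pwm <- buildPwm(oneHotPfm("AAAA"), pseudocount = 0.5)
  expected <- log2((10 + 0.5 * 0.25) / (10 + 0.5) / 0.25)
  expect_equal(unname(motifMatrix(pwm)["A", 1]), expected, tolerance = 1e-3)

  # changing the background shifts entries by -log2(bg ratio)
  bg2 <- c(0.3, 0.2, 0.2, 0.3)
  pwm2 <- buildPwm(oneHotPfm("AAAA"), background = bg2)
  # entry(A) under bg2 = log2(freqA/0.3) with freqA = (10 + .5*.3)/10.5
  expect_equal(unname(motifMatrix(pwm2)["A", 1]),
               log2((10 + 0.5 * 0.3) / 10.5 / 0.3), tolerance = 1e-3)

  expect_error(buildPwm(oneHotPfm("AAAA"), pseudocount = 0), "pseudocount")
})

test_that("DP score distribution equals exhaustive k-mer enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    pfm <- randomPfm(5, id = paste0("R", rep))
    pwm <- buildPwm(pfm)
    enum <- enumerateKmerScores(motifMatrix(pwm))
    # tail probability at every distinct achievable score agrees
    for (s in sample(unique(enum$score), 10)) {
      expect_equal(pwmTailProbability(pwm, s), enumTail(enum, s),
                   tolerance = 1e-10)
    }
  }
})

test_that("score thresholds are monotone and reach the minimum at p = 1", {
  pwm <- buildPwm(randomPfm(6, id = "mono"))
  enum <- enumerateKmerScores(motifMatrix(pwm))
  expect_equal(scoreThreshold(pwm, 1), min(enum$score), tolerance = 2e-3)
  ps <- c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 1)
  th <- vapply(ps, function(p) scoreThreshold(pwm, p), 0)
  expect_true(all(diff(th) <= 1e-12))  # looser p -> lower threshold
  expect_error(scoreThreshold(pwm, 0), "p must lie")
})

test_that("threshold semantics: P(score >= threshold) <= p, and the next lattice score below fails", {
  set.seed(12)
  pwm <- buildPwm(randomPfm(5, id = "sem"))
  enum <- enumerateKmerScores(motifMatrix(pwm))
  for (p in c(1e-4, 1e-3, 0.05)) {
    th <- scoreThreshold(pwm, p)
    expect_lte(enumTail(enum, th), p + 1e-12)
    below <- max(enum$score[enum$score < th - 1e-9], -Inf)
    if (is.finite(below)) expect_gt(enumTail(enum, below), p)
  }
})

test_that("scanning finds a planted consensus on either strand, in forward coordinates", {
  set.seed(21)
  consensus <- "ACGTTGCA"
  pwm <- buildPwm(oneHotPfm(consensus, major = 85, minor = 5))
  bg <- randSeq(200)
  plant <- function(s, at, ins) paste0(substr(s, 1, at - 1), ins,
                                       substr(s, at + nchar(ins), nchar(s)))
  fwdSeq <- plant(bg, 11, consensus)
  hits <- scanSequence(fwdSeq, pwm, p = 1e-4)
  expect_equal(length(hits), 1)
  expect_equal(GenomicRanges::start(hits), 11)
  expect_equal(GenomicRanges::width(hits), 8)
  expect_identical(as.character(GenomicRanges::strand(hits)), "+")

  revSeq <- plant(bg, 11, revcompStr(consensus))
  rhits <- scanSequence(revSeq, pwm, p = 1e-4)
  expect_equal(GenomicRanges::start(rhits), 11)
  expect_identical(as.character(GenomicRanges::strand(rhits)), "-")

  expect_equal(length(scanSequence(strrep("N", 50), pwm, p = 1e-4)), 0)
})

test_that("scanning is strand-symmetric under reverse complement", {
  set.seed(22)
  for (rep in 1:10) {
    pwm <- buildPwm(randomPfm(6, id = paste0("S", rep)))
    s <- randSeq(300)
    h1 <- scanSequence(s, pwm, p = 1e-3)
    h2 <- scanSequence(revcompStr(s), pwm, p = 1e-3)
    # mirrored coordinates: start' = n - end + 1, strands swapped
    m1 <- data.frame(
      start = as.integer(300 - GenomicRanges::end(h1) + 1),
      strand = as.character(
        ifelse(as.character(GenomicRanges::strand(h1)) == "+", "-", "+")),
      score = round(S4Vectors::mcols(h1)$score, 9))
    m2 <- data.frame(start = GenomicRanges::start(h2),
                     strand = as.character(GenomicRanges::strand(h2)),
                     score = round(S4Vectors::mcols(h2)$score, 9))
    expect_equal(m1[order(m1$start, m1$strand), , drop = FALSE],
                 m2[order(m2$start, m2$strand), , drop = FALSE],
                 ignore_attr = TRUE)
    if (rep == 1) expect_gt(length(h1), 0)  # the property is not vacuous
  }
})

test_that("Bumscore counts planted non-overlapping sites per CRE", {
  consensus <- "ACGTTGCA"
  pwm <- buildPwm(oneHotPfm(consensus, major = 85, minor = 5))
  set.seed(31)
  bg <- randSeq(2000)
  ins <- function(s, at, x) paste0(substr(s, 1, at - 1), x,
                                   substr(s, at + nchar(x), nchar(s)))
  # 3 sites in CRE1 (101-400), 2 in CRE2 (1001-1300)
  s <- bg
  for (at in c(120, 200, 300, 1050, 1150)) s <- ins(s, at, consensus)
  cres <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(101, 1001),
                                                          c(400, 1300)),
                                 name = c("CRE1", "CRE2"))
  genome <- Biostrings::DNAStringSet(c(chrT = s))
  bum <- computeBumscore(list(pwm), cres, genome, p = 1e-4)
  expect_equal(unname(bum$creCounts[1, ]), c(3, 2))
  expect_equal(bum$bumscore, 5)

  # zero CREs -> bumscore 0
  bum0 <- computeBumscore(list(pwm), cres[0], genome, p = 1e-4)
  expect_equal(bum0$bumscore, 0)

  # out-of-bounds CRE -> coordinate error
  badCre <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1900, 2100))
  expect_error(computeBumscore(list(pwm), badCre, genome), "outside")
})

test_that("overlapping same-TF hits collapse to the single best-scoring one", {
  # a palindromic consensus hits both strands at the same interval
  pal <- "ACGCGT"
  pwm <- buildPwm(oneHotPfm(pal, major = 85, minor = 5))
  set.seed(32)
  s <- paste0(randSeq(50), pal, randSeq(50))
  cres <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, nchar(s)))
  bum <- computeBumscore(list(pwm), cres,
                         Biostrings::DNAStringSet(c(chrT = s)), p = 1e-3)
  hits <- S4Vectors::metadata(bum)$hits[[1]]
  expect_equal(bum$bumscore, length(hits))
  # no two retained hits overlap
  if (length(hits) > 1)
    expect_equal(length(GenomicRanges::findOverlaps(hits, drop.self = TRUE,
                                                    ignore.strand = TRUE)), 0)
  # the palindrome interval is counted once, not twice
  expect_equal(sum(GenomicRanges::start(hits) == 51), 1)
})

test_that("Bumscore never loses planted sites as p loosens", {
  cfg <- simulationConfig(seed = 5, trackNoiseSd = 0)
  study <- simulateStudy(cfg)
  gt <- study$groundTruth
  cres <- creRegions(gt)
  bums <- vapply(c(1e-6, 1e-5, 1e-4, 1e-3),
                 function(p) computeBumscore(study$locus$pfms["TF_TRUE"], cres,
                                             study$locus$seq, p = p)$bumscore,
                 0L)
  expect_true(all(diff(bums) >= 0))
  expect_gte(bums[3], length(plantedSites(gt)))  # >= sites per CRE x n CREs
})
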