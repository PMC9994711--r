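# Shared fixtures and independent oracles, all built in code.

writeTmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# One-hot PFM whose consensus is `seq` (count `major` on the consensus
# base, 0 elsewhere unless `minor` given).
oneHotPfm <- function(seq, major = 10, minor = 0, id = "M1") {
  b <- strsplit(seq, "")[[1]]
  m <- matrix(minor, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(b, c("A", "C", "G", "T")), seq_along(b))] <- major
  PFM(id, m)
}

randomPfm <- function(len, id = "R1", total = 20) {
  counts <- replicate(len, as.vector(stats::rmultinom(1, total, rep(0.25, 4))))
  counts[counts == 0 & row(counts) == 1] <- 0  # zeros allowed
  if (any(colSums(counts) == 0)) counts[1, colSums(counts) == 0] <- 1
  rownames(counts) <- c("A", "C", "G", "T")
  PFM(id, counts)
}

# Independent oracle: enumerate all 4^L k-mers, score them with `mat`
# column by column, weight by the background product. Returns a
# data.frame(score, prob) independent of the package's DP convolution.
enumerateKmerScores <- function(mat, bg = rep(0.25, 4)) {
  L <- ncol(mat)
  idx <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(idx))
  probs <- rep(1, nrow(idx))
  for (j in seq_len(L)) {
    scores <- scores + mat[cbind(idx[, j], j)]
    probs <- probs * bg[idx[, j]]
  }
  data.frame(score = scores, prob = probs)
}

enumTail <- function(enum, s) sum(enum$prob[enum$score >= s - 1e-9])

# Independent hypergeometric upper-tail sum via log-binomials:
# P(X >= a) for X ~ Hyper(white = setSize, black = U - setSize, drawn = listSize)
hyperTailOracle <- function(a, setSize, listSize, universe) {
  kmax <- min(setSize, listSize)
  if (a > kmax) return(0)
  ks <- a:kmax
  terms <- lchoose(setSize, ks) + lchoose(universe - setSize, listSize - ks) -
    lchoose(universe, listSize)
  sum(exp(terms))
}

revcompStr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
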