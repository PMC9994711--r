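## I/O boundary: every external format crosses into validated in-memory
## objects here and nowhere else. BED / bedGraph are 0-based half-open on
## disk and converted once to the 1-based closed GRanges convention; no
## coordinate arithmetic elsewhere in the package reconverts.

.ioStop <- function(path, line, msg) {
  where <- if (is.null(line)) path else paste0(path, ":", line)
  stop(sprintf("[%s] %s", where, msg), call. = FALSE)
}

.readLinesChecked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a FASTA file of nucleotide sequences
#'
#' Parses with \code{\link[Biostrings]{readBStringSet}}, then validates
#' that identifiers are unique and sequences are non-empty and contain
#' only A, C, G, T or N (case-folded to upper case).
#'
#' @param path FASTA file (optionally gzipped).
#' @return A \link[Biostrings]{DNAStringSet}, names = record ids (first
#'   whitespace-delimited token of each header).
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .ioStop(path, NULL,
                    paste("malformed FASTA:", conditionMessage(e))))
  if (length(raw) == 0L) .ioStop(path, NULL, "FASTA contains no records")
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    .ioStop(path, NULL, paste("duplicate sequence id:",
                              ids[duplicated(ids)][1L]))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L))
    .ioStop(path, NULL, paste("empty sequence for id:",
                              ids[nchar(seqs) == 0L][1L]))
  bad <- gsub("[ACGTN]", "", seqs)
  if (any(nchar(bad) > 0L)) {
    i <- which(nchar(bad) > 0L)[1L]
    .ioStop(path, NULL, sprintf(
      "sequence '%s' contains invalid character(s): %s", ids[i],
      paste(unique(strsplit(bad[i], "")[[1L]]), collapse = ", ")))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named \link[Biostrings]{DNAStringSet} or named character.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaSeqs <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

.parseBedLines <- function(lines, path, minCols, maxCols) {
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < minCols | ncols > maxCols)
  if (length(bad))
    .ioStop(path, idx[bad[1L]],
            sprintf("expected %d-%d tab-separated columns, found %d",
                    minCols, maxCols, ncols[bad[1L]]))
  list(fields = fields, lineno = idx)
}

.numOrStop <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    i <- which(is.na(v))[1L]
    .ioStop(path, lineno[i], sprintf("non-numeric %s: '%s'", what, x[i]))
  }
  v
}

#' Read a BED3-BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open on disk; the returned GRanges is
#' 1-based closed (the conversion happens here, once). Input order is
#' preserved. Strand "." is kept as "*"; both ASCII "-" and the Unicode
#' minus sign are accepted.
#'
#' @param path BED file with 3 to 6 columns.
#' @return GRanges, with \code{name} / \code{score} metadata columns when
#'   present in the file.
#' @export
readBed <- function(path) {
  lines <- .readLinesChecked(path)
  p <- .parseBedLines(lines, path, 3L, 6L)
  if (length(p$fields) == 0L)
    return(GenomicRanges::GRanges())
  chrom <- vapply(p$fields, `[`, "", 1L)
  start0 <- .numOrStop(vapply(p$fields, `[`, "", 2L), path, p$lineno, "start")
  end0 <- .numOrStop(vapply(p$fields, `[`, "", 3L), path, p$lineno, "end")
  bad <- which(start0 < 0)
  if (length(bad)) .ioStop(path, p$lineno[bad[1L]], "negative start coordinate")
  bad <- which(start0 >= end0)
  if (length(bad))
    .ioStop(path, p$lineno[bad[1L]],
            sprintf("empty or inverted interval (start %d >= end %d)",
                    start0[bad[1L]], end0[bad[1L]]))
  ncols <- lengths(p$fields)
  name <- ifelse(ncols >= 4L, vapply(p$fields, function(f) f[4L], ""), NA)
  score <- rep(NA_real_, length(chrom))
  has5 <- ncols >= 5L
  if (any(has5))
    score[has5] <- .numOrStop(vapply(p$fields[has5], `[`, "", 5L),
                              path, p$lineno[has5], "score")
  strand <- rep("*", length(chrom))
  has6 <- ncols >= 6L
  if (any(has6)) {
    s <- vapply(p$fields[has6], `[`, "", 6L)
    s[s == "−"] <- "-"
    s[s == "."] <- "*"
    bad <- which(!s %in% c("+", "-", "*"))
    if (length(bad))
      .ioStop(path, p$lineno[has6][bad[1L]], paste("invalid strand:", s[bad[1L]]))
    strand[has6] <- s
  }
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start0 + 1L, end0), strand = strand)
  if (any(ncols >= 4L)) S4Vectors::mcols(gr)$name <- name
  if (any(has5)) S4Vectors::mcols(gr)$score <- score
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED3/BED6 (6 columns whenever a name, score or strand is
#' informative), converting back to 0-based half-open.
#'
#' @param gr GRanges.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  hasExtra <- "name" %in% names(mc) || "score" %in% names(mc) ||
    any(as.character(GenomicRanges::strand(gr)) != "*")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (hasExtra) {
    nm <- if ("name" %in% names(mc)) mc$name else rep(".", length(gr))
    nm[is.na(nm)] <- "."
    sc <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
    sc[is.na(sc)] <- 0
    st <- as.character(GenomicRanges::strand(gr))
    st[st == "*"] <- "."
    df <- cbind(df, name = nm, score = sc, strand = st)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a SignalTrack
#'
#' Validates the 4-column format, requires finite non-negative values, and
#' rejects overlapping intervals (an overlapping coverage track is
#' ill-defined). Intervals are sorted by (chrom, start).
#'
#' @param path bedGraph file.
#' @param mark assay label to attach (e.g. \code{"H3K27ac"}).
#' @param sample sample / cell-type label to attach.
#' @return A \linkS4class{SignalTrack}.
#' @export
readBedGraph <- function(path, mark = "signal", sample = "sample") {
  lines <- .readLinesChecked(path)
  p <- .parseBedLines(lines, path, 4L, 4L)
  if (length(p$fields) == 0L)
    return(SignalTrack(GenomicRanges::GRanges(score = numeric()), mark, sample))
  chrom <- vapply(p$fields, `[`, "", 1L)
  start0 <- .numOrStop(vapply(p$fields, `[`, "", 2L), path, p$lineno, "start")
  end0 <- .numOrStop(vapply(p$fields, `[`, "", 3L), path, p$lineno, "end")
  value <- .numOrStop(vapply(p$fields, `[`, "", 4L), path, p$lineno, "value")
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad)) .ioStop(path, p$lineno[bad[1L]], "invalid interval coordinates")
  bad <- which(!is.finite(value) | value < 0)
  if (length(bad))
    .ioStop(path, p$lineno[bad[1L]],
            sprintf("signal value must be finite and >= 0, found %s",
                    value[bad[1L]]))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                               score = value)
  gr <- GenomicRanges::sort(gr)
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                    drop.redundant = TRUE)
  if (length(ov) > 0L)
    .ioStop(path, NULL, "overlapping intervals: the track is ill-defined")
  SignalTrack(gr, mark, sample)
}

#' Write a SignalTrack as bedGraph
#'
#' @param st \linkS4class{SignalTrack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(st, path) {
  gr <- trackRegions(st)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = S4Vectors::mcols(gr)$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a JASPAR-format motif library
#'
#' Accepts the JASPAR 2016+ text format: a \code{">ID NAME"} header
#' followed by four count rows in A, C, G, T order, with or without the
#' \code{A [ ... ]} row labels and brackets. Rows labelled out of order
#' are normalized to A, C, G, T.
#'
#' @param path motif file.
#' @return A named list of \linkS4class{PFM} objects (names = motif ids).
#' @export
readJasparPfm <- function(path) {
  lines <- .readLinesChecked(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) .ioStop(path, NULL, "no '>' motif headers found")
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- list()
  for (k in seq_along(hdr)) {
    block <- lines[hdr[k]:ends[k]]
    header <- sub("^>\\s*", "", block[1L])
    toks <- strsplit(trimws(header), "\\s+")[[1L]]
    id <- toks[1L]
    tf <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    rows <- block[-1L]
    if (length(rows) != 4L)
      .ioStop(path, NULL, sprintf("motif %s: expected 4 count rows, found %d",
                                  id, length(rows)))
    labels <- toupper(sub("^\\s*([ACGTacgt])[\\s\\[].*$", "\\1", rows,
                          perl = TRUE))
    labelled <- all(labels %in% DNA_BASES4) && !anyDuplicated(labels)
    vals <- lapply(rows, function(r) {
      r <- gsub("^\\s*[ACGTacgt]?\\s*\\[?", "", r, perl = TRUE)
      r <- gsub("\\]\\s*$", "", r)
      v <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1L]]))
      if (anyNA(v))
        .ioStop(path, NULL, sprintf("motif %s: non-numeric count row", id))
      v
    })
    if (length(unique(lengths(vals))) != 1L)
      .ioStop(path, NULL, sprintf("motif %s: count rows have unequal lengths (%s)",
                                  id, paste(lengths(vals), collapse = ", ")))
    m <- do.call(rbind, vals)
    rownames(m) <- if (labelled) labels else DNA_BASES4
    m <- m[DNA_BASES4, , drop = FALSE]
    if (any(colSums(m) <= 0))
      .ioStop(path, NULL, sprintf("motif %s: all-zero count column", id))
    pfm <- tryCatch(PFM(id, m, tf = tf), error = function(e)
      .ioStop(path, NULL, sprintf("motif %s: %s", id, conditionMessage(e))))
    out[[id]] <- pfm
  }
  out
}

#' Write a motif library in JASPAR text format
#'
#' @param pfms list of \linkS4class{PFM}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeJasparPfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pfm in pfms) {
    writeLines(paste0(">", motifId(pfm), " ", tfName(pfm)), con)
    m <- motifCounts(pfm)
    for (b in DNA_BASES4)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m[b, ], trim = TRUE), collapse = " ")),
                 con)
  }
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column = gene identifiers, remaining columns = samples; values
#' on the CPM scale (or raw counts with \code{counts = TRUE}, recorded in
#' the \code{"counts"} attribute).
#'
#' @param path TSV file with a header row.
#' @param counts logical; values are raw counts rather than CPM.
#' @return numeric matrix genes x samples with a \code{counts} attribute.
#' @export
readExpressionMatrix <- function(path, counts = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    .ioStop(path, NULL, "expression table needs a gene column plus >= 1 sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    .ioStop(path, NULL, paste("duplicate gene id:", genes[duplicated(genes)][1L]))
  sam <- colnames(df)[-1L]
  if (anyDuplicated(sam))
    .ioStop(path, NULL, paste("duplicate sample id:", sam[duplicated(sam)][1L]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    badcol <- sam[which(!vapply(df[-1L], is.numeric, TRUE))[1L]]
    .ioStop(path, NULL, paste("non-numeric values in column:", badcol))
  }
  if (any(!is.finite(m)) || any(m < 0))
    .ioStop(path, NULL, "expression values must be finite and >= 0")
  rownames(m) <- genes
  attr(m, "counts") <- isTRUE(counts)
  m
}

#' Write an expression matrix as TSV
#'
#' @param m genes x samples matrix.
#' @param path output path.
#' @param geneCol name of the identifier column.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(m, path, geneCol = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1L] <- geneCol
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Requires columns \code{gene}, \code{log2fc}, \code{fdr}; validates one
#' record per gene and \code{fdr} in [0, 1].
#'
#' @param path TSV file with a header row.
#' @return data.frame with columns gene, log2fc, fdr.
#' @export
readDeTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("gene", "log2fc", "fdr"))
    if (!col %in% colnames(df))
      .ioStop(path, NULL, paste("missing required column:", col))
  for (col in c("log2fc", "fdr"))
    if (!is.numeric(df[[col]]) || anyNA(df[[col]]))
      .ioStop(path, NULL, paste("non-numeric values in column:", col))
  if (any(df$fdr < 0 | df$fdr > 1))
    .ioStop(path, NULL, "column fdr must lie in [0, 1]")
  if (anyDuplicated(df$gene))
    .ioStop(path, NULL,
            paste("duplicate gene in DE table:", df$gene[duplicated(df$gene)][1L]))
  df[, c("gene", "log2fc", "fdr")]
}

#' Write a differential-expression table as TSV
#'
#' @param de data.frame with columns gene, log2fc, fdr.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDeTable <- function(de, path) {
  utils::write.table(de[, c("gene", "log2fc", "fdr")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' TSV with columns \code{gene}, \code{chrom}, \code{tss} (1-based
#' position) and \code{strand}.
#'
#' @param path TSV file.
#' @return GRanges of single-bp TSS positions, names = gene ids.
#' @export
readTssTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("gene", "chrom", "tss", "strand"))
    if (!col %in% colnames(df))
      .ioStop(path, NULL, paste("missing required column:", col))
  if (anyDuplicated(df$gene))
    .ioStop(path, NULL, "duplicate gene ids in TSS annotation")
  s <- df$strand
  s[s %in% c(".", "")] <- "*"
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$tss, df$tss),
                               strand = s)
  names(gr) <- df$gene
  gr
}

#' Write a TSS annotation table
#'
#' @param tss named GRanges of TSS positions.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTssTable <- function(tss, path) {
  df <- data.frame(gene = names(tss),
                   chrom = as.character(GenomicRanges::seqnames(tss)),
                   tss = GenomicRanges::start(tss),
                   strand = as.character(GenomicRanges::strand(tss)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT geneset file
#'
#' @param path GMT file (set name, description, member genes; tab-separated).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- .readLinesChecked(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      .ioStop(path, i, "GMT lines need name, description and >= 1 gene")
    out[[f[1L]]] <- unique(f[-(1:2)])
  }
  out
}
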