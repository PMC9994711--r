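## End-to-end orchestration: simulate (or read) inputs, call CREs, count
## binding sites, correlate, prioritize, and map ChIP targets, writing
## every stage's table plus a JSON run manifest. All randomness flows
## from the single master seed; identical config + inputs give
## byte-identical outputs.

.ANALYSIS_DEFAULTS <- list(
  pvalue = 1e-4, pseudocount = 0.5, windowBp = 20000L, mergeGapBp = 200L,
  minCellTypes = 1L, bumscoreStrict = 3, rMin = 0.3, bumscoreRelaxed = 2,
  cap = 96, fdrMax = 0.05, fcMin = 1.5, targetWindowBp = 2000L,
  chipBoundFraction = 0.3)

.checkKnownKeys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
}

#' Promoter accessibility per TF
#'
#' DNase aggregate signal at the core promoter for every TF with at
#' least one predicted site in a promoter-class CRE; 0 for the rest.
#'
#' @param bum \link[S4Vectors]{DataFrame} from
#'   \code{\link{computeBumscore}}.
#' @param cres GRanges from \code{\link{callCres}}.
#' @param corePromoter single-range GRanges from
#'   \code{\link{selectCorePromoter}} (or NULL).
#' @param dnase \linkS4class{SignalTrack} of DNase accessibility.
#' @return numeric vector, one accessibility value per TF.
#' @export
promoterAccessibility <- function(bum, cres, corePromoter, dnase) {
  if (is.null(corePromoter) || length(cres) == 0L)
    return(rep(0, nrow(bum)))
  promCols <- which(S4Vectors::mcols(cres)$creClass == "promoter")
  if (length(promCols) == 0L) return(rep(0, nrow(bum)))
  acc <- aggregateSignal(dnase, corePromoter)
  hasPromHit <- rowSums(bum$creCounts[, promCols, drop = FALSE]) >= 1L
  ifelse(hasPromHit, acc, 0)
}

.readPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    cfg <- yaml::read_yaml(config)
    attr(cfg, "path") <- config
    cfg
  } else if (is.list(config)) config
  else stop("config must be a YAML path or a list", call. = FALSE)
}

#' Run the full prioritization pipeline
#'
#' Stages: simulate (unless \code{inputs} paths are given) -> call CREs
#' -> Bumscore -> TF-target correlation -> composite score + selection ->
#' ChIP-target assignment -> DE crosstab -> geneset enrichment. Every
#' stage writes a TSV/BED under \code{outdir}; a \code{manifest.json}
#' records the echoed configuration, seed, package version and per-stage
#' row counts.
#'
#' @param config YAML file path or list with optional sections
#'   \code{seed} (integer), \code{simulation} (fields of
#'   \code{\link{simulationConfig}} minus seed), \code{analysis}
#'   (thresholds and windows; see details) and \code{inputs} (paths to
#'   pre-existing input files; when present the simulation stage is
#'   skipped). Unknown keys are rejected.
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory stage results:
#'   \code{cres}, \code{corePromoter}, \code{bumscore},
#'   \code{correlations}, \code{candidates}, \code{recovery} (synthetic
#'   mode only), \code{targets}, \code{crosstab}, \code{enrichment},
#'   \code{manifest}.
#' @export
runPipeline <- function(config = list(), outdir) {
  cfg <- .readPipelineConfig(config)
  .checkKnownKeys(cfg, c("seed", "simulation", "analysis", "inputs"),
                  "config")
  .checkKnownKeys(cfg$analysis, names(.ANALYSIS_DEFAULTS), "analysis")
  ana <- utils::modifyList(.ANALYSIS_DEFAULTS, as.list(cfg$analysis))
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  synthetic <- is.null(cfg$inputs)
  if (synthetic) {
    simArgs <- as.list(cfg$simulation)
    .checkKnownKeys(simArgs, setdiff(names(formals(simulationConfig)), "seed"),
                    "simulation")
    simConfig <- do.call(simulationConfig, c(list(seed = seed), simArgs))
    inputDir <- file.path(outdir, "inputs")
    study <- simulateStudy(simConfig, dir = inputDir)
    paths <- as.list(study$files)
    paths$peaks <- stats::setNames(
      file.path(inputDir, paste0("peaks_", names(study$tracks$peaks), ".bed")),
      names(study$tracks$peaks))
    paths$tracks <- stats::setNames(
      file.path(inputDir, paste0("track_", names(study$tracks$tracks),
                                 ".bedGraph")),
      names(study$tracks$tracks))
    trueTfId <- trueTf(study$groundTruth)
  } else {
    paths <- cfg$inputs
    .checkKnownKeys(paths, c("fasta", "tss", "pfms", "peaks", "tracks",
                             "expression", "de", "chipTss", "chipPeaks",
                             "genesets"), "inputs")
    flat <- unlist(paths, use.names = FALSE)
    missing <- flat[!file.exists(flat)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    trueTfId <- NULL
  }

  ## --- read inputs back through the I/O layer -------------------------
  genome <- readFastaSeqs(paths$fasta)
  tss <- readTssTable(paths$tss)
  pfms <- readJasparPfm(paths$pfms)
  peaks <- lapply(paths$peaks, readBed)
  tracks <- mapply(readBedGraph, paths$tracks, names(paths$tracks),
                   SIMPLIFY = FALSE)
  expr <- readExpressionMatrix(paths$expression)
  de <- readDeTable(paths$de)

  ## --- CRE calling ----------------------------------------------------
  cres <- callCres(peaks, tss[1L], windowBp = ana$windowBp,
                   minCellTypes = ana$minCellTypes,
                   mergeGapBp = ana$mergeGapBp, tracks = tracks)
  writeBed(cres, file.path(outdir, "cres.bed"))
  dnase <- tracks[[grep("dnase", names(tracks), ignore.case = TRUE)[1L]]]
  corePromoter <- selectCorePromoter(cres, dnase, tss[1L])

  ## --- Bumscore --------------------------------------------------------
  pwms <- lapply(pfms, buildPwm, pseudocount = ana$pseudocount)
  bum <- computeBumscore(pwms, cres, genome, p = ana$pvalue)
  bumOut <- data.frame(tf = bum$tf, bum$creCounts, bumscore = bum$bumscore,
                       check.names = FALSE)
  utils::write.table(bumOut, file.path(outdir, "bumscore.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- coexpression ----------------------------------------------------
  targetId <- names(tss)[1L]
  tfIds <- intersect(bum$tf, rownames(expr))
  cors <- correlateTfTarget(expr, tfIds, targetId)
  utils::write.table(cors, file.path(outdir, "correlations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- prioritization --------------------------------------------------
  deStatus <- classifyDe(de, fdrMax = ana$fdrMax, fcMin = ana$fcMin)
  acc <- promoterAccessibility(bum, cres, corePromoter, dnase)
  records <- data.frame(tf = bum$tf, bumscore = bum$bumscore,
                        rTarget = cors$r[match(bum$tf, cors$tf)],
                        accessibility = acc,
                        deFlag = unname(deStatus[bum$tf] != "NDE"))
  records$rTarget[is.na(records$rTarget)] <- 0
  records$deFlag[is.na(records$deFlag)] <- FALSE
  records <- compositeScore(records)
  records <- selectCandidates(records, bumscoreStrict = ana$bumscoreStrict,
                              rMin = ana$rMin,
                              bumscoreRelaxed = ana$bumscoreRelaxed,
                              cap = ana$cap)
  records <- records[order(records$compositeRankScore, records$tf), ]
  utils::write.table(records, file.path(outdir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  recovery <- if (!is.null(trueTfId)) recoverPlanted(trueTfId, records)

  ## --- ChIP targets, crosstab, enrichment ------------------------------
  targets <- crosstab <- enrichment <- NULL
  if (!is.null(paths$chipTss) && !is.null(paths$chipPeaks)) {
    chipTss <- readTssTable(paths$chipTss)
    chipPeaks <- readBed(paths$chipPeaks)
    targets <- assignTargets(chipPeaks, chipTss,
                             windowBp = ana$targetWindowBp)
    utils::write.table(as.data.frame(targets[, setdiff(colnames(targets),
                                                       "peaks")]),
                       file.path(outdir, "targets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(targets) > 0L) {
      crosstab <- crosstabTargets(targets, deStatus)
      ctdf <- data.frame(class = names(crosstab$counts),
                         count = as.integer(crosstab$counts),
                         fraction = as.numeric(crosstab$fractions))
      utils::write.table(ctdf, file.path(outdir, "crosstab.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      universe <- names(chipTss)
      genesets <- if (!is.null(paths$genesets)) readGmt(paths$genesets)
      else list(DE_UP = names(deStatus)[deStatus == "UP"],
                EVERY_THIRD = universe[seq(1L, length(universe), 3L)])
      genesets <- genesets[lengths(lapply(genesets, intersect, universe)) > 0]
      if (length(genesets)) {
        enrichment <- fisherEnrichment(targets$gene, genesets, universe)
        utils::write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  ## --- manifest ---------------------------------------------------------
  cfgPath <- attr(cfg, "path")
  manifest <- list(
    package = "regprior",
    version = as.character(utils::packageVersion("regprior")),
    rversion = as.character(getRversion()),
    seed = seed,
    configHash = if (!is.null(cfgPath))
      unname(tools::md5sum(cfgPath)) else NA,
    analysis = ana,
    synthetic = synthetic,
    rows = list(cres = length(cres), tfs = nrow(bum),
                candidates = sum(records$selected),
                targets = if (is.null(targets)) 0L else nrow(targets)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cres = cres, corePromoter = corePromoter, bumscore = bum,
                 correlations = cors, candidates = records,
                 recovery = recovery, targets = targets, crosstab = crosstab,
                 enrichment = enrichment, manifest = manifest))
}

#' Convenience: simulate, analyse, and score planted recovery in memory
#'
#' Runs the synthetic pipeline without touching the filesystem - the
#' workhorse of the package's own benchmarks. Same stages and defaults as
#' \code{\link{runPipeline}} in synthetic mode.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param pvalue scan p-value cutoff (default 1e-4).
#' @param bumscoreStrict,rMin,bumscoreRelaxed,cap selection thresholds as
#'   in \code{\link{selectCandidates}}.
#' @return list with \code{cres}, \code{corePromoter}, \code{bumscore},
#'   \code{correlations}, \code{candidates}, \code{recovery},
#'   \code{groundTruth}.
#' @export
runSyntheticBenchmark <- function(config = simulationConfig(),
                                  pvalue = 1e-4, bumscoreStrict = 3,
                                  rMin = 0.3, bumscoreRelaxed = 2,
                                  cap = 96) {
  study <- simulateStudy(config)
  gt <- study$groundTruth
  cres <- callCres(study$tracks$peaks, tssSite(gt),
                   tracks = study$tracks$tracks)
  corePromoter <- selectCorePromoter(cres, study$tracks$tracks$DNase,
                                     tssSite(gt))
  bum <- computeBumscore(study$locus$pfms, cres, study$locus$seq, p = pvalue)
  cors <- correlateTfTarget(study$expression, bum$tf, targetGene(gt))
  deStatus <- classifyDe(study$de)
  acc <- promoterAccessibility(bum, cres, corePromoter,
                               study$tracks$tracks$DNase)
  records <- data.frame(tf = bum$tf, bumscore = bum$bumscore,
                        rTarget = cors$r[match(bum$tf, cors$tf)],
                        accessibility = acc,
                        deFlag = unname(deStatus[bum$tf] != "NDE"))
  records <- selectCandidates(compositeScore(records),
                              bumscoreStrict = bumscoreStrict, rMin = rMin,
                              bumscoreRelaxed = bumscoreRelaxed, cap = cap)
  list(cres = cres, corePromoter = corePromoter, bumscore = bum,
       correlations = cors, candidates = records,
       recovery = recoverPlanted(gt, records), groundTruth = gt)
}
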