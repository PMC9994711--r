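## Candidate prioritization: rank-product composite score over binding
## (Bumscore), coexpression with the target, and promoter accessibility,
## followed by the two-rule selection logic with its strict thresholds
## (Bumscore > 3 with r > 0.3; or differentially expressed with
## Bumscore > 2) and an optional cap on the selected set.

#' Rank-product composite score
#'
#' For each of the three criteria (\code{bumscore}, \code{rTarget},
#' \code{accessibility}) TFs are ranked in descending order (average
#' ranks on ties); the composite score is the geometric mean of the three
#' ranks. Lower is better; a TF ranked first on all three criteria scores
#' exactly 1.
#'
#' @param records data.frame with columns \code{tf}, \code{bumscore},
#'   \code{rTarget}, \code{accessibility}.
#' @return the input with a \code{compositeRankScore} column appended.
#' @examples
#' df <- data.frame(tf = c("a", "b"), bumscore = c(5, 1),
#'                  rTarget = c(0.8, 0.1), accessibility = c(2, 0))
#' compositeScore(df)
#' @export
compositeScore <- function(records) {
  if (nrow(records) == 0L) {
    records$compositeRankScore <- numeric(0)
    return(records)
  }
  for (col in c("bumscore", "rTarget", "accessibility"))
    if (!col %in% colnames(records))
      stop("records lack required column: ", col, call. = FALSE)
  rb <- rank(-records$bumscore, ties.method = "average")
  rr <- rank(-records$rTarget, ties.method = "average")
  ra <- rank(-records$accessibility, ties.method = "average")
  records$compositeRankScore <- (rb * rr * ra)^(1 / 3)
  records
}

#' Apply the candidate-selection rules
#'
#' Two routes into the candidate set, with strict inequalities:
#' \itemize{
#'   \item rule A (\code{corr_and_sites}): \code{bumscore > bumscoreStrict}
#'     AND \code{rTarget > rMin};
#'   \item rule B (\code{de_and_sites}): differentially expressed
#'     (\code{deFlag}) AND \code{bumscore > bumscoreRelaxed}.
#' }
#' Rule A takes precedence for labelling. The union is capped at
#' \code{cap} TFs by ascending composite rank score (ties broken by TF
#' id); use \code{cap = Inf} for the uncapped union.
#'
#' @param records data.frame with columns \code{tf}, \code{bumscore},
#'   \code{rTarget}, \code{deFlag} and (optionally)
#'   \code{compositeRankScore}, which is computed via
#'   \code{\link{compositeScore}} if absent.
#' @param bumscoreStrict strict binding-site threshold (default 3).
#' @param rMin coexpression threshold (default 0.3).
#' @param bumscoreRelaxed relaxed binding-site threshold (default 2).
#' @param cap maximum size of the selected set (default 96).
#' @return the input with \code{selected} (logical) and
#'   \code{selectionRule} (\code{corr_and_sites}, \code{de_and_sites} or
#'   \code{none}) columns.
#' @export
selectCandidates <- function(records, bumscoreStrict = 3, rMin = 0.3,
                             bumscoreRelaxed = 2, cap = 96) {
  if (!is.infinite(cap) && (cap < 1 || cap != round(cap)))
    stop("cap must be a positive integer (or Inf)", call. = FALSE)
  if (bumscoreStrict <= bumscoreRelaxed)
    stop("bumscoreStrict must exceed bumscoreRelaxed", call. = FALSE)
  if (!"compositeRankScore" %in% colnames(records))
    records <- compositeScore(records)
  ruleA <- records$bumscore > bumscoreStrict & records$rTarget > rMin
  ruleB <- records$deFlag & records$bumscore > bumscoreRelaxed
  selected <- ruleA | ruleB
  if (sum(selected) > cap) {
    idx <- which(selected)
    ord <- idx[order(records$compositeRankScore[idx], records$tf[idx])]
    drop <- ord[-seq_len(cap)]
    selected[drop] <- FALSE
    ruleA[drop] <- FALSE
    ruleB[drop] <- FALSE
  }
  records$selected <- selected
  records$selectionRule <- ifelse(ruleA, "corr_and_sites",
                                  ifelse(ruleB, "de_and_sites", "none"))
  records
}

#' Score recovery of the planted regulator
#'
#' Reports the composite rank of the true TF and whether it entered the
#' selected set - the end-to-end benchmark of the whole pipeline on
#' synthetic data.
#'
#' @param groundTruth a \linkS4class{GroundTruth} (or the true TF id as a
#'   string).
#' @param records output of \code{\link{selectCandidates}}.
#' @return list with \code{trueTfRank} (1 = best; ties take the smallest
#'   rank), \code{selected}, \code{nSelected}.
#' @export
recoverPlanted <- function(groundTruth, records) {
  tf <- if (methods::is(groundTruth, "GroundTruth")) trueTf(groundTruth)
        else groundTruth
  if (!tf %in% records$tf)
    stop("true TF '", tf, "' absent from the candidate records",
         call. = FALSE)
  if (!"compositeRankScore" %in% colnames(records))
    records <- compositeScore(records)
  i <- match(tf, records$tf)
  list(trueTfRank = as.integer(rank(records$compositeRankScore,
                                    ties.method = "min")[i]),
       selected = isTRUE(records$selected[i]),
       nSelected = sum(records$selected))
}
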