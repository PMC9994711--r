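## Coexpression machinery: Pearson correlation of TF expression with the
## target gene and with per-CRE H3K27ac enrichment across samples / cell
## types. Correlations are computed on log2(CPM + 1) by default, the
## scale on which the candidate filter (r > 0.3) is applied.

#' Pearson product-moment correlation with strict validation
#'
#' Unlike \code{stats::cor}, a constant vector raises an error rather than
#' silently returning NA: an undefined correlation must never be read as
#' "no correlation".
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Pearson r.
#' @examples
#' pearsonCor(1:5, 2 * (1:5) + 3)   # 1
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' \eqn{\tanh(\mathrm{atanh}(r) \pm z_{1-\alpha/2}/\sqrt{n-3})}.
#'
#' @param r observed correlation.
#' @param n sample size (> 3).
#' @param conf confidence level (default 0.95).
#' @return numeric length-2 vector (lower, upper).
#' @export
fisherZCi <- function(r, n, conf = 0.95) {
  if (n <= 3L) stop("Fisher z interval needs n > 3", call. = FALSE)
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

.logTransform <- function(m) log2(m + 1)

#' Correlate TF expression with the target gene
#'
#' One Pearson correlation per TF against the target, computed across the
#' samples both rows share (complete-case intersection; samples with a
#' non-finite value in either row are dropped).
#'
#' @param expr genes x samples expression matrix (CPM scale).
#' @param tfIds character vector of TF gene identifiers.
#' @param targetId target gene identifier.
#' @param logTransform correlate on log2(CPM + 1) (default TRUE).
#' @return data.frame with columns tf, partner, r, n, logScale.
#' @export
correlateTfTarget <- function(expr, tfIds, targetId, logTransform = TRUE) {
  if (!targetId %in% rownames(expr))
    stop("target gene '", targetId, "' absent from the expression matrix",
         call. = FALSE)
  missing <- setdiff(tfIds, rownames(expr))
  if (length(missing))
    stop("TF(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- if (logTransform) .logTransform(expr) else expr
  y <- m[targetId, ]
  res <- lapply(tfIds, function(tf) {
    x <- m[tf, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L)
      stop("fewer than 3 shared samples for TF ", tf, call. = FALSE)
    data.frame(tf = tf, partner = targetId,
               r = pearsonCor(x[ok], y[ok]), n = sum(ok),
               logScale = logTransform)
  })
  do.call(rbind, res)
}

#' Correlate TF expression with per-CRE H3K27ac enrichment
#'
#' Pearson r for every (TF, CRE) pair across the cell types shared by the
#' two inputs, on log2(CPM + 1) expression versus raw enrichment.
#'
#' @param tfExpr TFs x cell-types expression matrix (CPM scale).
#' @param creEnrichment CREs x cell-types H3K27ac enrichment matrix.
#' @param logTransform log-transform the expression side (default TRUE).
#' @return data.frame with columns tf, cre, r, n.
#' @export
correlateTfH3k27ac <- function(tfExpr, creEnrichment, logTransform = TRUE) {
  shared <- intersect(colnames(tfExpr), colnames(creEnrichment))
  if (length(shared) < 3L)
    stop("fewer than 3 shared cell types between expression and enrichment",
         call. = FALSE)
  e <- if (logTransform) .logTransform(tfExpr[, shared, drop = FALSE])
       else tfExpr[, shared, drop = FALSE]
  a <- creEnrichment[, shared, drop = FALSE]
  grid <- expand.grid(tf = rownames(e), cre = rownames(a),
                      stringsAsFactors = FALSE)
  grid$r <- mapply(function(tf, cre) pearsonCor(e[tf, ], a[cre, ]),
                   grid$tf, grid$cre)
  grid$n <- length(shared)
  grid
}
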