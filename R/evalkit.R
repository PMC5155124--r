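# Evaluation of gene priority lists against labelled disease gene sets.

.asLabeledSets <- function(labels, universe) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("gene", "label") %in% names(labels)))
    labels <- list(disease = labels$gene[labels$label == 1],
                   nondisease = labels$gene[labels$label == 0])
  }
  stopifnot(is.list(labels), all(c("disease", "nondisease") %in% names(labels)))
  if (length(intersect(labels$disease, labels$nondisease)))
    stop("disease and nondisease gene sets must be disjoint")
  drop <- setdiff(c(labels$disease, labels$nondisease), universe)
  if (length(drop))
    warning(length(drop), " labelled gene(s) absent from the ranking dropped")
  list(disease = intersect(labels$disease, universe),
       nondisease = intersect(labels$nondisease, universe))
}

#' ROC curve and AUC of a gene priority list
#'
#' Sweeps a cutoff down the priority list; at each cutoff the true positive
#' rate is the fraction of disease genes ranked above it and the false
#' positive rate the fraction of nondisease genes ranked above it. The ROC
#' curve plots TPR against FPR and the AUC is its trapezoidal area. Genes
#' tied on the aggregated rank product are processed as one block (a single
#' ROC vertex, i.e. a diagonal segment), so ties cannot be split
#' arbitrarily. Unlabelled genes are ignored.
#'
#' @param ranking a rank table from [rankProduct()] (columns `gene`,
#'   `rankProduct`), or a character vector of gene IDs in priority order
#'   (treated as tie-free).
#' @param labels a list with elements `disease` and `nondisease` (gene ID
#'   vectors), or a `data.frame` with columns `gene` and `label` (1/0).
#' @return list of class `dcgnEval` with `rocPoints` (`data.frame` of
#'   `fpr`, `tpr`, starting at (0,0) and ending at (1,1)), `auc`, `nPos`,
#'   `nNeg`.
#' @examples
#' rocAuc(c("d1", "d2", "n1", "n2"),
#'        list(disease = c("d1", "d2"), nondisease = c("n1", "n2")))$auc  # 1
#' @export
rocAuc <- function(ranking, labels) {
  if (is.character(ranking)) {
    genes <- ranking
    key <- seq_along(genes)            # tie-free
  } else {
    stopifnot(is.data.frame(ranking), all(c("gene", "rankProduct") %in% names(ranking)))
    ord <- order(ranking$rankProduct, ranking$gene)
    genes <- ranking$gene[ord]
    key <- ranking$rankProduct[ord]
  }
  lab <- .asLabeledSets(labels, genes)
  nPos <- length(lab$disease); nNeg <- length(lab$nondisease)
  if (nPos == 0) stop("no disease genes present in the ranking")
  if (nNeg == 0) stop("no nondisease genes present in the ranking")

  isPos <- genes %in% lab$disease
  isNeg <- genes %in% lab$nondisease
  block <- cumsum(!duplicated(key))    # tie blocks share a vertex
  tpBlock <- tapply(isPos, block, sum)
  fpBlock <- tapply(isNeg, block, sum)
  keep <- tpBlock > 0 | fpBlock > 0
  tpr <- c(0, cumsum(tpBlock[keep]) / nPos)
  fpr <- c(0, cumsum(fpBlock[keep]) / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(rocPoints = data.frame(fpr = unname(fpr), tpr = unname(tpr)),
                 auc = auc, nPos = nPos, nNeg = nNeg),
            class = "dcgnEval")
}

#' @export
print.dcgnEval <- function(x, ...) {
  cat("ROC evaluation: AUC =", signif(x$auc, 4),
      sprintf("(%d disease / %d nondisease genes)\n", x$nPos, x$nNeg))
  invisible(x)
}

#' Overlap of two gene priority lists by ranking range
#'
#' For each half-open ranking range `[a, b)` (0-based, so `[0, 1000)` means
#' the top 1000 genes), counts the genes that both lists place inside the
#' range and reports the count and its fraction of the range length.
#'
#' @param listA,listB character vectors of gene IDs in priority order over
#'   the same gene universe.
#' @param ranges list of two-element integer vectors `c(a, b)`; defaults to
#'   consecutive blocks of 1000.
#' @return `data.frame` with columns `start`, `end`, `overlap`, `fraction`.
#' @export
overlapTable <- function(listA, listB, ranges = NULL) {
  if (!setequal(listA, listB))
    stop("both lists must cover the same gene universe")
  n <- length(listA)
  if (is.null(ranges)) {
    breaks <- seq(0, n, by = 1000)
    if (utils::tail(breaks, 1) < n) breaks <- c(breaks, n)
    ranges <- Map(c, utils::head(breaks, -1), utils::tail(breaks, -1))
  }
  rows <- lapply(ranges, function(r) {
    a <- r[1]; b <- r[2]
    stopifnot(a >= 0, b > a)
    if (b > n) {
      warning("range [", a, ",", b, ") exceeds list length ", n, "; truncated")
      b <- n
    }
    ga <- listA[(a + 1):b]; gb <- listB[(a + 1):b]
    ov <- length(intersect(ga, gb))
    data.frame(start = a, end = b, overlap = ov, fraction = ov / (b - a))
  })
  do.call(rbind, rows)
}

#' Rank-product baselines on differential expression
#'
#' Comparison baselines that aggregate per-phase-pair differential
#' \emph{expression} (not coexpression) with the same rank product as the
#' main method: mode `"FC"` scores each gene by the absolute difference of
#' its mean (log-scale) expression between the two phases; mode `"t"` by
#' the absolute Welch two-sample t statistic. Genes with zero within-phase
#' variance in mode `"t"` get an infinite statistic (top rank) with a
#' warning. Provided only as comparison conveniences.
#'
#' @param exprs list of >= 2 expression matrices (genes x samples, same
#'   rownames in the same order; values assumed on a log-like scale).
#' @param mode `"FC"` or `"t"`.
#' @return a rank table as returned by [rankProduct()].
#' @export
rpBaselines <- function(exprs, mode = c("FC", "t")) {
  mode <- match.arg(mode)
  stopifnot(length(exprs) >= 2)
  ids <- rownames(exprs[[1]])
  for (e in exprs[-1]) stopifnot(identical(rownames(e), ids))
  if (mode == "t")
    for (e in exprs) stopifnot(ncol(e) >= 2)

  pairs <- utils::combn(length(exprs), 2, simplify = FALSE)
  ranks <- lapply(pairs, function(pr) {
    A <- exprs[[pr[1]]]; B <- exprs[[pr[2]]]
    if (mode == "FC") {
      s <- abs(rowMeans(A) - rowMeans(B))
    } else {
      vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
      se <- sqrt(vA / ncol(A) + vB / ncol(B))
      if (any(se == 0))
        warning(sum(se == 0), " gene(s) with zero within-phase variance; ",
                "t statistic set to +Inf")
      s <- ifelse(se == 0 & abs(rowMeans(A) - rowMeans(B)) == 0, 0,
                  abs(rowMeans(A) - rowMeans(B)) / se)  # 0/0 -> null gene
    }
    rankScores(stats::setNames(s, ids))
  })
  names(ranks) <- vapply(pairs, function(pr) paste(pr, collapse = "|"), character(1))
  rankProduct(ranks)
}
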