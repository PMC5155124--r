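# Rank-product aggregation of per-pair differential-coexpression scores.

#' Rank genes within one score table
#'
#' Genes are ranked in descending score order: rank 1 is the largest
#' differential-coexpression value. Tied scores receive the average of the
#' ranks they span, the standard rank-product convention (keeps rank sums
#' invariant).
#'
#' @param table a score table from [scoreAll()] (`data.frame` with columns
#'   `gene`, `value`), or a named numeric vector of scores.
#' @return named numeric vector of ranks (a tie-averaged permutation of
#'   `1..n`).
#' @examples
#' rankScores(c(A = 5, B = 5, C = 1))  # 1.5, 1.5, 3
#' @export
rankScores <- function(table) {
  if (is.data.frame(table)) {
    scores <- stats::setNames(table$value, table$gene)
  } else {
    scores <- table
  }
  if (is.null(names(scores))) stop("scores must be named by gene")
  if (any(!is.finite(scores) & !is.infinite(scores)))
    stop("scores contain NaN/NA values")
  rank(-scores, ties.method = "average")
}

#' Aggregate per-pair ranks by rank product
#'
#' The comprehensive rank of gene \eqn{i} over \eqn{C} network pairs is the
#' geometric mean of its per-pair ranks,
#' \deqn{R_i = \Big(\prod_{(t_1,t_2)} r_i^{t_1,t_2}\Big)^{1/C},}
#' computed in log space to avoid overflow. The final priority list sorts
#' genes by ascending \eqn{R_i} (smaller = stronger differential
#' coexpression candidate); ties are broken lexicographically by gene ID
#' for determinism.
#'
#' @param perPairRanks a list of equally named rank vectors (one per phase
#'   pair, e.g. from [rankScores()]) or a genes-by-pairs numeric matrix of
#'   ranks with rownames.
#' @return `data.frame` in final priority order with the per-pair rank
#'   columns, `rankProduct`, and `finalRank` (`1..n`).
#' @examples
#' rankProduct(list(p1 = c(a = 2, b = 1), p2 = c(a = 8, b = 1),
#'                  p3 = c(a = 4, b = 1)))  # R_a = 4, R_b = 1
#' @export
rankProduct <- function(perPairRanks) {
  if (is.list(perPairRanks)) {
    genes <- names(perPairRanks[[1]])
    if (is.null(genes)) stop("rank vectors must be named by gene")
    mat <- vapply(perPairRanks, function(r) {
      if (!setequal(names(r), genes))
        stop("every pair must contribute a rank for every gene")
      r[genes]
    }, numeric(length(genes)))
    mat <- matrix(mat, nrow = length(genes),
                  dimnames = list(genes, names(perPairRanks)))
  } else {
    mat <- as.matrix(perPairRanks)
    if (is.null(rownames(mat))) stop("rank matrix must have gene rownames")
  }
  if (anyNA(mat) || any(mat <= 0)) stop("ranks must be positive and complete")
  R <- exp(rowMeans(log(mat)))
  ord <- order(R, rownames(mat))
  out <- data.frame(gene = rownames(mat)[ord], mat[ord, , drop = FALSE],
                    rankProduct = unname(R[ord]),
                    finalRank = seq_along(R),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
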