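# Construction of phase-specific weighted coexpression networks.

.EPS_OPEN <- 1e-12   # w_ij lives in the open interval [0, 1): clamp below 1
.DEFAULT_BETA <- 6L  # fallback soft power when scale-free fitting is degenerate

#' Network construction parameters
#'
#' Bundles the knobs of soft-threshold network construction: the candidate
#' soft powers, the scale-free fit target used to pick among them, and the
#' hard cutoff that sparsifies the weight matrix. With few samples per
#' phase, spurious correlations are common and a stricter `tau` (or a fixed
#' higher `beta`) filters out false-positive connections.
#'
#' @param powerGrid candidate soft-threshold exponents (all >= 1).
#' @param r2Target scale-free model fit (R squared) considered acceptable.
#' @param tau hard weight cutoff in `[0, 1)`: weights below `tau` are set
#'   to zero after soft-thresholding.
#' @param beta optional fixed exponent; when non-`NULL`, power selection is
#'   skipped and this exponent is used as-is.
#' @return a list of class `NetworkBuildConfig`.
#' @examples
#' networkBuildConfig(tau = 0.2)
#' @export
networkBuildConfig <- function(powerGrid = 1:10, r2Target = 0.8, tau = 0.1,
                               beta = NULL) {
  stopifnot(length(powerGrid) >= 1, all(powerGrid >= 1),
            length(r2Target) == 1, r2Target > 0, r2Target <= 1,
            length(tau) == 1, tau >= 0, tau < 1)
  if (!is.null(beta)) stopifnot(length(beta) == 1, beta >= 1)
  structure(list(powerGrid = as.numeric(powerGrid),
                 r2Target = as.numeric(r2Target),
                 tau = as.numeric(tau),
                 beta = if (is.null(beta)) NULL else as.numeric(beta)),
            class = "NetworkBuildConfig")
}

#' Create a coexpression network from a weight matrix
#'
#' Low-level constructor: validates the weight matrix, derives the
#' transition matrix, and wraps both in a [CoexNetwork-class]. Use
#' [buildCoexNetwork()] to construct a network from expression data.
#'
#' @param W symmetric numeric matrix with zero diagonal and entries in
#'   `[0, 1)`; dimnames (if present) supply the gene IDs.
#' @param geneIDs gene identifiers; defaults to `rownames(W)`.
#' @param phaseLabel phase/time-point tag.
#' @return a [CoexNetwork-class] object.
#' @export
CoexNetwork <- function(W, geneIDs = rownames(W), phaseLabel = "phase") {
  if (is.null(geneIDs)) stop("geneIDs are required (or set rownames on W)")
  geneIDs <- as.character(geneIDs)
  dimnames(W) <- list(geneIDs, geneIDs)
  new("CoexNetwork", geneIDs = geneIDs, W = W,
      M = transitionMatrix(W), phaseLabel = as.character(phaseLabel))
}

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "matrix", function(object) {
  if (any(object < 0)) stop("weight matrix must be non-negative")
  rs <- rowSums(object)
  M <- object / ifelse(rs > 0, rs, 1)  # isolated rows stay all-zero
  dimnames(M) <- dimnames(object)
  M
})

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "CoexNetwork", function(object) object@M)

#' @rdname dcgn-accessors
#' @export
setMethod("geneIDs", "CoexNetwork", function(object) object@geneIDs)

#' @rdname dcgn-accessors
#' @export
setMethod("weightMatrix", "CoexNetwork", function(object) object@W)

#' @rdname dcgn-accessors
#' @export
setMethod("adjacencyMatrix", "CoexNetwork", function(object) {
  A <- (object@W != 0) * 1L
  dimnames(A) <- list(object@geneIDs, object@geneIDs)
  A
})

#' @rdname dcgn-accessors
#' @export
setMethod("phaseLabel", "CoexNetwork", function(object) object@phaseLabel)

#' @rdname dcgn-accessors
#' @export
setMethod("edgeSet", "CoexNetwork", function(object) .edgeKeys(object@W))

setMethod("show", "CoexNetwork", function(object) {
  n <- length(object@geneIDs)
  ne <- sum(object@W[upper.tri(object@W)] > 0)
  iso <- sum(rowSums(object@W) == 0)
  cat("CoexNetwork '", object@phaseLabel, "': ", n, " genes, ", ne,
      " edges, ", iso, " isolated\n", sep = "")
  if (ne > 0)
    cat("  mean edge weight: ",
        signif(mean(object@W[upper.tri(object@W) & object@W > 0]), 4), "\n",
        sep = "")
})

# Canonical "a|b" edge keys (upper triangle, row index < col index) of the
# nonzero entries of a symmetric matrix. All edge-set arithmetic in the
# package runs on these keys; same gene order is enforced across phases.
.edgeKeys <- function(W, ids = rownames(W)) {
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(character(0))
  paste(ids[idx[, 1]], ids[idx[, 2]], sep = "|")
}

#' Build a phase-specific coexpression network from expression data
#'
#' Computes the unsigned weighted network \eqn{w_{ij} = |cor(x_i, x_j)|^\beta}
#' from the Pearson correlation of gene expression profiles, choosing the
#' soft power \eqn{\beta} by the scale-free criterion (see
#' [selectSoftPower()]) unless the config fixes it, then zeroes all weights
#' below the hard cutoff `tau`. Perfect correlations are clamped just below
#' 1 so that weights stay in `[0, 1)`. Genes with zero expression variance
#' have undefined correlations; they are kept (so gene indices stay aligned
#' across phases) but isolated, with a warning.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns; at least 3 genes and 3 samples.
#' @param config a [networkBuildConfig()] list.
#' @param phaseLabel phase tag stored in the result.
#' @return a [CoexNetwork-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("g", 1:5), NULL))
#' net <- buildCoexNetwork(x, networkBuildConfig(beta = 6), "t1")
#' @export
buildCoexNetwork <- function(expr, config = networkBuildConfig(),
                             phaseLabel = "phase") {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (nrow(expr) < 3) stop("need at least 3 genes")
  if (ncol(expr) < 3) stop("need at least 3 samples (correlation degenerate)")
  ids <- rownames(expr)
  if (is.null(ids)) stop("expression matrix must have gene IDs as rownames")
  if (anyDuplicated(ids)) stop("gene IDs must be unique")

  constant <- apply(expr, 1, stats::sd) == 0
  if (any(constant))
    warning(sum(constant), " zero-variance gene(s) isolated: ",
            paste(utils::head(ids[constant], 5), collapse = ", "),
            if (sum(constant) > 5) ", ..." else "")

  R <- suppressWarnings(stats::cor(t(expr)))
  R[is.na(R)] <- 0            # zero-variance genes: no coexpression evidence
  beta <- if (!is.null(config$beta)) config$beta
          else selectSoftPower(expr, config)
  W <- abs(R)^beta
  W <- pmin(W, 1 - .EPS_OPEN)  # keep the open interval [0, 1)
  W[W < config$tau] <- 0
  diag(W) <- 0
  W[constant, ] <- 0
  W[, constant] <- 0
  W <- (W + t(W)) / 2          # symmetrise away float asymmetry
  CoexNetwork(W, ids, phaseLabel)
}

#' Choose a soft-threshold power by the scale-free criterion
#'
#' For each candidate exponent the thresholded network is built and the fit
#' of its degree distribution to a power law is scored: degrees are binned
#' into 10 bins, and R squared of the linear regression of
#' `log10(frequency)` on `log10(mean degree)` is the fit statistic. The
#' smallest candidate whose fit reaches `r2Target` is returned; if none
#' does, the candidate with the best fit is returned with a warning. When
#' every candidate yields fewer than 3 distinct degree values the fit is
#' undefined and a documented default power (6) is returned with a warning.
#'
#' @inheritParams buildCoexNetwork
#' @return the selected exponent (single numeric).
#' @export
selectSoftPower <- function(expr, config = networkBuildConfig()) {
  R <- suppressWarnings(stats::cor(t(expr)))
  R[is.na(R)] <- 0
  grid <- sort(config$powerGrid)
  r2 <- vapply(grid, function(beta) {
    W <- abs(R)^beta
    W[W < config$tau] <- 0
    diag(W) <- 0
    .scaleFreeR2(rowSums(W > 0))
  }, numeric(1))
  if (all(is.na(r2))) {
    warning("degree distribution degenerate at every candidate power; ",
            "falling back to beta = ", .DEFAULT_BETA)
    return(as.numeric(.DEFAULT_BETA))
  }
  pass <- which(!is.na(r2) & r2 >= config$r2Target)
  if (length(pass)) return(grid[pass[1]])
  warning("no candidate power reaches R^2 target ", config$r2Target,
          "; using best-fit beta = ", grid[which.max(r2)])
  grid[which.max(r2)]
}

# R^2 of log10(freq) ~ log10(degree) over a 10-bin degree histogram.
# NA when fewer than 3 distinct positive degrees (fit undefined).
.scaleFreeR2 <- function(deg, nBins = 10) {
  deg <- deg[deg > 0]
  if (length(unique(deg)) < 3) return(NA_real_)
  bins <- cut(deg, breaks = nBins)
  freq <- tapply(deg, bins, length)
  mid <- tapply(deg, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mid[keep]))
  summary(fit)$r.squared
}

#' Global similarity of two coexpression networks
#'
#' Jaccard index of the two global edge sets,
#' \eqn{|E_A \cap E_B| / |E_A \cup E_B|}: 1 for identical edge sets, 0 for
#' disjoint ones. Two edgeless networks are deemed identical (similarity 1,
#' with a warning).
#'
#' @param netA,netB [CoexNetwork-class] objects over the same gene IDs.
#' @return similarity in `[0, 1]`.
#' @export
networkSimilarity <- function(netA, netB) {
  if (!identical(geneIDs(netA), geneIDs(netB)))
    stop("networks must share the same gene IDs in the same order")
  ea <- edgeSet(netA); eb <- edgeSet(netB)
  if (length(ea) == 0 && length(eb) == 0) {
    warning("both networks are edgeless; similarity 1 by convention")
    return(1)
  }
  length(intersect(ea, eb)) / length(union(ea, eb))
}
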