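#' @import methods
NULL

#' Phase-specific weighted gene coexpression network
#'
#' Container for one phase-specific coexpression network: the symmetric
#' weight matrix \eqn{W} (entries \eqn{w_{ij} \in [0,1)}, zero diagonal),
#' and the random-walk transition matrix \eqn{M} whose entry \eqn{m_{ij}}
#' is the probability of stepping from gene \eqn{i} to gene \eqn{j},
#' \eqn{m_{ij} = w_{ij} / \sum_{j' \in N_i} w_{ij'}} for nodes with at least
#' one neighbour and an all-zero row for isolated nodes. The 0/1 adjacency
#' matrix \eqn{A} (\eqn{a_{ij} = 1} iff \eqn{w_{ij} \neq 0}) is derived on
#' demand via [adjacencyMatrix()].
#'
#' @slot geneIDs character vector of unique gene identifiers; row/column
#'   order of all matrices.
#' @slot W numeric matrix, symmetric, zero diagonal, entries in `[0, 1)`.
#' @slot M numeric matrix, row-stochastic on non-isolated rows, zero rows
#'   for isolated genes.
#' @slot phaseLabel single character tag for the phase/time point.
#'
#' @seealso [CoexNetwork()], [buildCoexNetwork()], [transitionMatrix()]
#' @exportClass CoexNetwork
setClass("CoexNetwork",
  representation(
    geneIDs    = "character",
    W          = "matrix",
    M          = "matrix",
    phaseLabel = "character"
  )
)

setValidity("CoexNetwork", function(object) {
  msgs <- character()
  n <- length(object@geneIDs)
  if (anyDuplicated(object@geneIDs)) msgs <- c(msgs, "gene IDs must be unique")
  if (!is.numeric(object@W) || !identical(dim(object@W), c(n, n)))
    msgs <- c(msgs, "W must be a numeric n x n matrix matching geneIDs")
  else {
    if (any(abs(object@W - t(object@W)) > 1e-8)) msgs <- c(msgs, "W must be symmetric")
    if (any(diag(object@W) != 0)) msgs <- c(msgs, "W must have a zero diagonal")
    if (any(object@W < 0) || any(object@W >= 1)) msgs <- c(msgs, "W entries must lie in [0, 1)")
  }
  if (!identical(dim(object@M), c(n, n)))
    msgs <- c(msgs, "M must be a numeric n x n matrix matching geneIDs")
  else {
    rs <- rowSums(object@M)
    if (any(abs(rs[rs > 0] - 1) > 1e-9))
      msgs <- c(msgs, "non-isolated rows of M must sum to 1")
    if (is.numeric(object@W) && identical(dim(object@W), c(n, n)) &&
        !identical(object@M > 0, object@W > 0))
      msgs <- c(msgs, "M must be positive exactly where W is positive")
  }
  if (length(object@phaseLabel) != 1L)
    msgs <- c(msgs, "phaseLabel must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Gene-centric k-level subnetwork
#'
#' The \eqn{i}-centric subnetwork \eqn{SW_i^{t,k}}: the centre gene together
#' with all genes reachable within `k` steps in the phase-`t` network, the
#' induced edge set among those genes, and the restriction of the weight
#' matrix to them. BFS hop distances from the centre are cached because the
#' information-based score needs them for its layered maximum-probability
#' recursion.
#'
#' @slot center gene ID at the centre.
#' @slot k neighbourhood level (integer >= 1).
#' @slot nodeSet gene IDs reachable within `k` steps, centre included,
#'   in parent-network order.
#' @slot edgeKeys canonical `"a|b"` keys (parent order, first index smaller)
#'   of the induced edges.
#' @slot W weight submatrix restricted to `nodeSet`.
#' @slot dist named integer vector of BFS hop distances from the centre.
#' @slot phaseLabel phase tag inherited from the parent network.
#'
#' @seealso [extractSubnetwork()]
#' @exportClass Subnetwork
setClass("Subnetwork",
  representation(
    center     = "character",
    k          = "integer",
    nodeSet    = "character",
    edgeKeys   = "character",
    W          = "matrix",
    dist       = "integer",
    phaseLabel = "character"
  )
)

setValidity("Subnetwork", function(object) {
  msgs <- character()
  if (!(object@center %in% object@nodeSet))
    msgs <- c(msgs, "center must belong to nodeSet")
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  if (length(object@dist) != length(object@nodeSet) ||
      !all(names(object@dist) == object@nodeSet))
    msgs <- c(msgs, "dist must be named by nodeSet")
  else if (any(object@dist > object@k))
    msgs <- c(msgs, "all nodes must be within k steps of the center")
  if (length(msgs)) msgs else TRUE
})

#' Star-shaped information network around a centre gene
#'
#' Result of collapsing a gene-centric subnetwork onto a star in which the
#' centre connects directly to every other member. For each partner \eqn{j}:
#' `pMax` is the maximum probability of reaching \eqn{j} from the centre in
#' the least number of steps, `pNorm` its normalisation over partners,
#' `pTrans` the inverse-probability renormalisation that makes strong
#' (short, heavy) connections carry more information, and `info` the edge
#' information \eqn{I_{ij} = -\ln(p) \, p} evaluated at `pTrans`.
#'
#' @slot center centre gene ID.
#' @slot pMax named numeric, maximum least-step transition probabilities.
#' @slot pNorm named numeric, `pMax` normalised to sum 1.
#' @slot pTrans named numeric, inverse-normalised probabilities (sum 1).
#' @slot info named numeric, per-partner edge information (all >= 0).
#'
#' @seealso [starTransform()], [dcgnI()]
#' @exportClass StarInfoNetwork
setClass("StarInfoNetwork",
  representation(
    center = "character",
    pMax   = "numeric",
    pNorm  = "numeric",
    pTrans = "numeric",
    info   = "numeric"
  )
)

setValidity("StarInfoNetwork", function(object) {
  msgs <- character()
  np <- length(object@pMax)
  if (length(object@pNorm) != np || length(object@pTrans) != np ||
      length(object@info) != np)
    msgs <- c(msgs, "pMax, pNorm, pTrans and info must have equal length")
  if (np > 0) {
    if (abs(sum(object@pNorm) - 1) > 1e-9) msgs <- c(msgs, "pNorm must sum to 1")
    if (abs(sum(object@pTrans) - 1) > 1e-9) msgs <- c(msgs, "pTrans must sum to 1")
    if (any(object@info < 0)) msgs <- c(msgs, "edge information must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})
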