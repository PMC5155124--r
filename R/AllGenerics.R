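#' @name dcgn-accessors
#' @title Accessors for dcgn S4 objects
#'
#' @description Getters for the slots of [CoexNetwork-class],
#' [Subnetwork-class] and [StarInfoNetwork-class] objects.
#'
#' @param object a dcgn S4 object.
#' @return The corresponding slot value: gene IDs (character), the weight /
#'   adjacency / transition matrix (numeric matrix), the phase tag, node or
#'   edge sets, or named per-partner numeric vectors for star networks.
NULL

#' @rdname dcgn-accessors
#' @export
setGeneric("geneIDs", function(object) standardGeneric("geneIDs"))

#' @rdname dcgn-accessors
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))

#' @rdname dcgn-accessors
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))

#' @rdname dcgn-accessors
#' @export
setGeneric("phaseLabel", function(object) standardGeneric("phaseLabel"))

#' @rdname dcgn-accessors
#' @export
setGeneric("nodeSet", function(object) standardGeneric("nodeSet"))

#' @rdname dcgn-accessors
#' @export
setGeneric("edgeSet", function(object) standardGeneric("edgeSet"))

#' @rdname dcgn-accessors
#' @export
setGeneric("subnetCenter", function(object) standardGeneric("subnetCenter"))

#' @rdname dcgn-accessors
#' @export
setGeneric("partnerProbs", function(object) standardGeneric("partnerProbs"))

#' @rdname dcgn-accessors
#' @export
setGeneric("partnerInfo", function(object) standardGeneric("partnerInfo"))

#' Random-walk transition matrix of a weighted network
#'
#' For a symmetric non-negative weight matrix \eqn{W} with zero diagonal,
#' the transition probability from node \eqn{i} to node \eqn{j} is
#' \deqn{m_{ij} = w_{ij} / \sum_{j' \in N_i} w_{ij'}}
#' where \eqn{N_i} is the neighbour set of \eqn{i}; rows of isolated nodes
#' (empty \eqn{N_i}) are all zero. Applied to a [CoexNetwork-class] it
#' returns the stored transition matrix.
#'
#' @param object a numeric weight matrix or a [CoexNetwork-class].
#' @return numeric matrix `M`; every non-isolated row sums to 1, isolated
#'   rows are all zeros. `M` is generally asymmetric even for symmetric `W`.
#' @examples
#' W <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
#' W["a", "b"] <- W["b", "a"] <- 0.2
#' W["a", "c"] <- W["c", "a"] <- 0.3
#' transitionMatrix(W)["a", ]  # 0, 0.4, 0.6
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))
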