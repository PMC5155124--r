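# Per-gene differential coexpression between two phase-specific networks.
#
# Two scores are implemented. DCGN-S is one minus the Jaccard index of the
# edge sets of the gene's k-level neighbourhood subgraphs in the two phases.
# DCGN-I collapses each neighbourhood onto a star of least-step maximum
# transition probabilities, converts them to per-edge information values,
# and sums the information carried by neighbourhood members exclusive to one
# of the two phases.

# BFS ball of radius k around `center` over the nonzero pattern of W.
# Returns nodes in parent order together with hop distances.
.bfsBall <- function(W, center, k) {
  ids <- rownames(W)
  n <- nrow(W)
  ci <- match(center, ids)
  dist <- rep(NA_integer_, n)
  dist[ci] <- 0L
  frontier <- ci
  for (step in seq_len(k)) {
    if (!length(frontier)) break
    reach <- which(rowSums(W[, frontier, drop = FALSE] != 0) > 0)
    newly <- reach[is.na(dist[reach])]
    dist[newly] <- step
    frontier <- newly
  }
  keep <- which(!is.na(dist))
  list(idx = keep, dist = stats::setNames(dist[keep], ids[keep]))
}

#' Extract a gene-centric k-level subnetwork
#'
#' Builds \eqn{SW_i^{t,k}}: the set of genes reachable from the centre gene
#' within `k` steps (BFS over the network's adjacency pattern), together
#' with the induced edges among them and the restriction of the weight
#' matrix. An isolated centre yields a single-node subnetwork with an empty
#' edge set.
#'
#' @param net a [CoexNetwork-class].
#' @param center gene ID of the centre.
#' @param k neighbourhood level, integer >= 1.
#' @return a [Subnetwork-class].
#' @examples
#' W <- matrix(0, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2))
#' W["A", "B"] <- W["B", "A"] <- 0.5
#' W["B", "C"] <- W["C", "B"] <- 0.5
#' W["C", "D"] <- W["D", "C"] <- 0.5
#' nodeSet(extractSubnetwork(CoexNetwork(W), "A", 2))  # A, B, C
#' @export
extractSubnetwork <- function(net, center, k = 1L) {
  stopifnot(is(net, "CoexNetwork"), k >= 1)
  if (!center %in% net@geneIDs) stop("gene '", center, "' not in network")
  ball <- .bfsBall(net@W, center, as.integer(k))
  Wsub <- net@W[ball$idx, ball$idx, drop = FALSE]
  new("Subnetwork",
      center = center, k = as.integer(k),
      nodeSet = net@geneIDs[ball$idx],
      edgeKeys = .edgeKeys(Wsub),
      W = Wsub, dist = ball$dist,
      phaseLabel = net@phaseLabel)
}

#' @rdname dcgn-accessors
#' @export
setMethod("nodeSet", "Subnetwork", function(object) object@nodeSet)

#' @rdname dcgn-accessors
#' @export
setMethod("edgeSet", "Subnetwork", function(object) object@edgeKeys)

#' @rdname dcgn-accessors
#' @export
setMethod("subnetCenter", "Subnetwork", function(object) object@center)

#' @rdname dcgn-accessors
#' @export
setMethod("weightMatrix", "Subnetwork", function(object) object@W)

#' @rdname dcgn-accessors
#' @export
setMethod("phaseLabel", "Subnetwork", function(object) object@phaseLabel)

setMethod("show", "Subnetwork", function(object) {
  cat("Subnetwork around '", object@center, "' (k = ", object@k, ", phase '",
      object@phaseLabel, "'): ", length(object@nodeSet), " nodes, ",
      length(object@edgeKeys), " edges\n", sep = "")
})

# Maximum least-step transition probabilities from the centre to every other
# subnetwork member, via a layered max-product dynamic program: walks are
# restricted to minimal hop count, so each BFS layer only receives from the
# previous one and cycles cannot occur.
.maxStepProbs <- function(sub, M) {
  partners <- setdiff(sub@nodeSet, sub@center)
  if (!length(partners)) return(stats::setNames(numeric(0), character(0)))
  nodes <- sub@nodeSet
  d <- sub@dist
  Msub <- M[nodes, nodes, drop = FALSE]
  Asub <- sub@W != 0
  best <- stats::setNames(rep(0, length(nodes)), nodes)
  best[sub@center] <- 1
  for (layer in seq_len(max(d))) {
    cur <- nodes[d == layer]
    prev <- nodes[d == layer - 1L]
    for (j in cur) {
      from <- prev[Asub[prev, j]]
      best[j] <- max(best[from] * Msub[from, j])
    }
  }
  best[partners]
}

#' Maximum transition probability along least-step walks
#'
#' Within a gene-centric subnetwork, the maximum over all walks of minimal
#' hop length from the centre to `target` of the product of one-step
#' transition probabilities along the walk. Transition probabilities come
#' from the parent network's transition matrix restricted to the
#' subnetwork's nodes (not renormalised), so rows may sum to less than 1
#' inside the subnetwork.
#'
#' @param sub a [Subnetwork-class].
#' @param M the transition matrix of the parent network.
#' @param target gene ID in the subnetwork, different from the centre.
#' @return a single probability, strictly positive.
#' @export
maxLeastStepProb <- function(sub, M, target) {
  stopifnot(is(sub, "Subnetwork"))
  if (!target %in% sub@nodeSet || target == sub@center)
    stop("target must be a subnetwork member other than the center")
  p <- .maxStepProbs(sub, M)[[target]]
  stopifnot(p > 0)  # reachable by construction of the node set
  p
}

#' Collapse a subnetwork onto its star-shaped information network
#'
#' Transforms the centre's k-level subnetwork into a star in which the
#' centre connects directly to every other member, in four stages: (a) the
#' maximum least-step transition probability to each partner
#' ([maxLeastStepProb()]); (b) normalisation over partners to probabilities
#' summing to 1; (c) inverse renormalisation
#' \eqn{p'_j = (1/p_j) / \sum_{j'} (1/p_{j'})}, so that strongly coexpressed
#' (short, heavy) connections carry the larger information; (d) per-edge
#' information \eqn{I_{ij} = -\ln(p'_j)\, p'_j}. An isolated centre yields
#' an empty star (all downstream contributions zero).
#'
#' @param sub a [Subnetwork-class].
#' @param M transition matrix of the parent network.
#' @return a [StarInfoNetwork-class].
#' @examples
#' W <- matrix(0, 3, 3, dimnames = rep(list(c("i", "u", "v")), 2))
#' W["i", "u"] <- W["u", "i"] <- 0.4
#' W["i", "v"] <- W["v", "i"] <- 0.1
#' net <- CoexNetwork(W)
#' st <- starTransform(extractSubnetwork(net, "i", 1), transitionMatrix(net))
#' partnerProbs(st)  # inverse-normalised: the weak partner carries more mass
#' @export
starTransform <- function(sub, M) {
  stopifnot(is(sub, "Subnetwork"))
  pMax <- .maxStepProbs(sub, M)
  if (!length(pMax))
    return(new("StarInfoNetwork", center = sub@center,
               pMax = numeric(0), pNorm = numeric(0),
               pTrans = numeric(0), info = numeric(0)))
  pNorm <- pMax / sum(pMax)
  pTrans <- (1 / pNorm) / sum(1 / pNorm)
  info <- ifelse(pTrans >= 1, 0, -log(pmax(pTrans, 1e-300)) * pTrans)
  names(info) <- names(pTrans)
  new("StarInfoNetwork", center = sub@center,
      pMax = pMax, pNorm = pNorm, pTrans = pTrans, info = info)
}

#' @rdname dcgn-accessors
#' @export
setMethod("partnerProbs", "StarInfoNetwork", function(object) object@pTrans)

#' @rdname dcgn-accessors
#' @export
setMethod("partnerInfo", "StarInfoNetwork", function(object) object@info)

#' @rdname dcgn-accessors
#' @export
setMethod("subnetCenter", "StarInfoNetwork", function(object) object@center)

setMethod("show", "StarInfoNetwork", function(object) {
  cat("StarInfoNetwork around '", object@center, "': ",
      length(object@pMax), " partner(s), total information ",
      signif(sum(object@info), 5), "\n", sep = "")
})

.checkGenePair <- function(netA, netB, gene) {
  if (!gene %in% netA@geneIDs) stop("gene '", gene, "' missing from first network")
  if (!gene %in% netB@geneIDs) stop("gene '", gene, "' missing from second network")
}

#' Differential coexpression by local topological dissimilarity (DCGN-S)
#'
#' One minus the Jaccard index of the edge sets of the gene's k-level
#' neighbourhood subgraphs in the two phases:
#' \deqn{d_i = 1 - |E_i^{t_1,k} \cap E_i^{t_2,k}| / |E_i^{t_1,k} \cup E_i^{t_2,k}|.}
#' A gene whose neighbourhood is edgeless in both phases scores 0 (no
#' evidence of coexpression change).
#'
#' @param netA,netB [CoexNetwork-class] objects containing `gene`.
#' @param gene gene ID to score.
#' @param k neighbourhood level.
#' @return dissimilarity in `[0, 1]`; 0 for identical neighbourhoods,
#'   1 for disjoint non-empty edge sets.
#' @seealso [dcgnI()], [scoreAll()]
#' @export
dcgnS <- function(netA, netB, gene, k = 1L) {
  .checkGenePair(netA, netB, gene)
  ea <- extractSubnetwork(netA, gene, k)@edgeKeys
  eb <- extractSubnetwork(netB, gene, k)@edgeKeys
  if (length(ea) == 0 && length(eb) == 0) return(0)
  1 - length(intersect(ea, eb)) / length(union(ea, eb))
}

#' Differential coexpression by variation of topological information (DCGN-I)
#'
#' Builds the star information network ([starTransform()]) of the gene in
#' each phase and sums the per-edge information of neighbourhood members
#' exclusive to one phase:
#' \deqn{I_i = \sum_{j \in N^{t_1,k}_i \setminus N^{t_2,k}_i} I_{ij}^{t_1,k}
#'       + \sum_{j \in N^{t_2,k}_i \setminus N^{t_1,k}_i} I_{ij}^{t_2,k},}
#' where \eqn{N^{t,k}_i} is the node set of the gene's k-level
#' neighbourhood in phase \eqn{t}. Identical node sets give 0. Because the
#' symmetric difference of a high-degree hub that rewires contains many
#' members, hubs receive systematically larger values.
#'
#' @inheritParams dcgnS
#' @return non-negative information variation.
#' @seealso [dcgnS()], [scoreAll()]
#' @export
dcgnI <- function(netA, netB, gene, k = 1L) {
  .checkGenePair(netA, netB, gene)
  subA <- extractSubnetwork(netA, gene, k)
  subB <- extractSubnetwork(netB, gene, k)
  .dcgnIFromSubs(subA, subB, netA@M, netB@M)
}

.dcgnIFromSubs <- function(subA, subB, MA, MB) {
  exclA <- setdiff(setdiff(subA@nodeSet, subA@center), subB@nodeSet)
  exclB <- setdiff(setdiff(subB@nodeSet, subB@center), subA@nodeSet)
  total <- 0
  if (length(exclA)) total <- total + sum(starTransform(subA, MA)@info[exclA])
  if (length(exclB)) total <- total + sum(starTransform(subB, MB)@info[exclB])
  total
}

#' Score every gene across all phase pairs
#'
#' Applies [dcgnS()] or [dcgnI()] to every gene for every unordered pair of
#' phase-specific networks.
#'
#' @param nets list of two or more [CoexNetwork-class] objects over the
#'   identical gene universe (same IDs, same order).
#' @param metric `"S"` (topological dissimilarity) or `"I"` (information
#'   variation).
#' @param k neighbourhood level.
#' @return named list with one score table per unordered phase pair (name
#'   `"<t1>|<t2>"`), each a `data.frame` with columns `gene`, `value` and
#'   attributes `metric`, `k`, `phasePair`.
#' @export
scoreAll <- function(nets, metric = c("S", "I"), k = 1L) {
  metric <- match.arg(metric)
  stopifnot(length(nets) >= 2)
  ids <- geneIDs(nets[[1]])
  for (net in nets[-1])
    if (!identical(geneIDs(net), ids))
      stop("all networks must share the same gene IDs in the same order")

  # subnetworks are reused across pairs: extract once per network
  subs <- lapply(nets, function(net)
    lapply(stats::setNames(ids, ids), function(g) extractSubnetwork(net, g, k)))

  pairs <- utils::combn(length(nets), 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    vals <- vapply(ids, function(g) {
      if (metric == "S") {
        ea <- subs[[a]][[g]]@edgeKeys; eb <- subs[[b]][[g]]@edgeKeys
        if (length(ea) == 0 && length(eb) == 0) 0
        else 1 - length(intersect(ea, eb)) / length(union(ea, eb))
      } else {
        .dcgnIFromSubs(subs[[a]][[g]], subs[[b]][[g]],
                       nets[[a]]@M, nets[[b]]@M)
      }
    }, numeric(1))
    structure(data.frame(gene = ids, value = unname(vals),
                         stringsAsFactors = FALSE),
              metric = metric, k = as.integer(k),
              phasePair = c(phaseLabel(nets[[a]]), phaseLabel(nets[[b]])))
  })
  names(out) <- vapply(pairs, function(pr)
    paste(phaseLabel(nets[[pr[1]]]), phaseLabel(nets[[pr[2]]]), sep = "|"),
    character(1))
  out
}
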