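# Synthetic phase-specific expression data and networks with planted
# differentially coexpressed genes.
#
# Expression model: module members load on a shared latent factor,
# x = sqrt(rho) * f + noiseSD * e, so two members with the default
# noiseSD = sqrt(1 - rho) have expected Pearson correlation rho. Planted
# genes change their relationship to the module structure in phases after
# the first; background genes keep their membership, giving a stable
# network backbone against which rewired genes stand out.

# run `expr` with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic multi-phase expression study
#'
#' Defines the study conditions the generator emulates: a modular
#' coexpression background that is stable across phases, a planted set of
#' rewired genes whose neighbourhoods change after the first phase, plus
#' pure-noise (isolated) genes as edge cases. Defaults describe a
#' desk-scale study: 200 genes (8 modules of 20 plus 40 noise genes),
#' 3 phases, 20 samples per phase, within-module correlation 0.9, and 10
#' hub-collapse positives; networks are built at a fixed soft power 8 and
#' cutoff 0.1, chosen so that with 20 samples the module backbone is stable
#' while spurious correlations stay below the cutoff.
#'
#' @param nGenes total number of genes.
#' @param nSamples samples per phase.
#' @param nPhases number of phases (>= 2).
#' @param nModules number of coexpression modules.
#' @param moduleSize genes per module (`nModules * moduleSize <= nGenes`;
#'   the remainder are pure-noise genes).
#' @param rho expected within-module Pearson correlation, in (0, 1).
#' @param noiseSD standard deviation of the gene-private noise; the default
#'   `sqrt(1 - rho)` gives unit-variance expression and correlation exactly
#'   `rho`.
#' @param nRewired number of planted differentially coexpressed genes
#'   (drawn from module members).
#' @param rewireMode how planted genes change after phase 1:
#'   `"hub-collapse"` (drop to pure noise), `"module-switch"` (move to the
#'   next module), or `"edge-drop"` (mix a private factor in, lowering
#'   module correlation by `1 - dropFraction`).
#' @param dropFraction fraction in (0, 1) used by `"edge-drop"`.
#' @param beta,tau network construction parameters used downstream for
#'   this design (fixed soft power and hard cutoff).
#' @param seed mandatory RNG seed; the generator is fully deterministic
#'   given the spec.
#' @return a list of class `SyntheticSpec`.
#' @seealso [simulateExpression()], [denseSyntheticSpec()]
#' @export
syntheticSpec <- function(nGenes = 200, nSamples = 20, nPhases = 3,
                          nModules = 8, moduleSize = 20, rho = 0.9,
                          noiseSD = sqrt(1 - rho), nRewired = 10,
                          rewireMode = c("hub-collapse", "module-switch",
                                         "edge-drop"),
                          dropFraction = 0.5, beta = 8, tau = 0.1,
                          seed = 1) {
  rewireMode <- match.arg(rewireMode)
  stopifnot(nGenes >= 3, nSamples >= 3, nPhases >= 2,
            rho > 0, rho < 1, noiseSD > 0,
            nModules >= 1, moduleSize >= 2,
            dropFraction > 0, dropFraction < 1,
            nRewired >= 0, length(seed) == 1)
  if (nModules * moduleSize > nGenes)
    stop("module sizes exceed the number of genes")
  if (nRewired > nModules * moduleSize)
    stop("cannot plant more rewired genes than module members")
  structure(list(nGenes = nGenes, nSamples = nSamples, nPhases = nPhases,
                 nModules = nModules, moduleSize = moduleSize, rho = rho,
                 noiseSD = noiseSD, nRewired = nRewired,
                 rewireMode = rewireMode, dropFraction = dropFraction,
                 beta = beta, tau = tau, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Dense-network variant of the synthetic study
#'
#' A variant emulating densely connected coexpression networks with a
#' stable backbone: two large modules (90 genes each, within-module
#' correlation 0.85), a laxer soft power (4) under which scattered genes
#' occasionally pick up spurious edges, and planted genes that lose about
#' half of their module coexpression (`edge-drop`). In such networks a
#' low-degree scatter gene whose one or two spurious edges differ between
#' phases saturates the topological-dissimilarity score at 1 and outranks
#' the genuinely rewired hubs, while the information-based score still
#' weights changes by neighbourhood size — the regime in which the
#' information metric is the more suitable of the two.
#'
#' @inheritParams syntheticSpec
#' @param ... further overrides passed to [syntheticSpec()].
#' @return a `SyntheticSpec`.
#' @export
denseSyntheticSpec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(nGenes = 200, nModules = 2, moduleSize = 90, rho = 0.85,
         nRewired = 10, rewireMode = "edge-drop", dropFraction = 0.5,
         beta = 4, tau = 0.1, seed = seed),
    list(...))
  do.call(syntheticSpec, args)
}

#' Simulate phase-specific expression matrices with planted rewiring
#'
#' Draws one genes-by-samples matrix per phase from the latent-factor
#' module model of the spec. Background module genes keep their module
#' across phases; planted genes follow `rewireMode` from phase 2 onwards;
#' genes outside all modules are pure noise (isolated in the implied
#' networks). Fully deterministic given the spec (seed included).
#'
#' @param spec a [syntheticSpec()].
#' @return list with `exprs` (named list of matrices, one per phase, gene
#'   IDs `g001...` as rownames), `truth` (`data.frame` with columns `gene`,
#'   `planted`), and `spec`.
#' @export
simulateExpression <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  ids <- sprintf("g%03d", seq_len(spec$nGenes))
  module <- rep(NA_integer_, spec$nGenes)
  module[seq_len(spec$nModules * spec$moduleSize)] <-
    rep(seq_len(spec$nModules), each = spec$moduleSize)
  a <- sqrt(spec$rho)

  .withSeed(spec$seed, {
    planted <- sort(sample(which(!is.na(module)), spec$nRewired))
    exprs <- lapply(seq_len(spec$nPhases), function(phase) {
      f <- matrix(stats::rnorm(spec$nModules * spec$nSamples),
                  spec$nModules, spec$nSamples)
      x <- spec$noiseSD *
        matrix(stats::rnorm(spec$nGenes * spec$nSamples),
               spec$nGenes, spec$nSamples)
      for (g in seq_len(spec$nGenes)) {
        mod <- module[g]
        rewiredNow <- phase > 1 && g %in% planted
        if (rewiredNow) {
          mod <- switch(spec$rewireMode,
            "hub-collapse" = NA_integer_,
            "module-switch" = (module[g] %% spec$nModules) + 1L,
            "edge-drop" = module[g])
        }
        if (!is.na(mod)) {
          load <- a
          if (rewiredNow && spec$rewireMode == "edge-drop") {
            # split the module loading with a gene-private factor so the
            # module correlation drops to rho * (1 - dropFraction)
            priv <- stats::rnorm(spec$nSamples)
            x[g, ] <- x[g, ] +
              a * (sqrt(1 - spec$dropFraction) * f[mod, ] +
                   sqrt(spec$dropFraction) * priv)
            next
          }
          x[g, ] <- x[g, ] + load * f[mod, ]
        }
      }
      dimnames(x) <- list(ids, sprintf("s%02d", seq_len(spec$nSamples)))
      x
    })
    names(exprs) <- sprintf("phase%d", seq_len(spec$nPhases))
    list(exprs = exprs,
         truth = data.frame(gene = ids,
                            planted = as.integer(seq_len(spec$nGenes) %in% planted),
                            stringsAsFactors = FALSE),
         spec = spec)
  })
}

#' Simulate a pair of networks with planted rewired nodes
#'
#' Generates a scale-free-ish weighted network (preferential-attachment
#' topology, uniform weights in (0.2, 0.9)) and a second network equal to
#' the first except at the planted nodes, whose incident edges are altered
#' according to `rewireMode`: `"hub-collapse"` removes them all,
#' `"edge-drop"` removes a fraction `dropFraction` of them, and
#' `"module-switch"` reconnects them to randomly chosen new partners. This
#' lets the differential-coexpression scores be exercised directly, free of
#' correlation-estimation noise.
#'
#' @param nNodes number of nodes (>= 5).
#' @param rewired character vector of node IDs to rewire (subset of
#'   `n001...`); empty set with a rewire mode set gives identical networks
#'   with a warning.
#' @param rewireMode one of `"hub-collapse"`, `"edge-drop"`,
#'   `"module-switch"`.
#' @param dropFraction fraction of incident edges dropped by `"edge-drop"`.
#' @param seed RNG seed.
#' @return list with elements `netA` and `netB` ([CoexNetwork-class]).
#' @export
simulateNetworkPair <- function(nNodes, rewired = character(0),
                                rewireMode = c("hub-collapse", "edge-drop",
                                               "module-switch"),
                                dropFraction = 0.5, seed = 1) {
  rewireMode <- match.arg(rewireMode)
  stopifnot(nNodes >= 5)
  ids <- sprintf("n%03d", seq_len(nNodes))
  stopifnot(all(rewired %in% ids))
  if (!length(rewired))
    warning("rewired set is empty; returning identical networks")

  .withSeed(seed, {
    g <- igraph::sample_pa(nNodes, m = 2, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    W <- matrix(0, nNodes, nNodes, dimnames = list(ids, ids))
    wts <- stats::runif(nrow(el), 0.2, 0.9)
    W[el] <- wts
    W[el[, c(2, 1), drop = FALSE]] <- wts
    diag(W) <- 0

    W2 <- W
    for (node in rewired) {
      nb <- which(W2[node, ] > 0)
      if (!length(nb)) next
      drop <- switch(rewireMode,
        "hub-collapse" = nb,
        "edge-drop" = sample(nb, max(1, round(length(nb) * dropFraction))),
        "module-switch" = nb)
      W2[node, drop] <- 0
      W2[drop, node] <- 0
      if (rewireMode == "module-switch") {
        cand <- setdiff(which(W[node, ] == 0), match(node, ids))
        new <- sample(cand, min(length(nb), length(cand)))
        w <- stats::runif(length(new), 0.2, 0.9)
        W2[node, new] <- w
        W2[new, node] <- w
      }
    }
    list(netA = CoexNetwork(W, ids, "phaseA"),
         netB = CoexNetwork(W2, ids, "phaseB"))
  })
}
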