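# Reading and writing the package's file formats: expression TSV/CSV,
# weighted edge lists, GraphML, score/rank tables, labels, YAML config.

#' Read an expression matrix
#'
#' Expects a TSV (or CSV, by extension) with gene IDs in the first column
#' and a header row of sample IDs; one file per phase.
#'
#' @param file path to the file.
#' @return numeric matrix, genes in rows with gene-ID rownames.
#' @export
readExpressionMatrix <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene IDs in ", file)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write / read a network as a weighted edge list
#'
#' Three tab-separated columns `gene_a`, `gene_b`, `weight`; each
#' undirected edge written once with the lexicographically smaller ID
#' first. `readEdgeList()` reconstructs a [CoexNetwork-class]; pass
#' `geneIDs` to retain isolated genes absent from the file.
#'
#' @param net a [CoexNetwork-class].
#' @param file path to the edge-list file.
#' @param geneIDs full gene universe (defaults to the IDs present in the
#'   file).
#' @param phaseLabel phase tag for the reconstructed network.
#' @return `writeEdgeList()` returns `file` invisibly; `readEdgeList()`
#'   returns a [CoexNetwork-class].
#' @export
writeEdgeList <- function(net, file) {
  W <- weightMatrix(net)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  ids <- geneIDs(net)
  a <- ids[idx[, 1]]; b <- ids[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(gene_a = a, gene_b = b, weight = W[idx])
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(file, geneIDs = NULL, phaseLabel = "phase") {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(df)))
  ids <- if (is.null(geneIDs)) sort(unique(c(df$gene_a, df$gene_b)))
         else as.character(geneIDs)
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  W[cbind(match(df$gene_a, ids), match(df$gene_b, ids))] <- df$weight
  W[cbind(match(df$gene_b, ids), match(df$gene_a, ids))] <- df$weight
  CoexNetwork(W, ids, phaseLabel)
}

#' Export a network to GraphML
#'
#' @param net a [CoexNetwork-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeGraphML <- function(net, file) {
  W <- weightMatrix(net)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Write score tables as TSV
#'
#' One row per gene and phase pair with columns `gene_id`, `phase_pair`,
#' `metric`, `k`, `value`.
#'
#' @param tables list of score tables from [scoreAll()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeScoreTables <- function(tables, file) {
  rows <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    data.frame(gene_id = tab$gene, phase_pair = nm,
               metric = attr(tab, "metric"), k = attr(tab, "k"),
               value = tab$value, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a labelled gene set
#'
#' Two-column TSV `gene_id`, `label` with label 1 = disease,
#' 0 = nondisease.
#'
#' @param file path to the label file.
#' @return `data.frame` with columns `gene` and `label`.
#' @export
readGeneLabels <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene", "label")
  stopifnot(all(df$label %in% c(0, 1)))
  df
}
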