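# Coexpression refinement of an interaction network: keep the edges whose
# endpoints are strongly coexpressed across tissues, annotate nodes with
# seed membership and (optionally) a functional class.

#' Refine an interaction network by tissue coexpression
#'
#' Computes the Pearson correlation of the two endpoints' expression
#' profiles across the collapsed tissue columns for every edge and retains
#' edges with correlation strictly greater than the threshold. Edges with
#' an endpoint absent from the expression matrix, or with zero variance in
#' either profile, are dropped (and counted), never retained.
#'
#' @param ppi an [InteractionEdges-class].
#' @param x a [TissueExpression-class]; replicate columns are averaged per
#'   tissue before correlating (correlation is across anatomy, not across
#'   replicates).
#' @param seedGenes gene ids flagged as seeds (e.g. the selected
#'   target-preferential set).
#' @param threshold PCC retention threshold, strict (default 0.5).
#' @param classMap optional named character vector (or two-column
#'   data.frame) mapping gene id to a functional class label.
#' @return A [RefinedNetwork-class]; its node set is exactly the endpoints
#'   of the retained edges.
#' @export
refineNetwork <- function(ppi, x, seedGenes, threshold = 0.5,
                          classMap = NULL) {
    e <- edgeTable(ppi)
    if (length(unique(sampleTissues(x))) < ncol(x))
        x <- collapseReplicates(x)
    v <- assay(x, "log2")
    covered <- e$a %in% rownames(v) & e$b %in% rownames(v)
    nDropped <- sum(!covered)
    e <- e[covered, , drop = FALSE]
    pcc <- vapply(seq_len(nrow(e)), function(i) {
        a <- v[e$a[i], ]; b <- v[e$b[i], ]
        if (stats::sd(a) == 0 || stats::sd(b) == 0)
            return(NA_real_)                     # undefined, never passes
        stats::cor(a, b)
    }, numeric(1L))
    keep <- !is.na(pcc) & pcc > threshold
    edges <- cbind(e[keep, c("a", "b"), drop = FALSE],
                   pcc = pcc[keep],
                   source = e$source[keep])
    rownames(edges) <- NULL
    if (is.data.frame(classMap))
        classMap <- stats::setNames(as.character(classMap[[2L]]),
                                    classMap[[1L]])
    ids <- sort(unique(c(edges$a, edges$b)))
    nodes <- data.frame(id = ids, is_seed = ids %in% seedGenes,
                        class = if (is.null(classMap)) NA_character_
                                else unname(classMap[ids]),
                        stringsAsFactors = FALSE)
    new("RefinedNetwork", edges = edges, nodes = nodes,
        threshold = threshold, nDroppedMissing = as.integer(nDropped))
}

#' Write a refined network
#'
#' Writes the edge table (a, b, pcc, source) and node table (id, is_seed,
#' class) as tab-separated files.
#'
#' @param net a [RefinedNetwork-class].
#' @param dir output directory.
#' @return Invisibly, the two file paths.
#' @export
writeNetwork <- function(net, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ep <- file.path(dir, "network_edges.tsv")
    np <- file.path(dir, "network_nodes.tsv")
    utils::write.table(edgeTable(net), ep, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.table(nodeTable(net), np, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(c(ep, np))
}

#' Export a refined network as GraphML
#'
#' @param net a [RefinedNetwork-class].
#' @param path output GraphML file.
#' @return Invisibly, \code{path}.
#' @export
exportGraphML <- function(net, path) {
    g <- igraph::graph_from_data_frame(
        edgeTable(net), directed = FALSE,
        vertices = within(nodeTable(net),
                          class <- ifelse(is.na(class), "", class)))
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}
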