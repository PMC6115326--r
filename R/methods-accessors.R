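#' @describeIn TissueExpression-class tissue whose preferential genes are
#'   sought.
#' @export
setMethod("targetTissue", "TissueExpression",
          function(x) metadata(x)$targetTissue)

#' @describeIn TissueExpression-class fold-change baseline tissue.
#' @export
setMethod("referenceTissue", "TissueExpression",
          function(x) metadata(x)$referenceTissue)

#' @describeIn TissueExpression-class tissue label of every sample, named by
#'   sample id.
#' @export
setMethod("sampleTissues", "TissueExpression", function(x) {
    stats::setNames(colData(x)$tissue, colnames(x))
})

#' @export
setMethod("collapseReplicates", "TissueExpression", function(x) {
    tis <- colData(x)$tissue
    lev <- unique(tis)
    v <- assay(x, "log2")
    out <- vapply(lev, function(t)
        rowMeans(v[, tis == t, drop = FALSE]), numeric(nrow(v)))
    dimnames(out) <- list(rownames(v), lev)
    TissueExpression(out, stats::setNames(lev, lev),
                     targetTissue(x), referenceTissue(x))
})

setMethod("show", "TissueExpression", function(object) {
    cat("TissueExpression:", nrow(object), "genes x", ncol(object),
        "samples\n")
    tab <- table(colData(object)$tissue)
    cat("  tissues:", paste0(names(tab), " (", tab, ")", collapse = ", "),
        "\n")
    cat("  target:", targetTissue(object),
        " reference:", referenceTissue(object), "\n")
})

#' @describeIn PromoterSet-class the promoter sequences as a
#'   \code{DNAStringSet}.
#' @export
setMethod("promoterSequences", "PromoterSet", function(x) x@sequences)

#' @describeIn PromoterSet-class the nominal window length in nucleotides.
#' @export
setMethod("promoterWindow", "PromoterSet", function(x) x@windowLength)

setMethod("length", "PromoterSet", function(x) length(x@sequences))

setMethod("names", "PromoterSet", function(x) names(x@sequences))

setMethod("show", "PromoterSet", function(object) {
    w <- Biostrings::width(object@sequences)
    cat("PromoterSet:", length(object), "promoters, window",
        object@windowLength, "nt")
    if (length(object))
        cat(" (observed ", min(w), "-", max(w), " nt)", sep = "")
    cat("\n")
})

#' @describeIn AnnotationRepeats-class the gene/term pair table.
#' @export
setMethod("annotationPairs", "AnnotationRepeats", function(x) x@pairs)

#' @describeIn AnnotationRepeats-class the genome-wide repeat total G.
#' @export
setMethod("genomeTotal", "AnnotationRepeats", function(x) x@genomeTotal)

setMethod("show", "AnnotationRepeats", function(object) {
    cat("AnnotationRepeats:", nrow(object@pairs), "gene-term pairs,",
        length(unique(object@pairs$term_id)), "terms, G =",
        object@genomeTotal, "\n")
})

#' @describeIn InteractionEdges-class canonical edge table (a, b, source).
#' @export
setMethod("edgeTable", "InteractionEdges", function(x) x@edges)

setMethod("length", "InteractionEdges", function(x) nrow(x@edges))

setMethod("show", "InteractionEdges", function(object) {
    cat("InteractionEdges:", nrow(object@edges), "edges,",
        length(unique(c(object@edges$a, object@edges$b))), "nodes\n")
})

#' @describeIn OrthologPairs-class the (gene1, gene2) pair table.
#' @export
setMethod("orthologTable", "OrthologPairs", function(x) x@pairs)

setMethod("show", "OrthologPairs", function(object) {
    cat("OrthologPairs:", nrow(object@pairs), "pairs (",
        length(unique(object@pairs$gene1)), "species-1 genes,",
        length(unique(object@pairs$gene2)), "species-2 genes )\n")
})

#' @describeIn Motif-class motif length in nucleotides.
#' @export
setMethod("motifLength", "Motif", function(x) {
    if (x@mode == "consensus") nchar(x@consensus) else nrow(x@matrix)
})

setMethod("show", "Motif", function(object) {
    if (object@mode == "consensus")
        cat("Motif '", object@name, "': consensus ", object@consensus,
            " (<= ", object@maxMismatches, " mismatches)\n", sep = "")
    else
        cat("Motif '", object@name, "': ", nrow(object@matrix),
            "-column probability matrix (score fraction ",
            object@scoreFraction, ")\n", sep = "")
})

#' @describeIn SelectionResult-class the selected gene ids, in input order.
#' @export
setMethod("selectedGenes", "SelectionResult", function(x) x@selected)

#' @describeIn SelectionResult-class per-stage in/out counts.
#' @export
setMethod("stageSummary", "SelectionResult", function(x) x@stages)

#' @describeIn SelectionResult-class per-stage removed genes with reasons.
#' @export
setMethod("removedGenes", "SelectionResult", function(x) x@removed)

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult:", length(object@selected), "genes selected\n")
    s <- object@stages
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %-18s %6d -> %6d\n", s$stage[i], s$n_in[i], s$n_out[i]))
})

#' @describeIn RefinedNetwork-class retained edges with their PCC.
#' @export
setMethod("edgeTable", "RefinedNetwork", function(x) x@edges)

#' @describeIn RefinedNetwork-class node table (id, is_seed, class).
#' @export
setMethod("nodeTable", "RefinedNetwork", function(x) x@nodes)

#' @export
setMethod("networkSummary", "RefinedNetwork", function(x) {
    c(n_edges = nrow(x@edges),
      n_seed_nodes = sum(x@nodes$is_seed),
      n_interactor_nodes = sum(!x@nodes$is_seed))
})

setMethod("show", "RefinedNetwork", function(object) {
    s <- networkSummary(object)
    cat("RefinedNetwork: ", s["n_edges"], " edges (pcc > ",
        object@threshold, "), ", s["n_seed_nodes"], " seed + ",
        s["n_interactor_nodes"], " interactor nodes; ",
        object@nDroppedMissing, " edges lacked expression data\n", sep = "")
})

#' @describeIn SyntheticTruth-class planted preferential gene ids.
#' @export
setMethod("plantedGenes", "SyntheticTruth", function(x) x@preferential)

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@preferential), "planted genes")
    if (!is.na(object@term)) cat(", planted term", object@term)
    if (length(object@motifPositions))
        cat(",", sum(vapply(object@motifPositions, nrow, 0L)),
            "planted motif sites")
    if (nrow(object@plantedEdges))
        cat(",", nrow(object@plantedEdges), "planted edges")
    cat("\n")
})
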