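#' @rdname TissueExpression-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("targetTissue", function(x) standardGeneric("targetTissue"))

#' @rdname TissueExpression-class
#' @export
setGeneric("referenceTissue", function(x) standardGeneric("referenceTissue"))

#' @rdname TissueExpression-class
#' @export
setGeneric("sampleTissues", function(x) standardGeneric("sampleTissues"))

#' Average replicate samples into one column per tissue
#'
#' @param x a [TissueExpression-class] object.
#' @return A [TissueExpression-class] with one column per tissue, each the
#'   arithmetic mean (in log2 units) of that tissue's replicate columns.
#'   Tissue order follows first appearance among the samples.
#' @export
setGeneric("collapseReplicates", function(x) standardGeneric("collapseReplicates"))

#' @rdname SelectionResult-class
#' @param x a \code{SelectionResult}.
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname SelectionResult-class
#' @export
setGeneric("stageSummary", function(x) standardGeneric("stageSummary"))

#' @rdname SelectionResult-class
#' @export
setGeneric("removedGenes", function(x) standardGeneric("removedGenes"))

#' @rdname PromoterSet-class
#' @param x a \code{PromoterSet}.
#' @export
setGeneric("promoterSequences", function(x) standardGeneric("promoterSequences"))

#' @rdname PromoterSet-class
#' @export
setGeneric("promoterWindow", function(x) standardGeneric("promoterWindow"))

#' @rdname AnnotationRepeats-class
#' @param x an \code{AnnotationRepeats} table.
#' @export
setGeneric("annotationPairs", function(x) standardGeneric("annotationPairs"))

#' @rdname AnnotationRepeats-class
#' @export
setGeneric("genomeTotal", function(x) standardGeneric("genomeTotal"))

#' @rdname InteractionEdges-class
#' @param x an object holding edges.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname RefinedNetwork-class
#' @param x a \code{RefinedNetwork}.
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' Summary counts of a refined network
#'
#' @param x a [RefinedNetwork-class].
#' @return Named numeric vector: \code{n_edges}, \code{n_seed_nodes},
#'   \code{n_interactor_nodes}.
#' @export
setGeneric("networkSummary", function(x) standardGeneric("networkSummary"))

#' @rdname OrthologPairs-class
#' @param x an \code{OrthologPairs} table.
#' @export
setGeneric("orthologTable", function(x) standardGeneric("orthologTable"))

#' @rdname SyntheticTruth-class
#' @param x a \code{SyntheticTruth}.
#' @export
setGeneric("plantedGenes", function(x) standardGeneric("plantedGenes"))

#' @rdname Motif-class
#' @param x a \code{Motif}.
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))
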