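#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

# ---------------------------------------------------------------------------
# TissueExpression: a genes x samples log2-intensity matrix with a tissue
# label per sample and a designated target / reference tissue pair.
# ---------------------------------------------------------------------------

#' Multi-tissue expression compendium
#'
#' A \linkS4class{SummarizedExperiment} holding log2 intensities (assay
#' \code{"log2"}) with one tissue label per sample column and a designated
#' target tissue (whose preferential genes are sought) and reference tissue
#' (the fold-change baseline, e.g. whole root for root hairs).
#'
#' @slot .Data inherits all \code{SummarizedExperiment} slots.
#' @seealso [TissueExpression()] for construction,
#'   [collapseReplicates()], [selectPreferential()].
#' @name TissueExpression-class
#' @exportClass TissueExpression
setClass("TissueExpression", contains = "SummarizedExperiment")

setValidity("TissueExpression", function(object) {
    msg <- character()
    a <- SummarizedExperiment::assays(object)
    if (length(a) < 1L)
        return("no assay present")
    x <- a[[1L]]
    if (is.null(rownames(x)) || is.null(colnames(x)))
        msg <- c(msg, "assay must carry gene ids as rownames and sample ids as colnames")
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    if (length(dup))
        msg <- c(msg, paste0("duplicate gene ids: ", paste(utils::head(dup, 3L), collapse = ", ")))
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    if (length(dup))
        msg <- c(msg, paste0("duplicate sample ids: ", paste(utils::head(dup, 3L), collapse = ", ")))
    if (!is.numeric(x) || any(!is.finite(x)))
        msg <- c(msg, "all expression values must be finite numbers")
    tis <- colData(object)[["tissue"]]
    if (is.null(tis) || anyNA(tis))
        msg <- c(msg, "every sample needs a tissue label in colData(x)$tissue")
    tgt <- metadata(object)[["targetTissue"]]
    ref <- metadata(object)[["referenceTissue"]]
    if (is.null(tgt) || !tgt %in% tis)
        msg <- c(msg, "targetTissue must map to at least one sample")
    if (is.null(ref) || !ref %in% tis)
        msg <- c(msg, "referenceTissue must map to at least one sample")
    if (length(msg)) msg else TRUE
})

#' Construct a TissueExpression object
#'
#' @param values numeric matrix of log2 intensities; rownames are gene ids,
#'   colnames are sample ids.
#' @param tissue character vector of tissue labels, either named by sample id
#'   or positionally aligned with \code{colnames(values)}.
#' @param targetTissue,referenceTissue tissue labels; each must annotate at
#'   least one sample.
#' @return A [TissueExpression-class] object.
#' @examples
#' m <- matrix(8 + rnorm(6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' te <- TissueExpression(m, c(s1 = "root_hair", s2 = "root"),
#'                        "root_hair", "root")
#' @export
TissueExpression <- function(values, tissue, targetTissue, referenceTissue) {
    if (!is.matrix(values))
        values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (!is.null(names(tissue))) {
        missing <- setdiff(colnames(values), names(tissue))
        if (length(missing))
            stop("samples without a tissue label: ",
                 paste(utils::head(missing, 5L), collapse = ", "))
        tissue <- unname(tissue[colnames(values)])
    }
    if (length(tissue) != ncol(values))
        stop("'tissue' must provide one label per sample column")
    se <- SummarizedExperiment(
        assays = list(log2 = values),
        colData = DataFrame(tissue = as.character(tissue),
                            row.names = colnames(values)))
    metadata(se)$targetTissue <- targetTissue
    metadata(se)$referenceTissue <- referenceTissue
    new("TissueExpression", se)
}

# ---------------------------------------------------------------------------
# PromoterSet
# ---------------------------------------------------------------------------

#' Promoter sequence set
#'
#' Upstream promoter windows, one per gene, stored as a
#' \code{\link[Biostrings]{DNAStringSet}}. Sequences are uppercase over
#' A/C/G/T/N and never longer than the nominal window (genes near a contig
#' edge may be shorter).
#'
#' @slot sequences a named \code{DNAStringSet}.
#' @slot windowLength nominal promoter window length in nucleotides.
#' @name PromoterSet-class
#' @exportClass PromoterSet
setClass("PromoterSet",
         representation(sequences = "DNAStringSet", windowLength = "integer"))

setValidity("PromoterSet", function(object) {
    msg <- character()
    s <- object@sequences
    if (length(s)) {
        if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
            msg <- c(msg, "every promoter needs a gene id")
        if (anyDuplicated(names(s)))
            msg <- c(msg, "duplicate gene ids in promoter set")
        freq <- colSums(Biostrings::alphabetFrequency(s))
        extra <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
        if (extra > 0)
            msg <- c(msg, "promoter sequences must use only A/C/G/T/N")
        if (any(Biostrings::width(s) > object@windowLength))
            msg <- c(msg, "promoter longer than the declared window")
    }
    if (length(object@windowLength) != 1L || object@windowLength < 1L)
        msg <- c(msg, "windowLength must be a single positive integer")
    if (length(msg)) msg else TRUE
})

#' Construct a PromoterSet
#'
#' @param sequences named character vector or \code{DNAStringSet}; names are
#'   gene ids. Lowercase input is uppercased.
#' @param windowLength nominal window length (default 2000 nt).
#' @return A [PromoterSet-class] object.
#' @export
PromoterSet <- function(sequences, windowLength = 2000L) {
    ids <- names(sequences)
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
    if (is.null(names(sequences)))
        names(sequences) <- ids
    new("PromoterSet", sequences = sequences,
        windowLength = as.integer(windowLength))
}

# ---------------------------------------------------------------------------
# AnnotationRepeats
# ---------------------------------------------------------------------------

#' Gene-to-term annotation repeats
#'
#' A flat gene/term annotation table ("repeats": one row per gene-term
#' assignment) together with the genome-wide total number of repeats G used
#' as the hypergeometric population size.
#'
#' @slot pairs data.frame with columns \code{gene_id}, \code{term_id},
#'   \code{term_label}.
#' @slot genomeTotal total number of annotation repeats genome-wide (G).
#' @name AnnotationRepeats-class
#' @exportClass AnnotationRepeats
setClass("AnnotationRepeats",
         representation(pairs = "data.frame", genomeTotal = "numeric"))

setValidity("AnnotationRepeats", function(object) {
    msg <- character()
    p <- object@pairs
    need <- c("gene_id", "term_id", "term_label")
    if (!all(need %in% names(p)))
        msg <- c(msg, paste0("pairs must have columns ",
                             paste(need, collapse = ", ")))
    else if (anyDuplicated(p[c("gene_id", "term_id")]))
        msg <- c(msg, "duplicate (gene_id, term_id) pair")
    if (length(object@genomeTotal) != 1L || object@genomeTotal <= 0)
        msg <- c(msg, "genomeTotal (G) must be a single positive number")
    else if (all(need %in% names(p)) && object@genomeTotal < nrow(p))
        msg <- c(msg, "genomeTotal (G) smaller than the number of stored pairs")
    if (length(msg)) msg else TRUE
})

#' Construct an AnnotationRepeats table
#'
#' @param pairs data.frame with columns \code{gene_id}, \code{term_id} and
#'   optionally \code{term_label} (defaults to \code{term_id}).
#' @param genomeTotal genome-wide total number of annotation repeats G;
#'   defaults to \code{nrow(pairs)} (the table is the whole genome).
#' @return An [AnnotationRepeats-class] object.
#' @export
AnnotationRepeats <- function(pairs, genomeTotal = nrow(pairs)) {
    pairs <- as.data.frame(pairs)
    if (is.null(pairs$term_label))
        pairs$term_label <- pairs$term_id
    pairs <- pairs[c("gene_id", "term_id", "term_label")]
    pairs[] <- lapply(pairs, as.character)
    rownames(pairs) <- NULL
    new("AnnotationRepeats", pairs = pairs, genomeTotal = as.numeric(genomeTotal))
}

# ---------------------------------------------------------------------------
# InteractionEdges
# ---------------------------------------------------------------------------

#' Undirected interaction edge list
#'
#' Protein-protein (or other) interactions stored canonically: no self-loops,
#' \code{a < b} lexicographically, no duplicates.
#'
#' @slot edges data.frame with columns \code{a}, \code{b}, \code{source}.
#' @name InteractionEdges-class
#' @exportClass InteractionEdges
setClass("InteractionEdges", representation(edges = "data.frame"))

setValidity("InteractionEdges", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("a", "b", "source") %in% names(e)))
        msg <- c(msg, "edges must have columns a, b, source")
    else {
        if (any(e$a == e$b))
            msg <- c(msg, "self-loops are not allowed")
        if (any(e$a > e$b))
            msg <- c(msg, "edges must be stored canonically (a < b)")
        if (anyDuplicated(e[c("a", "b")]))
            msg <- c(msg, "duplicate edges")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an InteractionEdges object
#'
#' Edges are canonicalized (endpoints sorted within each edge), self-loops
#' rejected, duplicates collapsed to the first occurrence.
#'
#' @param a,b character vectors of endpoint gene ids.
#' @param source optional character vector tagging the provenance of each
#'   edge (default \code{"ppi"}).
#' @return An [InteractionEdges-class] object.
#' @export
InteractionEdges <- function(a = character(), b = character(), source = "ppi") {
    a <- as.character(a); b <- as.character(b)
    if (length(a) != length(b))
        stop("'a' and 'b' must have the same length")
    if (any(a == b))
        stop("self-loop edge(s): ", paste(utils::head(a[a == b], 3L), collapse = ", "))
    source <- rep_len(as.character(source), length(a))
    lo <- pmin(a, b); hi <- pmax(a, b)
    e <- data.frame(a = lo, b = hi, source = source, stringsAsFactors = FALSE)
    e <- e[!duplicated(e[c("a", "b")]), , drop = FALSE]
    rownames(e) <- NULL
    new("InteractionEdges", edges = e)
}

# ---------------------------------------------------------------------------
# OrthologPairs
# ---------------------------------------------------------------------------

#' Cross-species ortholog pair table
#'
#' Oriented (species1, species2) gene pairs; many-to-many relations are
#' allowed, duplicate pairs are not.
#'
#' @slot pairs data.frame with columns \code{gene1}, \code{gene2}.
#' @name OrthologPairs-class
#' @exportClass OrthologPairs
setClass("OrthologPairs", representation(pairs = "data.frame"))

setValidity("OrthologPairs", function(object) {
    p <- object@pairs
    if (!all(c("gene1", "gene2") %in% names(p)))
        return("pairs must have columns gene1, gene2")
    if (anyDuplicated(p[c("gene1", "gene2")]))
        return("duplicate ortholog pair")
    TRUE
})

#' Construct an OrthologPairs table
#'
#' @param gene1,gene2 character vectors: species-1 and species-2 gene ids of
#'   each pair.
#' @return An [OrthologPairs-class] object.
#' @export
OrthologPairs <- function(gene1 = character(), gene2 = character()) {
    p <- unique(data.frame(gene1 = as.character(gene1),
                           gene2 = as.character(gene2),
                           stringsAsFactors = FALSE))
    rownames(p) <- NULL
    new("OrthologPairs", pairs = p)
}

# ---------------------------------------------------------------------------
# Motif
# ---------------------------------------------------------------------------

#' Promoter motif (IUPAC consensus or position probability matrix)
#'
#' In consensus mode the motif is an IUPAC string (alphabet
#' ACGTRYSWKMBDHVN) matched with up to \code{maxMismatches} mismatches; an N
#' in the scanned promoter never matches. In matrix mode the motif is a
#' length x 4 position probability matrix (rows sum to 1, columns A,C,G,T)
#' scored as log2 odds against a uniform background; windows scoring at
#' least \code{scoreFraction} of the maximum attainable score are reported.
#'
#' @slot name motif name.
#' @slot mode \code{"consensus"} or \code{"pwm"}.
#' @slot consensus IUPAC consensus (consensus mode).
#' @slot matrix position probability matrix, length x 4 (matrix mode).
#' @slot maxMismatches allowed mismatches (consensus mode).
#' @slot scoreFraction fraction of the maximum log-odds score (matrix mode).
#' @name Motif-class
#' @exportClass Motif
setClass("Motif",
         representation(name = "character", mode = "character",
                        consensus = "character", matrix = "matrix",
                        maxMismatches = "integer", scoreFraction = "numeric"))

setValidity("Motif", function(object) {
    msg <- character()
    if (!object@mode %in% c("consensus", "pwm"))
        return("mode must be 'consensus' or 'pwm'")
    len <- motifLength(object)
    if (len < 4L || len > 30L)
        msg <- c(msg, "motif length must be in [4, 30]")
    if (object@mode == "consensus") {
        bad <- setdiff(strsplit(object@consensus, "")[[1]],
                       strsplit("ACGTRYSWKMBDHVN", "")[[1]])
        if (length(bad))
            msg <- c(msg, paste0("invalid consensus letter(s): ",
                                 paste(unique(bad), collapse = ", ")))
        if (object@maxMismatches < 0L)
            msg <- c(msg, "maxMismatches must be >= 0")
    } else {
        m <- object@matrix
        if (ncol(m) != 4L)
            msg <- c(msg, "probability matrix must have 4 columns (A,C,G,T)")
        else if (any(abs(rowSums(m) - 1) > 1e-9))
            msg <- c(msg, "probability matrix rows must sum to 1")
        if (object@scoreFraction <= 0 || object@scoreFraction > 1)
            msg <- c(msg, "scoreFraction must be in (0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Motif
#'
#' @param consensus IUPAC consensus string (consensus mode), or \code{NULL}.
#' @param matrix length x 4 position probability matrix with columns
#'   A,C,G,T (matrix mode), or \code{NULL}. Exactly one of \code{consensus}
#'   and \code{matrix} must be given.
#' @param name motif name.
#' @param maxMismatches mismatches tolerated in consensus mode (default 0).
#' @param scoreFraction log-odds threshold as a fraction of the maximum
#'   attainable score in matrix mode (default 0.85).
#' @return A [Motif-class] object.
#' @examples
#' Motif(consensus = "GCACGTG", maxMismatches = 1)
#' @export
Motif <- function(consensus = NULL, matrix = NULL, name = "motif",
                  maxMismatches = 0L, scoreFraction = 0.85) {
    if (is.null(consensus) == is.null(matrix))
        stop("give exactly one of 'consensus' or 'matrix'")
    if (!is.null(consensus)) {
        new("Motif", name = name, mode = "consensus",
            consensus = toupper(consensus), matrix = base::matrix(0, 0, 4),
            maxMismatches = as.integer(maxMismatches), scoreFraction = 1)
    } else {
        colnames(matrix) <- c("A", "C", "G", "T")
        new("Motif", name = name, mode = "pwm", consensus = "",
            matrix = matrix, maxMismatches = 0L,
            scoreFraction = scoreFraction)
    }
}

# ---------------------------------------------------------------------------
# SelectionResult
# ---------------------------------------------------------------------------

#' Result of the multi-stage preferential-gene selection
#'
#' Holds the surviving gene ids plus per-stage provenance: for every stage
#' the number of genes entering and leaving, and the removed genes with a
#' reason string.
#'
#' @slot selected ordered character vector of selected gene ids.
#' @slot stages data.frame with columns \code{stage}, \code{n_in},
#'   \code{n_out}.
#' @slot removed named list (one entry per stage) of data.frames with
#'   columns \code{gene_id}, \code{reason}.
#' @slot params the [selectionParams()] list used.
#' @name SelectionResult-class
#' @exportClass SelectionResult
setClass("SelectionResult",
         representation(selected = "character", stages = "data.frame",
                        removed = "list", params = "list"))

setValidity("SelectionResult", function(object) {
    s <- object@stages
    msg <- character()
    if (nrow(s)) {
        if (any(s$n_out > s$n_in))
            msg <- c(msg, "a stage cannot emit more genes than it received")
        if (nrow(s) > 1L && any(s$n_in[-1L] != s$n_out[-nrow(s)]))
            msg <- c(msg, "stage in/out counts must telescope")
        if (length(object@selected) != s$n_out[nrow(s)])
            msg <- c(msg, "selected set must equal the final stage output")
    }
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RefinedNetwork
# ---------------------------------------------------------------------------

#' Coexpression-refined interaction network
#'
#' Interaction edges retained because their endpoints' expression profiles
#' across tissues exceed a Pearson correlation threshold, with node
#' annotation (seed membership, optional functional class).
#'
#' @slot edges data.frame with columns \code{a}, \code{b}, \code{pcc},
#'   \code{source}.
#' @slot nodes data.frame with columns \code{id}, \code{is_seed},
#'   \code{class}.
#' @slot threshold the PCC retention threshold (strictly greater than).
#' @slot nDroppedMissing edges dropped because an endpoint lacked
#'   expression data.
#' @name RefinedNetwork-class
#' @exportClass RefinedNetwork
setClass("RefinedNetwork",
         representation(edges = "data.frame", nodes = "data.frame",
                        threshold = "numeric", nDroppedMissing = "integer"))

setValidity("RefinedNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (nrow(e)) {
        if (any(!is.finite(e$pcc)) || any(e$pcc <= object@threshold))
            msg <- c(msg, "every retained edge must have pcc > threshold")
        if (!all(c(e$a, e$b) %in% object@nodes$id))
            msg <- c(msg, "every edge endpoint must be a node")
        if (!all(object@nodes$id %in% c(e$a, e$b)))
            msg <- c(msg, "every node must touch at least one retained edge")
    }
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SyntheticTruth
# ---------------------------------------------------------------------------

#' Ground truth planted by the synthetic-data generators
#'
#' @slot preferential gene ids planted as target-tissue preferential.
#' @slot term planted over-represented annotation term id.
#' @slot motifPositions named list (gene id -> data.frame with columns
#'   \code{offset}, \code{strand}) of planted motif occurrences.
#' @slot plantedEdges data.frame (\code{a}, \code{b}) of planted
#'   interaction edges.
#' @slot params named list of all generator parameters, including seeds.
#' @name SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(preferential = "character", term = "character",
                        motifPositions = "list", plantedEdges = "data.frame",
                        params = "list"),
         prototype(preferential = character(), term = NA_character_,
                   motifPositions = list(),
                   plantedEdges = data.frame(a = character(),
                                             b = character()),
                   params = list()))
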