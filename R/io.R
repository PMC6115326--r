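# Readers and writers for the tab-separated tables and sequence formats the
# pipeline consumes. All writers emit UTF-8 with Unix newlines; expression
# tables are tab-separated with a mandatory header and decimal points.

#' Read a multi-tissue expression matrix
#'
#' @param path tab-separated table: first column gene ids (header
#'   \code{gene_id}), remaining columns one per sample, header row sample
#'   ids.
#' @param tissueMap either the path of a two-column tab-separated table
#'   (\code{sample_id}, \code{tissue}) or a named character vector mapping
#'   sample id to tissue label. Must cover every sample.
#' @param targetTissue,referenceTissue tissue labels, each mapping to at
#'   least one sample.
#' @return A validated [TissueExpression-class]; row and column order of the
#'   file are preserved.
#' @export
readExpressionMatrix <- function(path, tissueMap, targetTissue,
                                 referenceTissue) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
    gene <- tab[[1L]]
    dup <- unique(gene[duplicated(gene)])
    if (length(dup))
        stop("duplicate gene id(s) in ", path, ": ",
             paste(utils::head(dup, 5L), collapse = ", "))
    vals <- as.matrix(tab[-1L])
    suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    if (anyNA(num)) {
        bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
        stop("non-numeric value at row ", bad["row"], " (gene ",
             gene[bad["row"]], "), column '", colnames(vals)[bad["col"]], "'")
    }
    dimnames(num) <- list(gene, colnames(vals))
    if (is.character(tissueMap) && is.null(names(tissueMap)) &&
        length(tissueMap) == 1L && file.exists(tissueMap)) {
        tm <- utils::read.table(tissueMap, header = TRUE, sep = "\t",
                                colClasses = "character", quote = "")
        tissueMap <- stats::setNames(tm[[2L]], tm[[1L]])
    }
    unmapped <- setdiff(colnames(num), names(tissueMap))
    if (length(unmapped))
        stop("sample(s) without a tissue label: ",
             paste(utils::head(unmapped, 5L), collapse = ", "))
    TissueExpression(num, tissueMap, targetTissue, referenceTissue)
}

#' Write an expression matrix
#'
#' @param x a [TissueExpression-class].
#' @param path output file; a sibling \code{<path>.tissues.tsv} receives
#'   the sample-to-tissue map.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path) {
    v <- assay(x, "log2")
    df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    tm <- data.frame(sample_id = colnames(v),
                     tissue = unname(sampleTissues(x)))
    utils::write.table(tm, paste0(path, ".tissues.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Read pre-windowed promoter sequences from FASTA
#'
#' Gene ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased; N is allowed; sequences longer than
#' \code{windowLength} are an error (extract windows first with
#' [extractPromoters()]).
#'
#' @param path FASTA file.
#' @param windowLength nominal promoter window (default 2000 nt).
#' @return A [PromoterSet-class].
#' @export
readPromoterFasta <- function(path, windowLength = 2000L) {
    s <- Biostrings::readDNAStringSet(path)
    names(s) <- vapply(strsplit(names(s), "\\s+"), `[`, "", 1L)
    if (any(Biostrings::width(s) > windowLength))
        stop("promoter sequence(s) longer than the ", windowLength,
             "-nt window: ",
             paste(utils::head(names(s)[Biostrings::width(s) > windowLength],
                               3L), collapse = ", "))
    PromoterSet(s, windowLength)
}

#' Write promoters to FASTA
#'
#' @param x a [PromoterSet-class].
#' @param path output FASTA file.
#' @return Invisibly, \code{path}.
#' @export
writePromoterFasta <- function(x, path) {
    Biostrings::writeXStringSet(promoterSequences(x), path)
    invisible(path)
}

#' Extract strand-aware promoter windows from a genome
#'
#' For a + strand gene the window covers the \code{windowLength} bases
#' immediately 5' of the feature start; for a - strand gene, the reverse
#' complement of the window immediately 3' of the feature end. Windows are
#' truncated at contig edges. In the returned sequences position 0 is the
#' farthest-upstream base, so the last base abuts the annotated start.
#'
#' @param genomeFasta genome FASTA file.
#' @param gff GFF3 file; features of type \code{gene} are used. Gene ids are
#'   taken from the \code{ID} attribute.
#' @param windowLength window size in nucleotides (default 2000).
#' @return A [PromoterSet-class].
#' @export
extractPromoters <- function(genomeFasta, gff, windowLength = 2000L) {
    genome <- Biostrings::readDNAStringSet(genomeFasta)
    names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[`, "", 1L)
    gr <- rtracklayer::import(gff)
    gr <- gr[gr$type == "gene"]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(!chr %in% names(genome)))
        stop("contig(s) absent from the genome: ",
             paste(utils::head(setdiff(chr, names(genome)), 3L),
                   collapse = ", "))
    if (any(strand == "*"))
        stop("gene feature(s) without strand: ",
             paste(utils::head(ids[strand == "*"], 3L), collapse = ", "))
    seqs <- character(length(gr))
    for (i in seq_along(gr)) {
        len <- length(genome[[chr[i]]])
        if (strand[i] == "+") {
            # GFF3 is 1-based inclusive; window is [start - w, start - 1]
            from <- max(1L, BiocGenerics::start(gr)[i] - windowLength)
            to <- BiocGenerics::start(gr)[i] - 1L
            s <- if (to < from) "" else
                as.character(Biostrings::subseq(genome[[chr[i]]], from, to))
        } else {
            from <- BiocGenerics::end(gr)[i] + 1L
            to <- min(len, BiocGenerics::end(gr)[i] + windowLength)
            s <- if (to < from) "" else
                reverseComplementString(
                    as.character(Biostrings::subseq(genome[[chr[i]]],
                                                    from, to)))
        }
        seqs[i] <- s
    }
    names(seqs) <- ids
    PromoterSet(seqs[nchar(seqs) > 0L], windowLength)
}

#' Read a gene-to-term annotation table
#'
#' @param path tab-separated table with header; columns \code{gene_id},
#'   \code{term_id} and optionally \code{term_label}.
#' @param genomeTotal genome-wide total number of annotation repeats G. When
#'   \code{NULL} (default) the table is taken to be genome-wide and G is its
#'   row count.
#' @return An [AnnotationRepeats-class].
#' @export
readAnnotationTable <- function(path, genomeTotal = NULL) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "")
    AnnotationRepeats(tab, genomeTotal = if (is.null(genomeTotal))
        nrow(tab) else genomeTotal)
}

#' @rdname readAnnotationTable
#' @param x an [AnnotationRepeats-class].
#' @export
writeAnnotationTable <- function(x, path) {
    utils::write.table(annotationPairs(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read an interaction edge list
#'
#' @param path tab-separated table with header; first two columns are the
#'   endpoints, an optional third column a source tag.
#' @return An [InteractionEdges-class] (canonicalized, deduplicated).
#' @export
readEdgeList <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "")
    InteractionEdges(tab[[1L]], tab[[2L]],
                     if (ncol(tab) >= 3L) tab[[3L]] else "ppi")
}

#' @rdname readEdgeList
#' @param x an [InteractionEdges-class].
#' @export
writeEdgeList <- function(x, path) {
    utils::write.table(edgeTable(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read an ortholog pair table
#'
#' @param path tab-separated table with header; columns are the species-1
#'   and species-2 gene ids of each pair.
#' @return An [OrthologPairs-class].
#' @export
readOrthologPairs <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "")
    OrthologPairs(tab[[1L]], tab[[2L]])
}

#' @rdname readOrthologPairs
#' @param x an [OrthologPairs-class].
#' @export
writeOrthologPairs <- function(x, path) {
    utils::write.table(orthologTable(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a motif file
#'
#' Two formats are accepted: a minimal MEME-style motif file (a
#' \code{MOTIF <name>} line followed by a \code{letter-probability matrix:}
#' block with one A/C/G/T probability row per position), or a one-line IUPAC
#' consensus, optionally preceded by a \code{>name} header line.
#'
#' @param path motif file.
#' @param maxMismatches mismatches tolerated in consensus mode.
#' @param scoreFraction score threshold (fraction of maximum) in matrix
#'   mode.
#' @return A [Motif-class].
#' @export
readMotif <- function(path, maxMismatches = 0L, scoreFraction = 0.85) {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (any(grepl("^letter-probability matrix", lines))) {
        nameLine <- grep("^MOTIF\\b", lines, value = TRUE)
        name <- if (length(nameLine))
            strsplit(nameLine[1L], "\\s+")[[1L]][2L] else "motif"
        i <- grep("^letter-probability matrix", lines)[1L]
        rows <- list()
        for (j in seq(i + 1L, length(lines))) {
            v <- suppressWarnings(as.numeric(strsplit(lines[j], "\\s+")[[1L]]))
            if (length(v) != 4L || anyNA(v)) break
            rows[[length(rows) + 1L]] <- v
        }
        Motif(matrix = do.call(rbind, rows), name = name,
              scoreFraction = scoreFraction)
    } else {
        name <- "motif"
        if (startsWith(lines[1L], ">")) {
            name <- sub("^>\\s*", "", lines[1L])
            lines <- lines[-1L]
        }
        Motif(consensus = lines[1L], name = name,
              maxMismatches = maxMismatches)
    }
}
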