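# Promoter motif scanning on both strands. Offsets are 0-based positions
# of the match's leftmost base on the forward promoter strand; position 0
# is the farthest-upstream base of the window, so distance to the TSS is
# L - offset - w.

# Exact mismatch count of a concrete window against an IUPAC consensus;
# an N in the window never matches (the IUPAC expansion of every code
# covers A/C/G/T only).
consensusMismatches <- function(windowChars, allowed) {
    sum(!mapply(function(ch, a) ch %in% a, windowChars, allowed,
                USE.NAMES = FALSE))
}

scanConsensusOneStrand <- function(subject, consensus, maxMismatch) {
    w <- nchar(consensus)
    if (w > length(subject))
        return(integer())
    # candidate superset via bit-overlap matching, then an exact recount
    # that treats subject N as a mismatch at every position
    cand <- Biostrings::matchPattern(Biostrings::DNAString(consensus),
                                     subject, max.mismatch = maxMismatch,
                                     fixed = FALSE)
    starts <- BiocGenerics::start(cand)
    if (!length(starts))
        return(integer())
    allowed <- iupacAllowed(strsplit(consensus, "")[[1L]])
    mism <- vapply(starts, function(s) {
        win <- strsplit(as.character(
            Biostrings::subseq(subject, s, s + w - 1L)), "")[[1L]]
        consensusMismatches(win, allowed)
    }, 0L)
    stats::setNames(starts[mism <= maxMismatch], mism[mism <= maxMismatch])
}

# Log-odds score rows against a uniform background, with a small
# pseudocount so zero probabilities stay finite.
pwmLogOdds <- function(prob, pseudocount = 1e-4) {
    p <- (prob + pseudocount) / (1 + 4 * pseudocount)
    log2(p / 0.25)
}

scanPwmOneStrand <- function(seqChars, lo, threshold) {
    w <- nrow(lo)
    L <- length(seqChars)
    if (w > L)
        return(list(starts = integer(), scores = numeric()))
    idx <- match(seqChars, c("A", "C", "G", "T"))   # N -> NA
    nWin <- L - w + 1L
    scores <- numeric(nWin)
    ok <- rep(TRUE, nWin)
    for (j in seq_len(w)) {
        col <- idx[j:(j + nWin - 1L)]
        bad <- is.na(col)
        ok <- ok & !bad                  # window with N never matches
        col[bad] <- 1L
        scores <- scores + lo[j, col]
    }
    keep <- ok & scores >= threshold
    list(starts = which(keep), scores = scores[keep])
}

#' Scan one promoter for a motif on both strands
#'
#' Slides the motif and its reverse complement across every valid offset.
#' Consensus mode reports windows with at most \code{maxMismatches}
#' mismatches (an N in the promoter never matches and always counts as a
#' mismatch); matrix mode reports windows whose log2-odds score against a
#' uniform background reaches \code{scoreFraction} of the maximum
#' attainable score. All overlapping occurrences are reported.
#'
#' @param promoter a promoter sequence (character or
#'   \code{\link[Biostrings]{DNAString}}, alphabet A/C/G/T/N).
#' @param motif a [Motif-class].
#' @return data.frame with columns \code{offset} (0-based, leftmost base on
#'   the forward strand), \code{strand} (\code{+}/\code{-}; hits sorted by
#'   offset, then \code{+} before \code{-}), \code{match} (the matched
#'   sequence read in motif orientation) and \code{score} (mismatch count
#'   in consensus mode, log2-odds in matrix mode). A motif longer than the
#'   promoter yields zero rows.
#' @examples
#' scanPromoter("AAGCACGTGTT", Motif(consensus = "GCACGTG"))
#' @export
scanPromoter <- function(promoter, motif) {
    seqStr <- toupper(as.character(promoter))
    subject <- Biostrings::DNAString(seqStr)
    w <- motifLength(motif)
    empty <- data.frame(offset = integer(), strand = character(),
                        match = character(), score = numeric(),
                        stringsAsFactors = FALSE)
    if (w > length(subject))
        return(empty)
    if (motif@mode == "consensus") {
        fwd <- scanConsensusOneStrand(subject, motif@consensus,
                                      motif@maxMismatches)
        rev <- scanConsensusOneStrand(
            subject, reverseComplementString(motif@consensus),
            motif@maxMismatches)
        hits <- data.frame(
            offset = c(fwd, rev) - 1L,
            strand = rep(c("+", "-"), c(length(fwd), length(rev))),
            score = as.numeric(c(names(fwd), names(rev))),
            stringsAsFactors = FALSE)
    } else {
        lo <- pwmLogOdds(motif@matrix)
        threshold <- motif@scoreFraction * sum(apply(lo, 1L, max))
        chars <- strsplit(seqStr, "")[[1L]]
        fwd <- scanPwmOneStrand(chars, lo, threshold)
        # reverse strand: scan with the reverse-complemented matrix
        loRC <- lo[rev(seq_len(nrow(lo))), c(4L, 3L, 2L, 1L), drop = FALSE]
        bwd <- scanPwmOneStrand(chars, loRC, threshold)
        hits <- data.frame(
            offset = c(fwd$starts, bwd$starts) - 1L,
            strand = rep(c("+", "-"),
                         c(length(fwd$starts), length(bwd$starts))),
            score = c(fwd$scores, bwd$scores),
            stringsAsFactors = FALSE)
    }
    if (nrow(hits) == 0L)
        return(empty)
    win <- substring(seqStr, hits$offset + 1L, hits$offset + w)
    hits$match <- ifelse(hits$strand == "+", win,
                         vapply(win, reverseComplementString, ""))
    hits <- hits[order(hits$offset, match(hits$strand, c("+", "-"))), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    hits[c("offset", "strand", "match", "score")]
}

#' Scan a promoter set and summarize hits per gene
#'
#' @param promoters a [PromoterSet-class].
#' @param motif a [Motif-class].
#' @return A list: \code{hits}, the concatenated [scanPromoter()] tables
#'   with a leading \code{gene_id} column and a \code{distance_to_tss}
#'   column (\code{L - offset - w}); and \code{summary}, a named vector
#'   with \code{total_hits}, \code{genes_with_hit} and
#'   \code{fraction_with_hit}.
#' @export
scanPromoterSet <- function(promoters, motif) {
    seqs <- promoterSequences(promoters)
    w <- motifLength(motif)
    per <- lapply(seq_along(seqs), function(i) {
        h <- scanPromoter(seqs[[i]], motif)
        if (nrow(h) == 0L)
            return(NULL)
        cbind(gene_id = names(seqs)[i], h,
              distance_to_tss = Biostrings::width(seqs)[i] - h$offset - w,
              stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, per)
    if (is.null(hits))
        hits <- data.frame(gene_id = character(), offset = integer(),
                           strand = character(), match = character(),
                           score = numeric(), distance_to_tss = integer(),
                           stringsAsFactors = FALSE)
    nWith <- length(unique(hits$gene_id))
    list(hits = hits,
         summary = c(total_hits = nrow(hits), genes_with_hit = nWith,
                     fraction_with_hit = if (length(seqs))
                         nWith / length(seqs) else 0))
}

#' Write a motif hit table
#'
#' @param scan result of [scanPromoterSet()].
#' @param path output file (tab-separated).
#' @return Invisibly, \code{path}.
#' @export
writeMotifHits <- function(scan, path) {
    utils::write.table(scan$hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
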