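# Repeat-based annotation-term over-representation. The population is the
# set of genome-wide annotation repeats (gene-term assignments), not the
# set of genes: with m repeats of a term genome-wide, Q repeats across the
# queried genes and G repeats genome-wide, the expected count is m*Q/G and
# observing k repeats of the term among the query is scored by the
# hypergeometric upper tail. A gene-based parameterization is available
# via countUnits = "genes".

#' Count annotation repeats for a query gene set
#'
#' @param annotations an [AnnotationRepeats-class].
#' @param queryGenes non-empty character vector of gene ids; genes absent
#'   from the annotation contribute nothing.
#' @return A list: \code{counts} (data.frame with \code{term_id},
#'   \code{term_label}, \code{m} genome repeats, \code{k} query repeats),
#'   \code{Q} (total query repeats) and \code{G} (genome total).
#' @export
countRepeats <- function(annotations, queryGenes) {
    if (length(queryGenes) == 0L)
        stop("empty query gene set")
    p <- annotationPairs(annotations)
    m <- table(p$term_id)
    inQ <- p$gene_id %in% queryGenes
    k <- table(factor(p$term_id[inQ], levels = names(m)))
    labels <- p$term_label[!duplicated(p$term_id)]
    names(labels) <- p$term_id[!duplicated(p$term_id)]
    counts <- data.frame(term_id = names(m),
                         term_label = unname(labels[names(m)]),
                         m = as.integer(m), k = as.integer(k),
                         stringsAsFactors = FALSE)
    rownames(counts) <- NULL
    list(counts = counts, Q = sum(counts$k), G = genomeTotal(annotations))
}

#' Expected number of annotation repeats under proportional sampling
#'
#' @param m genome-wide repeats of the term.
#' @param Q total repeats across the queried genes.
#' @param G total repeats genome-wide (> 0).
#' @return \code{m * Q / G}, unrounded.
#' @examples
#' expectedCount(9, 422, 39571)     # 0.0959... , 0.10 at 2 dp
#' @export
expectedCount <- function(m, Q, G) {
    if (any(G <= 0))
        stop("G must be positive")
    m * Q / G
}

#' Fold enrichment of observed over expected repeats
#'
#' Computed from the unrounded expectation; any rounding happens at report
#' time only. \code{expected == 0} with \code{k > 0} yields \code{Inf};
#' with \code{k == 0}, \code{NaN}.
#'
#' @param k observed repeats in the query.
#' @param expected unrounded expected count (>= 0).
#' @return \code{k / expected}.
#' @export
foldEnrichment <- function(k, expected) {
    if (any(expected < 0))
        stop("expected must be >= 0")
    ifelse(expected == 0, ifelse(k > 0, Inf, NaN), k / expected)
}

#' Hypergeometric upper-tail p-value for term over-representation
#'
#' P(X >= k) for X ~ Hypergeometric(population G, successes m, draws Q).
#'
#' @param k observed successes (0 <= k <= min(m, Q)).
#' @param m,Q,G hypergeometric parameters with \code{m, Q <= G}.
#' @return Upper-tail probability in [0, 1].
#' @export
hypergeomPValue <- function(k, m, Q, G) {
    if (any(m > G) || any(Q > G) || any(k > pmin(m, Q)) || any(k < 0))
        stop("inconsistent hypergeometric counts")
    stats::phyper(k - 1, m, G - m, Q, lower.tail = FALSE)
}

#' Term enrichment table for a query gene set
#'
#' Computes per-term observed and expected repeat counts, fold enrichment
#' and the raw hypergeometric p-value (no multiple-testing correction is
#' applied; the column is named \code{p_raw} accordingly).
#'
#' @param annotations an [AnnotationRepeats-class].
#' @param queryGenes character vector of gene ids.
#' @param countUnits \code{"repeats"} (default: population = annotation
#'   repeats, the parameterization whose expectation m*Q/G the reference
#'   tables pin down) or \code{"genes"} (population = annotated genes,
#'   draws = queried annotated genes, per-term counts = distinct genes).
#' @return data.frame with columns \code{term_id}, \code{term_label},
#'   \code{m}, \code{k}, \code{expected}, \code{fold}, \code{p_raw},
#'   plus attributes \code{Q} and \code{G}.
#' @export
termEnrichment <- function(annotations, queryGenes,
                           countUnits = c("repeats", "genes")) {
    countUnits <- match.arg(countUnits)
    if (countUnits == "repeats") {
        cr <- countRepeats(annotations, queryGenes)
        counts <- cr$counts; Q <- cr$Q; G <- cr$G
    } else {
        p <- annotationPairs(annotations)
        u <- p[!duplicated(p[c("gene_id", "term_id")]), ]
        m <- table(u$term_id)
        inQ <- u$gene_id %in% queryGenes
        k <- table(factor(u$term_id[inQ], levels = names(m)))
        labels <- p$term_label[!duplicated(p$term_id)]
        names(labels) <- p$term_id[!duplicated(p$term_id)]
        counts <- data.frame(term_id = names(m),
                             term_label = unname(labels[names(m)]),
                             m = as.integer(m), k = as.integer(k),
                             stringsAsFactors = FALSE)
        G <- length(unique(p$gene_id))
        Q <- length(intersect(unique(p$gene_id), queryGenes))
    }
    if (Q == 0L)
        stop("query genes share no annotation with the table")
    counts$expected <- expectedCount(counts$m, Q, G)
    counts$fold <- foldEnrichment(counts$k, counts$expected)
    counts$p_raw <- hypergeomPValue(counts$k, counts$m, Q, G)
    attr(counts, "Q") <- Q
    attr(counts, "G") <- G
    counts
}

#' Select over-represented terms
#'
#' Keeps terms with \code{p_raw <= pMax} and \code{fold >= foldMin} (both
#' inclusive), sorted by fold descending with ties broken by term id.
#'
#' @param enrichment a [termEnrichment()] table.
#' @param pMax raw hypergeometric p cutoff (default 0.05).
#' @param foldMin minimum fold enrichment (default 2).
#' @return The filtered, sorted subset of the input table.
#' @export
enrichSelect <- function(enrichment, pMax = 0.05, foldMin = 2) {
    keep <- enrichment$p_raw <= pMax & enrichment$fold >= foldMin
    out <- enrichment[keep, , drop = FALSE]
    out <- out[order(-out$fold, out$term_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "Q") <- attr(enrichment, "Q")
    attr(out, "G") <- attr(enrichment, "G")
    out
}

#' Write an enrichment report
#'
#' Tab-separated report with \code{expected} and \code{fold} displayed at
#' 2 decimal places (half-up) and the unrounded raw hypergeometric p; a
#' header comment states Q, G and that the p-values are uncorrected.
#'
#' @param enrichment a [termEnrichment()] (or [enrichSelect()]) table.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeEnrichmentTable <- function(enrichment, path) {
    out <- enrichment
    out$expected <- sprintf("%.2f", roundHalfUp(out$expected, 2L))
    out$fold <- sprintf("%.2f", roundHalfUp(out$fold, 2L))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf(
        "# term enrichment: Q = %s query repeats, G = %s genome repeats; p column is raw hypergeometric p (uncorrected)",
        attr(enrichment, "Q"), attr(enrichment, "G")), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
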