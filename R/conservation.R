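# Cross-species conservation of tissue-preferential expression: ortholog
# coverage of each species' preferential set and the fraction whose
# ortholog partner is itself preferential in the other species.

#' Ortholog coverage and expression-conservation statistics
#'
#' A species-1 gene "has an ortholog" iff it appears in at least one pair
#' of the table, and is "conserved" iff at least one of its partners lies
#' in the species-2 preferential set (and symmetrically for species 2).
#' Many-to-many orthology is counted at the gene level: each gene counts
#' once however many partners it has.
#'
#' @param set1,set2 preferential gene sets of species 1 and species 2.
#' @param orthologs an [OrthologPairs-class], oriented
#'   (species 1, species 2).
#' @return data.frame with one row per species and columns \code{n} (set
#'   size), \code{with_ortholog}, \code{conserved},
#'   \code{pct_with_ortholog} and \code{pct_conserved} (percentages of
#'   \code{n}, half-up at 1 decimal place).
#' @examples
#' orth <- OrthologPairs(c("r1", "r2"), c("a1", "a9"))
#' conservationStats(c("r1", "r2", "r3"), c("a1", "a2"), orth)
#' @export
conservationStats <- function(set1, set2, orthologs) {
    p <- orthologTable(orthologs)
    set1 <- unique(as.character(set1)); set2 <- unique(as.character(set2))
    with1 <- intersect(set1, p$gene1)
    with2 <- intersect(set2, p$gene2)
    cons1 <- intersect(set1, p$gene1[p$gene2 %in% set2])
    cons2 <- intersect(set2, p$gene2[p$gene1 %in% set1])
    pct <- function(count, n) if (n == 0L) 0 else
        roundHalfUp(100 * count / n, 1L)
    data.frame(
        species = c("species1", "species2"),
        n = c(length(set1), length(set2)),
        with_ortholog = c(length(with1), length(with2)),
        conserved = c(length(cons1), length(cons2)),
        pct_with_ortholog = c(pct(length(with1), length(set1)),
                              pct(length(with2), length(set2))),
        pct_conserved = c(pct(length(cons1), length(set1)),
                          pct(length(cons2), length(set2))),
        stringsAsFactors = FALSE)
}

#' Write a conservation summary
#'
#' @param stats a [conservationStats()] table.
#' @param path output file (tab-separated).
#' @return Invisibly, \code{path}.
#' @export
writeConservationStats <- function(stats, path) {
    utils::write.table(stats, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
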