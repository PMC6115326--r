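# Shared fixtures and independent oracles. The oracles here are written as
# plain double loops / closed forms so they stay independent of the
# package's implementation paths.

assay <- SummarizedExperiment::assay

tissues10 <- c("root_hair", "root", "leaf", "stem", "seed",
               "flower", "anther", "pistil", "embryo", "callus")

tinyExpression <- function() {
    m <- matrix(c(10, 8, 12, 9, 9, 6,
                  10.2, 8.1, 11.8, 9.2, 8.8, 6.1),
                nrow = 3, byrow = FALSE,
                dimnames = list(c("g1", "g2", "g3"),
                                c("rh_1", "rt_1", "rh_2", "rt_2")))
    TissueExpression(m[, c(1, 3, 2, 4)],
                     c(rh_1 = "root_hair", rh_2 = "root_hair",
                       rt_1 = "root", rt_2 = "root"),
                     "root_hair", "root")
}

# Naive O(L * w) double-loop motif scanner over both strands; IUPAC-aware,
# N in the sequence never matches.
naiveScan <- function(seqStr, consensus, maxMismatch = 0L) {
    iu <- Biostrings::IUPAC_CODE_MAP
    expand <- function(cons) strsplit(unname(iu[strsplit(cons, "")[[1]]]), "")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(consensus)))
    allowF <- expand(consensus); allowR <- expand(rc)
    chars <- strsplit(toupper(seqStr), "")[[1]]
    w <- nchar(consensus); L <- length(chars)
    off <- integer(); str <- character(); sc <- integer()
    if (w <= L) for (o in 0:(L - w)) {
        win <- chars[(o + 1):(o + w)]
        mmF <- 0L; mmR <- 0L
        for (j in seq_len(w)) {
            if (!win[j] %in% allowF[[j]]) mmF <- mmF + 1L
            if (!win[j] %in% allowR[[j]]) mmR <- mmR + 1L
        }
        if (mmF <= maxMismatch) {
            off <- c(off, o); str <- c(str, "+"); sc <- c(sc, mmF)
        }
        if (mmR <= maxMismatch) {
            off <- c(off, o); str <- c(str, "-"); sc <- c(sc, mmR)
        }
    }
    d <- data.frame(offset = off, strand = str, score = as.numeric(sc),
                    stringsAsFactors = FALSE)
    d[order(d$offset, match(d$strand, c("+", "-"))), , drop = FALSE]
}

# Exhaustive-enumeration hypergeometric upper tail via binomial coefficients.
hyperEnumUpper <- function(k, m, Q, G) {
    js <- seq(max(k, max(0, Q - (G - m))), min(m, Q))
    if (k > min(m, Q)) return(0)
    sum(choose(m, js) * choose(G - m, Q - js)) / choose(G, Q)
}

# Cross-species fixture realizing set sizes 409/405 with 315/289 genes in
# ortholog pairs, of which 50/38 have a partner in the other species' set.
conservationFixture <- function() {
    rice <- sprintf("r%03d", 1:409)
    ara <- sprintf("a%03d", 1:405)
    g1 <- c(sprintf("r%03d", 1:38),          # 1-1 conserved pairs
            sprintf("r%03d", 39:50),         # extra conserved rice, reusing
            sprintf("r%03d", 51:315),        # rice w/ ortholog outside set2
            sprintf("rx%03d", 1:251))        # outside-set1 partners
    g2 <- c(sprintf("a%03d", 1:38),
            sprintf("a%03d", 1:12),
            sprintf("ax%03d", 1:265),        # ara partners outside set2
            sprintf("a%03d", 39:289))        # ara w/ ortholog outside set1
    list(set1 = rice, set2 = ara, orth = OrthologPairs(g1, g2))
}

# Reference per-term genome (m) and query (k) repeat counts for the
# published 409-gene root-hair-preferential query (Q = 422, G = 39571),
# with the printed expected/fold display values.
referenceEnrichmentTable <- function() {
    tab <- utils::read.table(
        system.file("extdata", "go_reference_counts.tsv",
                    package = "TissuePref"),
        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    tab$printed_expected <- c(0.10, 0.22, 0.57, 1.41, 0.54, 0.49, 1.98,
                              0.32, 2.16, 0.51, 1.13, 2.13, 16.99)
    tab$printed_fold <- c(31.25, 13.39, 5.10, 2.84, 5.52, 8.15, 6.55,
                          6.25, 2.31, 5.86, 3.54, 3.75, 2.47)
    tab
}
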