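test_that("a promoter equal to the motif yields exactly its own-strand hit", {
    m <- Motif(consensus = "GCACGTAC")
    hits <- scanPromoter("GCACGTAC", m)
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$offset, 0L)
    expect_identical(hits$strand, "+")
    expect_identical(hits$match, "GCACGTAC")
    expect_identical(hits$score, 0)

    # a reverse-complement palindrome is reported on both strands
    pal <- Motif(consensus = "GCATATGC")
    hitsP <- scanPromoter("GCATATGC", pal)
    expect_identical(hitsP$strand, c("+", "-"))
})

test_that("reverse-complement copies are found on the minus strand", {
    m <- Motif(consensus = "GCACGTACTGCATCGA")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString("GCACGTACTGCATCGA")))
    promoter <- paste0(strrep("A", 500), rc, strrep("A", 484))
    hits <- scanPromoter(promoter, m)
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$offset, 500L)
    expect_identical(hits$strand, "-")
    expect_identical(hits$match, "GCACGTACTGCATCGA")
})

test_that("an N in the promoter never matches and counts as a mismatch", {
    m0 <- Motif(consensus = "GCACGTAC", maxMismatches = 0)
    expect_identical(nrow(scanPromoter("GCACGNAC", m0)), 0L)
    m1 <- Motif(consensus = "GCACGTAC", maxMismatches = 1)
    hits <- scanPromoter("GCACGNAC", m1)
    expect_identical(hits$score[hits$strand == "+"], 1)
})

test_that("IUPAC ambiguity codes in the consensus expand correctly", {
    m <- Motif(consensus = "GCRYGTAC")    # R = A/G, Y = C/T
    expect_identical(nrow(scanPromoter("GCACGTAC", m)), 1L)
    expect_identical(nrow(scanPromoter("GCGTGTAC", m)), 1L)
    expect_identical(nrow(scanPromoter("GCCCGTAC", m)), 0L)
})

test_that("the scanner equals the naive double-loop oracle with mismatches", {
    set.seed(7)
    consensus <- "GCACGTACTGCATCGA"
    for (i in 1:20) {
        seqStr <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                        collapse = "")
        for (mm in c(0L, 2L, 4L)) {
            got <- scanPromoter(seqStr, Motif(consensus = consensus,
                                              maxMismatches = mm))
            ref <- naiveScan(seqStr, consensus, mm)
            expect_identical(got$offset, ref$offset)
            expect_identical(got$strand, ref$strand)
            expect_identical(got$score, ref$score)
        }
    }
})

test_that("strand symmetry: scanning the reverse complement mirrors offsets", {
    set.seed(9)
    consensus <- "GCACGTACTGCATCGA"
    m <- Motif(consensus = consensus, maxMismatches = 2)
    w <- motifLength(m)
    flip <- c("+" = "-", "-" = "+")
    for (i in 1:5) {
        L <- 200L
        # plant one forward and one reverse-complement copy so both
        # orientations carry hits
        chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        chars[21:36] <- strsplit(consensus, "")[[1]]
        chars[101:116] <- strsplit(as.character(
            Biostrings::reverseComplement(
                Biostrings::DNAString(consensus))), "")[[1]]
        s <- paste(chars, collapse = "")
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        fwd <- scanPromoter(s, m)
        expect_gte(nrow(fwd), 2L)
        bwd <- scanPromoter(rc, m)
        mapped <- data.frame(offset = L - w - bwd$offset,
                             strand = unname(flip[bwd$strand]),
                             score = bwd$score,
                             stringsAsFactors = FALSE)
        mapped <- mapped[order(mapped$offset,
                               match(mapped$strand, c("+", "-"))), ]
        expect_identical(fwd$offset, mapped$offset)
        expect_identical(fwd$strand, mapped$strand)
        expect_identical(fwd$score, mapped$score)
    }
})

test_that("matrix-mode scanning thresholds on the fraction of the top score", {
    # a deterministic matrix equivalent to consensus GCAC at fraction 1
    pm <- matrix(0, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    pm[1, "G"] <- 1; pm[2, "C"] <- 1; pm[3, "A"] <- 1; pm[4, "C"] <- 1
    m <- Motif(matrix = pm, scoreFraction = 1)
    hits <- scanPromoter("TTGCACTT", m)
    expect_identical(hits$offset, 2L)
    expect_identical(hits$strand, "+")
    # the reverse complement GTGC is found on the minus strand
    hitsRC <- scanPromoter("TTGTGCTT", m)
    expect_identical(hitsRC$strand, "-")
    # an N inside the window suppresses the hit
    expect_identical(nrow(scanPromoter("TTGNACTT", m)), 0L)
    # a soft matrix with a lowered fraction admits a one-off window
    soft <- matrix(0.05, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    soft[1, "G"] <- 0.85; soft[2, "C"] <- 0.85
    soft[3, "A"] <- 0.85; soft[4, "C"] <- 0.85
    mSoft <- Motif(matrix = soft, scoreFraction = 0.4)
    hitsSoft <- scanPromoter("TTGCTCTT", mSoft)   # GCTC: one mismatch
    expect_true(any(hitsSoft$offset == 2L & hitsSoft$strand == "+"))
    # but not at a stringent fraction
    mHard <- Motif(matrix = soft, scoreFraction = 0.9)
    hitsHard <- scanPromoter("TTGCTCTT", mHard)
    expect_false(any(hitsHard$offset == 2L & hitsHard$strand == "+"))
})

test_that("motif longer than the promoter yields an empty result, not an error", {
    m <- Motif(consensus = "GCACGTACTGCATCGA")
    expect_identical(nrow(scanPromoter("GCAC", m)), 0L)
})

test_that("gene-set scanning counts total hits and genes with hits", {
    motif <- Motif(consensus = "GCCGTTGC")
    copy <- "GCCGTTGC"
    bg <- strrep("A", 100)
    seqs <- c(g1 = paste0(copy, strrep("A", 12), copy, strrep("A", 72)),
              g2 = paste0(strrep("A", 30), copy, copy, strrep("A", 54)),
              g3 = bg, g4 = bg, g5 = bg,
              g6 = paste0(strrep("A", 92), copy),
              g7 = bg, g8 = bg, g9 = bg, g10 = bg)
    ps <- PromoterSet(seqs, 100)
    scan <- scanPromoterSet(ps, motif)
    expect_identical(unname(scan$summary["total_hits"]), 5)
    expect_identical(unname(scan$summary["genes_with_hit"]), 3)
    expect_identical(unname(scan$summary["fraction_with_hit"]), 0.30)
    expect_identical(
        scan$hits$distance_to_tss,
        100L - scan$hits$offset - 8L)
    empty <- scanPromoterSet(PromoterSet(c(gx = bg), 100), motif)
    expect_identical(unname(empty$summary),
                     c(0, 0, 0))
})
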