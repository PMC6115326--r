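test_that("generators are bit-reproducible given the seed", {
    a <- simulateCompendium(100, tissues10[1:4], replicates = 2,
                            nPreferential = 10, seed = 7)
    b <- simulateCompendium(100, tissues10[1:4], replicates = 2,
                            nPreferential = 10, seed = 7)
    expect_identical(assay(a$expr, "log2"), assay(b$expr, "log2"))
    expect_identical(plantedGenes(a$truth), plantedGenes(b$truth))
    c <- simulateCompendium(100, tissues10[1:4], replicates = 2,
                            nPreferential = 10, seed = 8)
    expect_false(identical(assay(a$expr, "log2"), assay(c$expr, "log2")))
})

test_that("the planted effect size is recovered on average", {
    sim <- simulateCompendium(2000, tissues10, replicates = 3,
                              nPreferential = 100, effectLog2 = 2,
                              noiseSd = 0.3, seed = 12)
    coll <- assay(collapseReplicates(sim$expr), "log2")
    planted <- plantedGenes(sim$truth)
    gap <- coll[planted, "root_hair"] -
        rowMeans(coll[planted, setdiff(colnames(coll), "root_hair")])
    se <- stats::sd(gap) / sqrt(length(gap))
    expect_lt(abs(mean(gap) - 2), 3 * se)
})

test_that("a zero effect leaves planted target means indistinguishable", {
    sim <- simulateCompendium(1000, tissues10[1:5], replicates = 3,
                              nPreferential = 100, effectLog2 = 0,
                              seed = 13)
    coll <- assay(collapseReplicates(sim$expr), "log2")
    planted <- plantedGenes(sim$truth)
    bg <- setdiff(rownames(coll), planted)
    p <- stats::t.test(coll[planted, "root_hair"],
                       coll[bg, "root_hair"])$p.value
    expect_gt(p, 0.005)
})

test_that("generator input validation rejects impossible sizes and rates", {
    expect_error(simulateCompendium(10, tissues10[1:3], nPreferential = 11),
                 "exceed")
    expect_error(simulateCompendium(10, tissues10[1:3], effectLog2 = -1),
                 "effectLog2")
    truth <- new("SyntheticTruth", preferential = "g1")
    expect_error(simulateAnnotations(paste0("g", 1:5), truth,
                                     enrichmentRate = 1.5), "rates")
    expect_error(simulateAnnotations(paste0("g", 1:5), truth, nTerms = 0),
                 "term")
})

test_that("the planted term dominates fold enrichment across seeds", {
    hits <- vapply(1:30, function(s) {
        sim <- simulateCompendium(1000, tissues10[1:4], replicates = 1,
                                  nPreferential = 100, seed = s)
        ann <- simulateAnnotations(rownames(sim$expr), sim$truth,
                                   nTerms = 50, enrichmentRate = 0.5,
                                   backgroundRate = 0.02, seed = s)
        enr <- termEnrichment(ann$annotations, plantedGenes(sim$truth))
        enr$term_id[which.max(enr$fold)] == "TERM_planted"
    }, TRUE)
    expect_gte(mean(hits), 0.95)
})

test_that("matched rates leave the planted term unenriched", {
    sim <- simulateCompendium(500, tissues10[1:4], replicates = 1,
                              nPreferential = 50, seed = 41)
    ann <- simulateAnnotations(rownames(sim$expr), sim$truth, nTerms = 20,
                               enrichmentRate = 0.1, backgroundRate = 0.1,
                               seed = 41)
    enr <- termEnrichment(ann$annotations, plantedGenes(sim$truth))
    fold <- enr$fold[enr$term_id == "TERM_planted"]
    expect_lt(abs(fold - 1), 1)    # fold ~ 1, not systematically inflated
    expect_gt(enr$p_raw[enr$term_id == "TERM_planted"], 0.01)
})

test_that("planted motif copies are placed, recorded and recoverable", {
    motif <- Motif(consensus = "GCACGTACTGCATCGA")
    truth <- new("SyntheticTruth",
                 preferential = sprintf("g%02d", 1:6))
    sim <- simulatePromoters(sprintf("g%02d", 1:20), truth, motif,
                             windowLength = 500, hitsPerGene = 2,
                             seed = 17)
    pos <- sim$truth@motifPositions
    expect_length(pos, 6L)
    w <- motifLength(motif)
    for (g in names(pos)) {
        hits <- scanPromoter(promoterSequences(sim$promoters)[[g]], motif)
        # every recorded position is found on the recorded strand
        for (i in seq_len(nrow(pos[[g]]))) {
            expect_true(any(hits$offset == pos[[g]]$offset[i] &
                            hits$strand == pos[[g]]$strand[i]))
        }
        # planted positions lie within the promoter and do not overlap
        o <- sort(pos[[g]]$offset)
        expect_true(all(o >= 0 & o <= 500 - w))
        expect_true(all(diff(o) >= w))
    }
})

test_that("background promoters produce only chance-level motif hits", {
    # short 8-nt consensus so the closed-form expectation is appreciable:
    # E[hits] = 2 * (L - w + 1) * n * (1/4)^w
    motif <- Motif(consensus = "GCACGTAC")
    truth <- new("SyntheticTruth")
    sim <- simulatePromoters(sprintf("g%02d", 1:50), truth, motif,
                             genesWithMotif = character(),
                             windowLength = 500, seed = 19)
    scan <- scanPromoterSet(sim$promoters, motif)
    expected <- 2 * (500 - 8 + 1) * 50 * (1 / 4)^8
    sigma <- sqrt(expected)
    expect_lte(scan$summary[["total_hits"]], expected + 3 * sigma + 1)
})

test_that("simulated interaction lists have exact structure", {
    truth <- new("SyntheticTruth",
                 preferential = sprintf("g%02d", 1:10))
    sim <- simulatePPI(sprintf("g%02d", 1:40), truth, nEdgesPlanted = 10,
                       nEdgesBackground = 30, seed = 23)
    e <- edgeTable(sim$ppi)
    expect_identical(nrow(e), 40L)
    expect_identical(sum(e$source == "planted"), 10L)
    planted <- plantedGenes(truth)
    expect_true(all(e$a[e$source == "planted"] %in% planted &
                    e$b[e$source == "planted"] %in% planted))
    expect_false(any(e$a[e$source == "background"] %in% planted |
                     e$b[e$source == "background"] %in% planted))
    expect_false(any(duplicated(e[c("a", "b")])))
    expect_true(all(e$a < e$b))
    empty <- simulatePPI(sprintf("g%02d", 1:40), truth, seed = 23)
    expect_identical(nrow(edgeTable(empty$ppi)), 0L)
    expect_error(simulatePPI(sprintf("g%02d", 1:40), truth,
                             nEdgesPlanted = 1000, seed = 1),
                 "more planted edges")
})

test_that("a bundle writes every input plus machine-readable truth", {
    dir <- withr::local_tempdir()
    bundle <- simulateBundle(dir, nGenes = 150, tissues = tissues10[1:5],
                             replicates = 2, nPreferential = 15,
                             nEdgesPlanted = 10, nEdgesBackground = 20,
                             seed = 29)
    expect_true(all(file.exists(file.path(
        dir, c("expression.tsv", "expression.tsv.tissues.tsv",
               "annotations.tsv", "promoters.fasta", "ppi.tsv",
               "motif.txt", "truth.yaml")))))
    truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
    expect_identical(sort(unlist(truth$preferential)),
                     plantedGenes(bundle$truth))
})
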