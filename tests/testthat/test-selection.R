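test_that("quantile normalization equalizes column distributions", {
    # hand example: ranks map both columns onto the per-rank means
    m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                dimnames = list(paste0("g", 1:3), c("s1", "s2")))
    te <- TissueExpression(m, c(s1 = "a", s2 = "b"), "a", "b")
    qn <- quantileNormalize(te)
    expect_equal(unname(assay(qn, "log2")),
                 cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

    # identical columns are a fixed point
    m2 <- matrix(c(7, 9, 8, 7, 9, 8), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("s1", "s2")))
    te2 <- TissueExpression(m2, c(s1 = "a", s2 = "b"), "a", "b")
    expect_equal(assay(quantileNormalize(te2), "log2"), m2)

    # random matrix: all column distributions identical (sort-and-compare)
    set.seed(11)
    m3 <- matrix(rnorm(200, 10), 50, 4,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
    te3 <- TissueExpression(m3, stats::setNames(c("a", "a", "b", "b"),
                                                paste0("s", 1:4)), "a", "b")
    v <- assay(quantileNormalize(te3), "log2")
    sorted <- apply(v, 2, sort)
    for (j in 2:4)
        expect_equal(sorted[, j], sorted[, 1])
})

test_that("a single-sample matrix passes through normalization with a warning", {
    m <- matrix(1:3, 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
    te <- TissueExpression(m, c(s1 = "a"), "a", "a")
    expect_warning(out <- quantileNormalize(te), "single sample")
    expect_equal(assay(out, "log2"), assay(te, "log2"))
})

test_that("replicate collapsing averages per tissue and is idempotent", {
    te <- tinyExpression()  # root_hair replicate pairs (10, 10.2), (8, 8.1), (12, 11.8)
    coll <- collapseReplicates(te)
    v <- assay(coll, "log2")
    expect_identical(colnames(v), c("root_hair", "root"))
    expect_equal(unname(v[, "root_hair"]), c(10.1, 8.05, 11.9))
    expect_equal(unname(v[, "root"]), c(9.1, 8.9, 6.05))
    # collapsing a collapsed matrix (k equal columns per tissue) is identity
    expect_equal(assay(collapseReplicates(coll), "log2"), v)
})

test_that("the expression filter is strict and matches a naive re-scan", {
    m <- matrix(c(8, 9, 7.99, 8, 9, 8.01), 3, 2,
                dimnames = list(c("gBoundary", "gIn", "gOut"),
                                c("root_hair", "root")))
    te <- TissueExpression(m, c(root_hair = "root_hair", root = "root"),
                           "root_hair", "root")
    kept <- filterExpressed(te, 8)
    expect_false("gBoundary" %in% kept)     # max exactly 8 -> excluded
    expect_identical(kept, c("gIn", "gOut"))

    sim <- simulateCompendium(400, tissues10[1:5], replicates = 2,
                              nPreferential = 20, seed = 21)
    coll <- collapseReplicates(sim$expr)
    v <- assay(coll, "log2")
    naive <- rownames(v)[vapply(seq_len(nrow(v)),
                                function(i) any(v[i, ] > 8), TRUE)]
    expect_identical(filterExpressed(coll, 8), naive)
})

test_that("k-means has the closed form at k=1 and separates distant blobs", {
    set.seed(5)
    m <- matrix(rnorm(40, 10), 20, 2,
                dimnames = list(sprintf("g%02d", 1:20), c("a", "b")))
    te <- TissueExpression(m, c(a = "a", b = "b"), "a", "b")
    cl1 <- clusterExpression(te, k = 1, seed = 1)
    expect_equal(unname(cl1$centroids[1, ]), unname(colMeans(m)))
    expect_equal(cl1$inertia,
                 sum(sweep(m, 2, colMeans(m))^2))

    # two blobs 10 sigma apart must be recovered exactly
    blob <- rbind(matrix(rnorm(12, 0, 0.5), 6, 2),
                  matrix(rnorm(12, 5, 0.5), 6, 2))
    dimnames(blob) <- list(sprintf("g%02d", 1:12), c("a", "b"))
    teB <- TissueExpression(blob, c(a = "a", b = "b"), "a", "b")
    clB <- clusterExpression(teB, k = 2, seed = 1)
    lab <- clB$assignment
    expect_length(unique(lab[1:6]), 1L)
    expect_length(unique(lab[7:12]), 1L)
    expect_false(lab[1] == lab[7])

    expect_error(clusterExpression(teB, k = 20, seed = 1), "fewer genes")
})

test_that("the preferential cluster maximizes target-vs-best-other contrast", {
    cl <- list(centroids = rbind(c(10, 6, 5), c(8, 8, 8)))
    colnames(cl$centroids) <- c("root_hair", "root", "leaf")
    expect_identical(unname(selectPreferentialCluster(cl, "root_hair")), 1L)
    # all-identical centroids: tie resolves to the lowest (first) index
    clTie <- list(centroids = rbind(c(8, 8), c(8, 8), c(8, 8)))
    colnames(clTie$centroids) <- c("root_hair", "root")
    expect_identical(unname(selectPreferentialCluster(clTie, "root_hair")),
                     1L)
    expect_error(selectPreferentialCluster(cl, "petal"), "petal")
})

test_that("cross-tissue elimination applies the margin to non-reference tissues", {
    m <- rbind(gKeep = c(12, 8, 10, 9),
               gDrop = c(12, 8, 11.5, 9),
               gEdge = c(12, 8, 11, 9))
    colnames(m) <- c("root_hair", "root", "leaf", "stem")
    te <- TissueExpression(m, stats::setNames(colnames(m), colnames(m)),
                           "root_hair", "root")
    expect_identical(dropCrossTissueHigh(rownames(m), te, 1),
                     c("gKeep", "gEdge"))     # >= margin is inclusive
    # margin 0 keeps exactly genes maximal among non-reference tissues
    expect_identical(dropCrossTissueHigh(rownames(m), te, 0), rownames(m))
})

test_that("the fold-change rule is inclusive and matches linear-scale arithmetic", {
    m <- rbind(gTwoFold = c(10, 9), gBelow = c(10, 9.5), gAbove = c(12, 9))
    colnames(m) <- c("root_hair", "root")
    te <- TissueExpression(m, stats::setNames(colnames(m), colnames(m)),
                           "root_hair", "root")
    kept <- foldChangeFilter(rownames(m), te, 2)
    expect_identical(kept, c("gTwoFold", "gAbove"))
    # linear-scale oracle: 2^target >= fold * 2^reference
    naive <- rownames(m)[2^m[, "root_hair"] >= 2 * 2^m[, "root"]]
    expect_identical(kept, naive)
})

test_that("selection stages telescope and the result is deterministic", {
    sim <- simulateCompendium(400, tissues10[1:6], replicates = 3,
                              nPreferential = 25, seed = 31)
    p <- selectionParams(nClusters = 6, seed = 31)
    res <- selectPreferential(sim$expr, p)
    s <- stageSummary(res)
    expect_identical(s$n_in[-1], s$n_out[-nrow(s)])
    for (nm in names(removedGenes(res)))
        expect_identical(nrow(removedGenes(res)[[nm]]),
                         s$n_out[match(nm, s$stage)] * -1L +
                             s$n_in[match(nm, s$stage)])
    # each stage's output is a subset of its input (telescoping)
    expect_true(all(selectedGenes(res) %in% rownames(sim$expr)))
    res2 <- selectPreferential(sim$expr, p)
    expect_identical(res, res2)
})
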