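# The multi-stage tissue-preferential selection: quantile normalization,
# replicate averaging, expression filtering, K-means clustering with
# selection of the target-preferential cluster, elimination of genes also
# high in other tissues, and the final fold-change rule against the
# reference tissue.

#' Selection parameters
#'
#' @param expressionThreshold log2 expression cutoff; genes whose maximum
#'   collapsed tissue value is strictly above it survive the filter
#'   (default 8).
#' @param nClusters number of K-means clusters (default 12).
#' @param foldMin minimum linear fold change of target over reference
#'   tissue, inclusive (default 2).
#' @param crossTissueMargin log2 margin by which the target tissue must
#'   exceed the best tissue other than target and reference (default 1).
#' @param kmeansRestarts K-means++ restarts; the best inertia is kept
#'   (default 10).
#' @param normalize quantile-normalize the sample columns first
#'   (default TRUE).
#' @param seed integer seed for the clustering.
#' @return A validated named list of class \code{selection_params}.
#' @export
selectionParams <- function(expressionThreshold = 8, nClusters = 12L,
                            foldMin = 2, crossTissueMargin = 1,
                            kmeansRestarts = 10L, normalize = TRUE,
                            seed = 1L) {
    stopifnot(is.finite(expressionThreshold), nClusters >= 1L,
              foldMin >= 1, kmeansRestarts >= 1L)
    structure(list(expressionThreshold = expressionThreshold,
                   nClusters = as.integer(nClusters), foldMin = foldMin,
                   crossTissueMargin = crossTissueMargin,
                   kmeansRestarts = as.integer(kmeansRestarts),
                   normalize = isTRUE(normalize), seed = as.integer(seed)),
              class = "selection_params")
}

#' Quantile-normalize the sample columns
#'
#' After normalization every sample column carries the identical sorted
#' value vector (the mean of the per-rank values across columns; ties
#' averaged). A single-sample matrix is returned unchanged with a warning.
#'
#' @param x a [TissueExpression-class].
#' @return A [TissueExpression-class] with normalized values.
#' @export
quantileNormalize <- function(x) {
    v <- assay(x, "log2")
    if (ncol(v) < 2L) {
        warning("single sample; quantile normalization skipped")
        return(x)
    }
    n <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(n) <- dimnames(v)
    TissueExpression(n, sampleTissues(x), targetTissue(x),
                     referenceTissue(x))
}

#' Filter genes by expression level
#'
#' Keeps genes whose maximum over the collapsed tissue columns is strictly
#' greater than the threshold, preserving input order.
#'
#' @param x a collapsed [TissueExpression-class] (one column per tissue;
#'   see [collapseReplicates()]).
#' @param threshold log2 cutoff (default 8).
#' @return Character vector of surviving gene ids.
#' @export
filterExpressed <- function(x, threshold = 8) {
    v <- assay(x, "log2")
    rownames(v)[apply(v, 1L, max) > threshold]
}

# K-means++ seeding (Arthur & Vassilvitskii): each new center is drawn with
# probability proportional to the squared distance to the nearest center
# chosen so far.
kmeansPlusPlusInit <- function(X, k) {
    n <- nrow(X)
    centers <- matrix(NA_real_, k, ncol(X))
    centers[1L, ] <- X[sample.int(n, 1L), ]
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (j in seq_len(k - 1L) + 1L) {
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
        d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
    centers
}

#' K-means clustering of expression profiles
#'
#' Lloyd's algorithm over Euclidean distance with K-means++ initialization
#' and multiple restarts; the solution with the lowest total
#' within-cluster sum of squares (inertia) is kept. Deterministic given
#' the seed.
#'
#' @param x a collapsed [TissueExpression-class].
#' @param genes gene ids to cluster (e.g. the [filterExpressed()]
#'   survivors); at least \code{k} genes.
#' @param k number of clusters (default 12).
#' @param restarts number of restarts (default 10).
#' @param seed integer seed.
#' @param iterMax Lloyd iteration cap per restart.
#' @param standardize cluster z-scored gene profiles (row centered and
#'   scaled) instead of raw log2 values, so genes group by expression
#'   pattern rather than overall level. Default FALSE; the full pipeline
#'   turns it on.
#' @return A list with \code{assignment} (named integer, cluster index per
#'   gene, 1-based), \code{centroids} (k x tissues matrix, in the units
#'   that were clustered) and \code{inertia}.
#' @export
clusterExpression <- function(x, genes = rownames(x), k = 12L,
                              restarts = 10L, seed = 1L, iterMax = 100L,
                              standardize = FALSE) {
    X <- assay(x, "log2")[genes, , drop = FALSE]
    if (standardize) {
        mu <- rowMeans(X)
        sd <- apply(X, 1L, stats::sd)
        X <- (X - mu) / ifelse(sd > 0, sd, 1)   # constant rows -> all zeros
    }
    if (nrow(X) < k)
        stop("fewer genes (", nrow(X), ") than clusters (", k, ")")
    best <- NULL
    for (r in seq_len(restarts)) {
        fit <- withSeed(substreamSeed(seed, paste0("kmeans_restart_", r)), {
            init <- kmeansPlusPlusInit(X, k)
            tryCatch(suppressWarnings(
                stats::kmeans(X, centers = init, iter.max = iterMax,
                              algorithm = "Lloyd")),
                error = function(e) NULL)     # e.g. an emptied cluster
        })
        if (is.null(fit)) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss)
            best <- fit
    }
    if (is.null(best))
        stop("k-means failed on every restart")
    list(assignment = stats::setNames(best$cluster, genes),
         centroids = best$centers, inertia = best$tot.withinss)
}

#' Pick the cluster preferential for the target tissue
#'
#' Returns the cluster maximizing the centroid contrast
#' \code{centroid[target] - max(centroid[other tissues])}; ties break to
#' the lowest cluster index.
#'
#' @param clustering result of [clusterExpression()].
#' @param targetTissue tissue label present in the centroid columns.
#' @return Integer cluster index (1-based).
#' @export
selectPreferentialCluster <- function(clustering, targetTissue) {
    ce <- clustering$centroids
    if (!targetTissue %in% colnames(ce))
        stop("target tissue '", targetTissue, "' not among centroid columns")
    others <- ce[, setdiff(colnames(ce), targetTissue), drop = FALSE]
    contrast <- ce[, targetTissue] - apply(others, 1L, max)
    which.max(contrast)   # first maximum = lowest index on ties
}

#' Eliminate genes also highly expressed in other tissues
#'
#' Keeps a gene iff its target-tissue value exceeds the maximum over all
#' tissues other than target and reference by at least \code{margin} log2
#' units.
#'
#' @param genes candidate gene ids.
#' @param x a collapsed [TissueExpression-class].
#' @param margin log2 margin (default 1).
#' @return Character vector of surviving gene ids.
#' @export
dropCrossTissueHigh <- function(genes, x, margin = 1) {
    v <- assay(x, "log2")[genes, , drop = FALSE]
    otherCols <- setdiff(colnames(v), c(targetTissue(x), referenceTissue(x)))
    if (!length(otherCols))
        return(genes)
    best <- apply(v[, otherCols, drop = FALSE], 1L, max)
    genes[v[, targetTissue(x)] - best >= margin]
}

#' Fold-change filter against the reference tissue
#'
#' Keeps a gene iff target minus reference expression is at least
#' \code{log2(foldMin)} - "at least"-fold is inclusive.
#'
#' @param genes candidate gene ids.
#' @param x a collapsed [TissueExpression-class].
#' @param foldMin minimum linear fold (default 2).
#' @return Character vector of surviving gene ids.
#' @export
foldChangeFilter <- function(genes, x, foldMin = 2) {
    v <- assay(x, "log2")[genes, , drop = FALSE]
    genes[v[, targetTissue(x)] - v[, referenceTissue(x)] >= log2(foldMin)]
}

#' Run the full preferential-gene selection
#'
#' Chains (optional) quantile normalization, replicate averaging, the
#' expression filter, K-means clustering with target-cluster selection,
#' the cross-tissue elimination and the fold-change rule, recording which
#' stage removed which gene.
#'
#' @param x a [TissueExpression-class] (replicate-level).
#' @param params a [selectionParams()] list.
#' @return A [SelectionResult-class].
#' @examples
#' sim <- simulateCompendium(300, c("root_hair", "root", "leaf", "stem"),
#'                           replicates = 3, nPreferential = 20, seed = 7)
#' res <- selectPreferential(sim$expr, selectionParams(nClusters = 4))
#' stageSummary(res)
#' @export
selectPreferential <- function(x, params = selectionParams()) {
    stopifnot(inherits(params, "selection_params"))
    if (params$normalize && ncol(x) > 1L)
        x <- quantileNormalize(x)
    coll <- collapseReplicates(x)
    allGenes <- rownames(coll)

    stages <- list(); removed <- list()
    note <- function(name, genesIn, genesOut, reason) {
        stages[[length(stages) + 1L]] <<- data.frame(
            stage = name, n_in = length(genesIn), n_out = length(genesOut))
        gone <- setdiff(genesIn, genesOut)
        removed[[name]] <<- data.frame(gene_id = gone,
                                       reason = rep_len(reason, length(gone)),
                                       stringsAsFactors = FALSE)
        genesOut
    }

    g1 <- note("expression_filter", allGenes,
               filterExpressed(coll, params$expressionThreshold),
               sprintf("max log2 expression <= %g",
                       params$expressionThreshold))
    if (length(g1) < params$nClusters)
        stop("only ", length(g1), " genes pass the expression filter; ",
             "fewer than nClusters = ", params$nClusters)
    cl <- clusterExpression(coll, g1, k = params$nClusters,
                            restarts = params$kmeansRestarts,
                            seed = params$seed, standardize = TRUE)
    target <- selectPreferentialCluster(cl, targetTissue(x))
    g2 <- note("cluster_membership", g1,
               g1[cl$assignment[g1] == target],
               sprintf("outside target-preferential cluster %d", target))
    g3 <- note("cross_tissue", g2,
               dropCrossTissueHigh(g2, coll, params$crossTissueMargin),
               sprintf("within %g log2 of another tissue",
                       params$crossTissueMargin))
    g4 <- note("fold_change", g3,
               foldChangeFilter(g3, coll, params$foldMin),
               sprintf("below %g-fold over reference", params$foldMin))

    new("SelectionResult", selected = g4,
        stages = do.call(rbind, stages), removed = removed,
        params = c(unclass(params), list(targetCluster = unname(target))))
}

#' Write a selection result
#'
#' Writes the selected gene list (one id per line) and a per-stage
#' provenance table.
#'
#' @param x a [SelectionResult-class].
#' @param dir output directory.
#' @return Invisibly, the two file paths.
#' @export
writeSelectionResult <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    genesPath <- file.path(dir, "selected_genes.txt")
    writeLines(selectedGenes(x), genesPath)
    prov <- do.call(rbind, lapply(names(removedGenes(x)), function(s) {
        d <- removedGenes(x)[[s]]
        if (nrow(d)) cbind(stage = s, d) else NULL
    }))
    provPath <- file.path(dir, "selection_provenance.tsv")
    utils::write.table(
        if (is.null(prov)) data.frame(stage = character(),
                                      gene_id = character(),
                                      reason = character()) else prov,
        provPath, sep = "\t", quote = FALSE, row.names = FALSE,
        fileEncoding = "UTF-8")
    invisible(c(genesPath, provPath))
}
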