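# End-to-end orchestration: one structured config drives selection,
# enrichment, motif scanning, network refinement and (optionally)
# conservation, with a manifest of every output file and its content hash.
# Runs are deterministic given the master seed.

pipelineConfigKeys <- c(
    "expression", "tissue_map", "target_tissue", "reference_tissue",
    "annotations", "genome_total_repeats", "promoters", "motif",
    "max_mismatches", "score_fraction", "ppi", "class_map",
    "orthologs", "set2", "out_dir",
    "expression_threshold", "n_clusters", "fold_min",
    "cross_tissue_margin", "kmeans_restarts", "normalize",
    "pcc_threshold", "p_max", "enrich_fold_min", "seed", "truth")

#' Read and validate a pipeline configuration
#'
#' @param config a YAML file path or a named list. Unknown keys are
#'   rejected by name; thresholds are range-checked.
#' @return The validated config list.
#' @export
readPipelineConfig <- function(config) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    unknown <- setdiff(names(config), pipelineConfigKeys)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    need <- c("expression", "tissue_map", "target_tissue",
              "reference_tissue", "out_dir")
    missing <- setdiff(need, names(config))
    if (length(missing))
        stop("missing required config key(s): ",
             paste(missing, collapse = ", "))
    dflt <- list(expression_threshold = 8, n_clusters = 12L, fold_min = 2,
                 cross_tissue_margin = 1, kmeans_restarts = 10L,
                 normalize = TRUE, pcc_threshold = 0.5, p_max = 0.05,
                 enrich_fold_min = 2, max_mismatches = 0L,
                 score_fraction = 0.85, seed = 1L)
    config <- utils::modifyList(dflt, config)
    stopifnot(config$n_clusters >= 1L, config$fold_min >= 1,
              config$p_max >= 0, config$p_max <= 1,
              config$pcc_threshold >= -1, config$pcc_threshold <= 1,
              config$score_fraction > 0, config$score_fraction <= 1)
    config
}

#' Run the full analysis pipeline from a config
#'
#' Executes selection, then - depending on which inputs the config names -
#' term enrichment, promoter motif scanning, network refinement and
#' cross-species conservation. Every output file is listed in
#' \code{manifest.tsv} with its MD5 content hash; a second run with the
#' same config reproduces identical hashes. When the config points at a
#' \code{truth} file from [simulateBundle()], the F1 score of the selected
#' set against the planted genes is recorded in the manifest.
#'
#' @param config a YAML file path or named list, see
#'   [readPipelineConfig()]. All referenced input files must exist before
#'   any stage runs.
#' @return Invisibly, the manifest data.frame (columns \code{file},
#'   \code{md5}, plus attribute \code{notes}).
#' @export
runPipeline <- function(config) {
    cfg <- readPipelineConfig(config)
    inputs <- unlist(cfg[intersect(names(cfg),
                                   c("expression", "tissue_map",
                                     "annotations", "promoters", "motif",
                                     "ppi", "class_map", "orthologs",
                                     "set2", "truth"))])
    inputs <- inputs[is.character(inputs)]
    absent <- inputs[!file.exists(inputs)]
    if (length(absent))
        stop("missing input file(s): ", paste(absent, collapse = ", "))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character()
    notes <- character()

    te <- readExpressionMatrix(cfg$expression, cfg$tissue_map,
                               cfg$target_tissue, cfg$reference_tissue)
    res <- selectPreferential(te, selectionParams(
        expressionThreshold = cfg$expression_threshold,
        nClusters = cfg$n_clusters, foldMin = cfg$fold_min,
        crossTissueMargin = cfg$cross_tissue_margin,
        kmeansRestarts = cfg$kmeans_restarts,
        normalize = cfg$normalize, seed = cfg$seed))
    outputs <- c(outputs, writeSelectionResult(res, cfg$out_dir))
    sel <- selectedGenes(res)
    message("selected ", length(sel), " preferential genes")

    if (!is.null(cfg$truth)) {
        truth <- yaml::read_yaml(cfg$truth)
        planted <- as.character(truth$preferential)
        tp <- length(intersect(sel, planted))
        f1 <- if (length(sel) + length(planted) > 0)
            2 * tp / (length(sel) + length(planted)) else NA_real_
        notes <- c(notes, sprintf("selection_f1_vs_truth\t%.6f", f1))
    }
    if (!is.null(cfg$annotations) && length(sel)) {
        ann <- readAnnotationTable(cfg$annotations,
                                   cfg$genome_total_repeats)
        enr <- enrichSelect(termEnrichment(ann, sel),
                            pMax = cfg$p_max,
                            foldMin = cfg$enrich_fold_min)
        f <- file.path(cfg$out_dir, "enrichment.tsv")
        outputs <- c(outputs, writeEnrichmentTable(enr, f))
    }
    if (!is.null(cfg$promoters) && !is.null(cfg$motif) && length(sel)) {
        prom <- readPromoterFasta(cfg$promoters)
        keep <- intersect(names(prom), sel)
        prom <- PromoterSet(promoterSequences(prom)[keep],
                            promoterWindow(prom))
        motif <- readMotif(cfg$motif, maxMismatches = cfg$max_mismatches,
                           scoreFraction = cfg$score_fraction)
        scan <- scanPromoterSet(prom, motif)
        f <- file.path(cfg$out_dir, "motif_hits.tsv")
        outputs <- c(outputs, writeMotifHits(scan, f))
        notes <- c(notes, sprintf("motif_hits\t%d", scan$summary[["total_hits"]]),
                   sprintf("motif_genes_with_hit\t%d",
                           scan$summary[["genes_with_hit"]]))
    }
    if (!is.null(cfg$ppi) && length(sel)) {
        ppi <- readEdgeList(cfg$ppi)
        classMap <- if (!is.null(cfg$class_map))
            utils::read.table(cfg$class_map, header = TRUE, sep = "\t",
                              colClasses = "character", quote = "")
        else NULL
        net <- refineNetwork(ppi, te, sel,
                             threshold = cfg$pcc_threshold,
                             classMap = classMap)
        outputs <- c(outputs, writeNetwork(net, cfg$out_dir))
        s <- networkSummary(net)
        notes <- c(notes, sprintf("network_edges_retained\t%d",
                                  s[["n_edges"]]))
    }
    if (!is.null(cfg$orthologs) && !is.null(cfg$set2) && length(sel)) {
        orth <- readOrthologPairs(cfg$orthologs)
        set2 <- readLines(cfg$set2)
        cs <- conservationStats(sel, set2, orth)
        f <- file.path(cfg$out_dir, "conservation.tsv")
        outputs <- c(outputs, writeConservationStats(cs, f))
    }

    manifest <- data.frame(file = basename(outputs),
                           md5 = unname(tools::md5sum(outputs)),
                           stringsAsFactors = FALSE)
    mf <- file.path(cfg$out_dir, "manifest.tsv")
    con <- file(mf, open = "wt", encoding = "UTF-8")
    for (n in notes) writeLines(paste0("# ", n), con)
    utils::write.table(manifest, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    attr(manifest, "notes") <- notes
    invisible(manifest)
}
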