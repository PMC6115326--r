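# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of its parameters and seed; randomness is drawn from a
# substream derived from the seed so that adding one generator to a bundle
# never perturbs another (see substreamSeed()).

#' Simulate a multi-tissue expression compendium with planted
#' target-preferential genes
#'
#' The log2 intensity of gene g in tissue t is modeled as
#' \code{level_g + wobble_gt (+ effectLog2 if planted and t is the
#' target)}, with \code{level_g ~ N(baselineMean, geneLevelSd^2)} giving
#' genes a realistic dynamic range and
#' \code{wobble_gt ~ N(0, baselineSd^2)} the tissue-to-tissue fluctuation
#' of a non-preferential gene. A planted gene sits flat at its own
#' baseline \code{level_g} in every tissue and adds \code{effectLog2} in
#' the target tissue only. Every replicate then adds
#' \code{N(0, noiseSd^2)} measurement noise.
#'
#' @param nGenes number of genes.
#' @param tissues character vector of tissue labels; must contain
#'   \code{targetTissue} and \code{referenceTissue}.
#' @param replicates replicate arrays per tissue.
#' @param nPreferential number of planted target-preferential genes.
#' @param effectLog2 planted target-tissue effect in log2 units (>= 0).
#' @param baselineMean mean log2 intensity of an expressed gene.
#' @param baselineSd tissue-to-tissue sd of a non-preferential gene's
#'   mean (log2 units).
#' @param geneLevelSd gene-to-gene sd of overall expression level (log2
#'   units).
#' @param noiseSd replicate-level noise sd (log2 units).
#' @param targetTissue,referenceTissue tissue labels (defaults: first two of
#'   \code{tissues}).
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return A list with elements \code{expr} ([TissueExpression-class]) and
#'   \code{truth} ([SyntheticTruth-class]).
#' @examples
#' sim <- simulateCompendium(200, c("root_hair", "root", "leaf"),
#'                           replicates = 3, nPreferential = 10, seed = 1)
#' sim$expr
#' @export
simulateCompendium <- function(nGenes, tissues, replicates = 3L,
                               nPreferential = 0L, effectLog2 = 2,
                               baselineMean = 10, baselineSd = 0.3,
                               geneLevelSd = 1.5, noiseSd = 0.3,
                               targetTissue = tissues[1L],
                               referenceTissue = tissues[2L],
                               seed = 1L) {
    if (nGenes < 1L || replicates < 1L || length(tissues) < 2L)
        stop("need nGenes >= 1, replicates >= 1 and at least two tissues")
    if (nPreferential > nGenes)
        stop("nPreferential cannot exceed nGenes")
    if (effectLog2 < 0)
        stop("effectLog2 must be >= 0")
    if (!all(c(targetTissue, referenceTissue) %in% tissues))
        stop("target and reference tissue must appear in 'tissues'")
    geneIds <- sprintf("g%0*d", nchar(nGenes), seq_len(nGenes))
    nT <- length(tissues)
    withSeed(substreamSeed(seed, "compendium"), {
        planted <- sort(sample(geneIds, nPreferential))
        level <- stats::rnorm(nGenes, baselineMean, geneLevelSd)
        means <- level + matrix(stats::rnorm(nGenes * nT, 0, baselineSd),
                                nGenes, nT,
                                dimnames = list(geneIds, tissues))
        if (nPreferential > 0L) {
            lv <- level[match(planted, geneIds)]
            means[planted, ] <- lv     # flat profile, recycled by column
            means[planted, targetTissue] <- lv + effectLog2
        }
        sampleTissue <- rep(tissues, each = replicates)
        sampleIds <- paste0(sampleTissue, "_r", rep(seq_len(replicates), nT))
        vals <- means[, sampleTissue, drop = FALSE] +
            matrix(stats::rnorm(nGenes * nT * replicates, 0, noiseSd),
                   nGenes, nT * replicates)
        colnames(vals) <- sampleIds
    })
    expr <- TissueExpression(vals, stats::setNames(sampleTissue, sampleIds),
                             targetTissue, referenceTissue)
    truth <- new("SyntheticTruth", preferential = planted,
                 params = list(compendium = list(
                     nGenes = nGenes, tissues = tissues,
                     replicates = replicates,
                     nPreferential = nPreferential,
                     effectLog2 = effectLog2, baselineMean = baselineMean,
                     baselineSd = baselineSd, geneLevelSd = geneLevelSd,
                     noiseSd = noiseSd,
                     targetTissue = targetTissue,
                     referenceTissue = referenceTissue, seed = seed)))
    list(expr = expr, truth = truth)
}

#' Simulate a gene/term annotation table with one planted enriched term
#'
#' Planted genes carry the planted term with probability
#' \code{enrichmentRate}; all other gene-term assignments occur at
#' \code{backgroundRate}.
#'
#' @param geneIds gene universe.
#' @param truth a [SyntheticTruth-class] (its planted genes receive the
#'   enriched term); updated and returned.
#' @param plantedTerm id of the enriched term.
#' @param nTerms total number of terms (>= 1; the planted term included).
#' @param genomeTotalRepeats population size G; \code{NULL} (default) sets G
#'   to the number of generated pairs, i.e. the table is the whole genome.
#' @param enrichmentRate,backgroundRate probabilities in [0, 1].
#' @param seed integer seed.
#' @return A list with elements \code{annotations}
#'   ([AnnotationRepeats-class]) and \code{truth} (updated).
#' @export
simulateAnnotations <- function(geneIds, truth, plantedTerm = "TERM_planted",
                                nTerms = 50L, genomeTotalRepeats = NULL,
                                enrichmentRate = 0.5, backgroundRate = 0.02,
                                seed = 1L) {
    if (enrichmentRate < 0 || enrichmentRate > 1 ||
        backgroundRate < 0 || backgroundRate > 1)
        stop("rates must lie in [0, 1]")
    if (nTerms < 1L)
        stop("at least one term is required")
    planted <- plantedGenes(truth)
    withSeed(substreamSeed(seed, "annotations"), {
        isPlanted <- geneIds %in% planted
        p <- ifelse(isPlanted, enrichmentRate, backgroundRate)
        keep <- stats::runif(length(geneIds)) < p
        pairs <- data.frame(gene_id = geneIds[keep], term_id = plantedTerm,
                            stringsAsFactors = FALSE)
        if (nTerms > 1L) {
            other <- sprintf("TERM_%03d", seq_len(nTerms - 1L))
            hits <- which(matrix(stats::runif(length(geneIds) *
                                              (nTerms - 1L)) < backgroundRate,
                                 length(geneIds), nTerms - 1L),
                          arr.ind = TRUE)
            pairs <- rbind(pairs, data.frame(
                gene_id = geneIds[hits[, 1L]], term_id = other[hits[, 2L]],
                stringsAsFactors = FALSE))
        }
    })
    if (nrow(pairs) == 0L)
        stop("no annotation pairs were generated; raise the rates")
    pairs$term_label <- pairs$term_id
    ann <- AnnotationRepeats(pairs,
                             genomeTotal = if (is.null(genomeTotalRepeats))
                                 nrow(pairs) else genomeTotalRepeats)
    truth@term <- plantedTerm
    truth@params$annotations <- list(plantedTerm = plantedTerm,
                                     nTerms = nTerms,
                                     enrichmentRate = enrichmentRate,
                                     backgroundRate = backgroundRate,
                                     seed = seed)
    list(annotations = ann, truth = truth)
}

#' Simulate promoters with planted motif occurrences
#'
#' Promoters are i.i.d. uniform A/C/G/T. For each gene in
#' \code{genesWithMotif}, \code{hitsPerGene} exact copies of the motif (a
#' concrete realization of the consensus, forward or reverse complement
#' with equal probability) are planted at non-overlapping positions, which
#' are recorded in the truth object.
#'
#' @param geneIds genes to build promoters for.
#' @param truth a [SyntheticTruth-class]; updated and returned.
#' @param motif a consensus-mode [Motif-class].
#' @param genesWithMotif subset of \code{geneIds} to receive planted sites.
#' @param windowLength promoter length (default 2000 nt).
#' @param hitsPerGene planted occurrences per gene.
#' @param seed integer seed.
#' @return A list with elements \code{promoters} ([PromoterSet-class]) and
#'   \code{truth} (updated).
#' @export
simulatePromoters <- function(geneIds, truth, motif,
                              genesWithMotif = plantedGenes(truth),
                              windowLength = 2000L, hitsPerGene = 1L,
                              seed = 1L) {
    w <- motifLength(motif)
    if (w > windowLength)
        stop("motif longer than the promoter window")
    if (hitsPerGene * w > windowLength)
        stop("cannot place ", hitsPerGene, " non-overlapping copies of a ",
             w, "-nt motif in a ", windowLength, "-nt promoter")
    if (motif@mode != "consensus")
        stop("planting requires a consensus-mode motif")
    allowed <- iupacAllowed(strsplit(motif@consensus, "")[[1L]])
    withSeed(substreamSeed(seed, "promoters"), {
        seqs <- vapply(geneIds, function(g)
            paste(sample(c("A", "C", "G", "T"), windowLength,
                         replace = TRUE), collapse = ""), "")
        positions <- list()
        for (g in intersect(geneIds, genesWithMotif)) {
            placed <- integer()
            tries <- 0L
            while (length(placed) < hitsPerGene) {
                tries <- tries + 1L
                if (tries > 1000L * hitsPerGene)
                    stop("could not place non-overlapping motif copies")
                off <- sample.int(windowLength - w + 1L, 1L) - 1L # 0-based
                if (any(abs(placed - off) < w)) next
                placed <- c(placed, off)
            }
            placed <- sort(placed)
            strands <- sample(c("+", "-"), hitsPerGene, replace = TRUE)
            s <- strsplit(seqs[[g]], "")[[1L]]
            for (i in seq_along(placed)) {
                copy <- vapply(allowed, function(a)
                    a[sample.int(length(a), 1L)], "")
                if (strands[i] == "-")
                    copy <- strsplit(reverseComplementString(
                        paste(copy, collapse = "")), "")[[1L]]
                s[(placed[i] + 1L):(placed[i] + w)] <- copy
            }
            seqs[[g]] <- paste(s, collapse = "")
            positions[[g]] <- data.frame(offset = placed, strand = strands,
                                         stringsAsFactors = FALSE)
        }
    })
    prom <- PromoterSet(seqs, windowLength)
    truth@motifPositions <- positions
    truth@params$promoters <- list(windowLength = windowLength,
                                   hitsPerGene = hitsPerGene,
                                   motif = if (motif@mode == "consensus")
                                       motif@consensus else motif@name,
                                   seed = seed)
    list(promoters = prom, truth = truth)
}

#' Simulate an interaction edge list mixing planted and background edges
#'
#' Planted edges connect pairs of planted preferential genes (whose
#' expression shares the planted target-tissue program, so the pairs are
#' coexpressed); with \code{partnerPool = "all"} the second endpoint is
#' drawn from the full gene universe instead. Background edges are uniform
#' over pairs of non-planted genes. No self-loops, no duplicates.
#'
#' @param geneIds gene universe.
#' @param truth a [SyntheticTruth-class]; updated and returned.
#' @param nEdgesPlanted,nEdgesBackground edge counts.
#' @param partnerPool \code{"preferential"} (default) or \code{"all"}.
#' @param seed integer seed.
#' @return A list with elements \code{ppi} ([InteractionEdges-class]) and
#'   \code{truth} (updated).
#' @export
simulatePPI <- function(geneIds, truth, nEdgesPlanted = 0L,
                        nEdgesBackground = 0L,
                        partnerPool = c("preferential", "all"), seed = 1L) {
    partnerPool <- match.arg(partnerPool)
    planted <- intersect(geneIds, plantedGenes(truth))
    others <- setdiff(geneIds, planted)
    pool <- if (partnerPool == "preferential") planted else geneIds
    maxPlanted <- if (partnerPool == "preferential")
        choose(length(planted), 2L)
    else choose(length(planted), 2L) + length(planted) * length(others)
    if (nEdgesPlanted > maxPlanted)
        stop("requested more planted edges than distinct pairs exist")
    if (nEdgesBackground > choose(length(others), 2L))
        stop("requested more background edges than distinct pairs exist")
    samplePairs <- function(from, to, n, forbid = NULL) {
        out <- character(0)
        tries <- 0L
        while (length(out) < n) {
            tries <- tries + 1L
            if (tries > 200L + 50L * n)
                stop("could not sample the requested number of edges")
            a <- from[sample.int(length(from), 1L)]
            b <- to[sample.int(length(to), 1L)]
            if (a == b) next
            key <- paste(min(a, b), max(a, b), sep = "\r")
            if (key %in% out || key %in% forbid) next
            out <- c(out, key)
        }
        out
    }
    withSeed(substreamSeed(seed, "ppi"), {
        pk <- if (nEdgesPlanted > 0L)
            samplePairs(planted, pool, nEdgesPlanted) else character()
        bk <- if (nEdgesBackground > 0L)
            samplePairs(others, others, nEdgesBackground, forbid = pk)
        else character()
    })
    split2 <- function(keys) {
        if (!length(keys))
            return(data.frame(a = character(), b = character(),
                              stringsAsFactors = FALSE))
        parts <- strsplit(keys, "\r", fixed = TRUE)
        data.frame(a = vapply(parts, `[`, "", 1L),
                   b = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
    }
    pe <- split2(pk); be <- split2(bk)
    ppi <- InteractionEdges(c(pe$a, be$a), c(pe$b, be$b),
                            rep(c("planted", "background"),
                                c(nrow(pe), nrow(be))))
    truth@plantedEdges <- pe
    truth@params$ppi <- list(nEdgesPlanted = nEdgesPlanted,
                             nEdgesBackground = nEdgesBackground,
                             partnerPool = partnerPool, seed = seed)
    list(ppi = ppi, truth = truth)
}

#' Write a complete synthetic input bundle to a directory
#'
#' Runs all four generators off one master seed (via labeled substreams)
#' and writes the five pipeline input files plus a machine-readable truth
#' file (\code{truth.yaml}).
#'
#' @param dir output directory (created if needed).
#' @param nGenes,tissues,replicates,nPreferential,effectLog2,noiseSd
#'   compendium parameters, see [simulateCompendium()].
#' @param motif consensus-mode [Motif-class] planted into promoters.
#' @param nEdgesPlanted,nEdgesBackground interaction edge counts.
#' @param seed master seed.
#' @param ... further arguments passed to [simulateCompendium()].
#' @return Invisibly, a list with the generated objects and the truth.
#' @export
simulateBundle <- function(dir, nGenes = 2000L,
                           tissues = c("root_hair", "root", "leaf", "stem",
                                       "seed", "flower", "anther", "pistil",
                                       "embryo", "callus"),
                           replicates = 3L, nPreferential = 100L,
                           effectLog2 = 2, noiseSd = 0.3,
                           motif = Motif(consensus = "GCACGTACTGCATCGA",
                                         name = "RHE_like"),
                           nEdgesPlanted = 60L, nEdgesBackground = 200L,
                           seed = 1L, ...) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateCompendium(nGenes, tissues, replicates = replicates,
                              nPreferential = nPreferential,
                              effectLog2 = effectLog2, noiseSd = noiseSd,
                              seed = seed, ...)
    geneIds <- rownames(assay(sim$expr, "log2"))
    ann <- simulateAnnotations(geneIds, sim$truth, seed = seed)
    prom <- simulatePromoters(geneIds, ann$truth, motif, seed = seed)
    ppi <- simulatePPI(geneIds, prom$truth, nEdgesPlanted = nEdgesPlanted,
                       nEdgesBackground = nEdgesBackground, seed = seed)
    truth <- ppi$truth
    writeExpressionMatrix(sim$expr, file.path(dir, "expression.tsv"))
    writeAnnotationTable(ann$annotations, file.path(dir, "annotations.tsv"))
    writePromoterFasta(prom$promoters, file.path(dir, "promoters.fasta"))
    writeEdgeList(ppi$ppi, file.path(dir, "ppi.tsv"))
    writeLines(c(paste0(">", motif@name), motif@consensus),
               file.path(dir, "motif.txt"))
    yaml::write_yaml(list(
        preferential = truth@preferential,
        term = truth@term,
        motif_positions = lapply(truth@motifPositions, function(d)
            list(offset = d$offset, strand = d$strand)),
        planted_edges = truth@plantedEdges,
        params = truth@params), file.path(dir, "truth.yaml"))
    invisible(list(expr = sim$expr, annotations = ann$annotations,
                   promoters = prom$promoters, ppi = ppi$ppi,
                   truth = truth))
}
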