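# Config-driven orchestration of the analysis stages, plus a fixture
# writer wrapping the synthetic generators.  Stages communicate only via
# files; identical config + inputs give byte-identical outputs.

.defaultConfig <- function() {
    list(
        genomes = character(),          # FASTA and/or GenBank paths
        alignment = NULL,               # aligned FASTA
        groups = NULL,                  # id -> group TSV
        tribes = NULL,                  # id -> tribe TSV (codon tests)
        tree = NULL,                    # newick (cluster comparison)
        referenceId = NULL,             # projection reference row
        featuresFrom = NULL,            # genome id supplying annotation
        minIR = 1000L,
        windowFine = 100L,              # SNP/indel tracks
        windowWide = 500L,              # pi / diagnostide tracks
        piDeletion = "pairwise",
        testCodons = c("GCC", "GCT", "TTC", "GGT", "GGG", "TAG"),
        outDir = "plastome-out",
        seed = 1L)
}

.loadConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(.defaultConfig(), config)
    stopifnot(cfg$minIR > 0)
    if (cfg$windowFine <= 0 || cfg$windowWide <= 0)
        stop("schema error: window sizes must be positive")
    if (!cfg$piDeletion %in% c("pairwise", "complete"))
        stop("schema error: piDeletion must be pairwise or complete")
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
        stop("schema error: seed must be a single integer")
    cfg
}

.readGroupsTSV <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("id", "group"),
                             colClasses = "character", comment.char = "")
    if (nrow(tab) && identical(tolower(tab$id[1]), "id"))
        tab <- tab[-1, , drop = FALSE]
    stats::setNames(tab$group, tab$id)
}

.stage <- function(name, expr) {
    message(sprintf("[%s] start", name))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
}

#' Run the full comparative-plastome pipeline
#'
#' Executes structure detection, variation tracks, diagnostide analysis
#' and codon-usage analysis on the configured inputs, writing TSV/JSON
#' outputs plus a machine-readable manifest into \code{outDir}.  Any
#' stage failure aborts with the stage name.  Identical config and
#' inputs produce byte-identical outputs.
#'
#' @param config a named list or the path to a YAML file; see
#'   the package vignette for the schema.  Unset fields take the
#'   defaults of the design (windows 100/500 bp, minimum IR 1000 bp,
#'   pairwise deletion, Bonferroni-adjusted Dunn tests).
#' @return invisibly, the list of written file paths.
#' @export
runPipeline <- function(config) {
    cfg <- .loadConfig(config)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    put <- function(fname) {
        written <<- c(written, file.path(cfg$outDir, fname))
        file.path(cfg$outDir, fname)
    }
    genomes <- list()
    for (p in cfg$genomes) {
        gs <- if (grepl("\\.(gb|gbk|genbank)$", p, ignore.case = TRUE))
            readGenBank(p) else readPlastomeFasta(p)
        genomes <- c(genomes, gs)
    }
    names(genomes) <- vapply(genomes, genomeId, character(1))

    # -- structure ---------------------------------------------------
    if (length(genomes)) .stage("structure", {
        parts <- lapply(genomes, findInvertedRepeats, minLen = cfg$minIR)
        ptab <- do.call(rbind, lapply(parts, partitionTable))
        utils::write.table(ptab, put("partition.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jx <- lapply(parts, function(p)
            if (length(features(partitionGenome(p))))
                cbind(genome_id = genomeId(partitionGenome(p)),
                      junctionContext(p)))
        jx <- do.call(rbind, jx)
        if (!is.null(jx))
            utils::write.table(jx, put("junctions.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        inv <- lapply(parts, function(p) {
            gi <- geneInventory(p)
            cbind(genome_id = genomeId(partitionGenome(p)), gi$counts)
        })
        utils::write.table(do.call(rbind, inv), put("inventory.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        parts
    })

    aln <- NULL
    if (!is.null(cfg$alignment)) {
        if (is.null(cfg$groups))
            stop("alignment given without a groups file")
        aln <- readGroupedAlignment(cfg$alignment, cfg$groups)
    }
    refId <- cfg$referenceId
    if (is.null(refId) && !is.null(aln)) refId <- names(alnRows(aln))[1]

    refFeats <- NULL
    featSrc <- if (!is.null(cfg$featuresFrom)) cfg$featuresFrom else refId
    if (!is.null(aln) && !is.null(featSrc) &&
        featSrc %in% names(genomes) &&
        length(features(genomes[[featSrc]])))
        refFeats <- features(genomes[[featSrc]])

    # -- variation ---------------------------------------------------
    if (!is.null(aln)) .stage("variation", {
        snps <- callSNPs(aln)
        utils::write.table(snps, put("snps.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        indels <- callIndels(aln, referenceId = refId)
        utils::write.table(indels, put("indels.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        writeTrack(windowCounts(snps$column, aln,
                                window = cfg$windowFine,
                                statistic = "snp_count",
                                referenceId = refId),
                   put("track_snp.tsv"))
        writeTrack(windowCounts(indels$start, aln,
                                window = cfg$windowFine,
                                statistic = "indel_count",
                                referenceId = refId),
                   put("track_indel.tsv"))
        labels <- groupLabels(aln)
        for (g in unique(labels)) {
            ids <- names(labels)[labels == g]
            if (length(ids) < 2L) next
            tr <- nucleotideDiversity(aln, rows = ids,
                                      window = cfg$windowWide,
                                      deletion = cfg$piDeletion)
            tr@group <- g
            writeTrack(tr, put(sprintf("track_pi_%s.tsv", g)))
        }
        if (!is.null(refFeats)) {
            rp <- regionPercentages(aln, refFeats, referenceId = refId)
            utils::write.table(rp, put("region_stats.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        }
        NULL
    })

    # -- diagnostides ------------------------------------------------
    if (!is.null(aln)) .stage("diagnostides", {
        labels <- groupLabels(aln)
        sets <- lapply(unique(labels), function(g)
            findDiagnostides(aln, g))
        dtab <- do.call(rbind, lapply(sets, function(s) {
            p <- diagnostidePositions(s)
            if (!nrow(p)) return(NULL)
            cbind(group = diagnostideGroup(s), p)
        }))
        if (!is.null(dtab))
            utils::write.table(dtab, put("diagnostides.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
        tracks <- windowDiagnostides(sets, aln,
                                     window = cfg$windowWide,
                                     referenceId = refId)
        for (g in names(tracks))
            writeTrack(tracks[[g]],
                       put(sprintf("track_diagnostides_%s.tsv", g)))
        if (!is.null(refFeats)) {
            rk <- rankBarcodeRegions(sets, aln, refFeats,
                                     referenceId = refId,
                                     window = cfg$windowWide)
            utils::write.table(rk$ranking, put("barcode_ranking.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
            jsonlite::write_json(rk$shared, put("barcode_shared.json"))
        }
        NULL
    })

    # -- codon usage -------------------------------------------------
    annotated <- Filter(function(g)
        any(S4Vectors::mcols(features(g))$type == "CDS"), genomes)
    if (length(annotated) >= 1L) .stage("codon_usage", {
        cm <- t(vapply(annotated, function(g)
            as.integer(codonCounts(g)), integer(64)))
        colnames(cm) <- names(Biostrings::GENETIC_CODE)
        rmat <- rscu(cm)
        utils::write.table(
            data.frame(species = rownames(rmat), rmat,
                       check.names = FALSE),
            put("rscu.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        if (!is.null(cfg$groups)) {
            gm <- .readGroupsTSV(cfg$groups)
            gm <- gm[intersect(names(gm), rownames(cm))]
            if (length(gm) == nrow(cm)) {
                gr <- genusRSCU(cm, gm)
                utils::write.table(
                    data.frame(genus = rownames(gr), gr,
                               check.names = FALSE),
                    put("rscu_genus.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
            }
        }
        if (nrow(rmat) >= 2L) {
            hc <- clusterRSCU(rmat)
            ape::write.tree(ape::as.phylo(hc),
                            put("rscu_dendrogram.nwk"))
            if (!is.null(cfg$tree) && !is.null(cfg$tribes)) {
                tm <- .readGroupsTSV(cfg$tribes)
                rep_ <- compareClustersToClades(hc, cfg$tree, tm)
                jsonlite::write_json(rep_, put("clade_consistency.json"),
                                     auto_unbox = TRUE)
                if (length(tm) && min(table(tm)) >= 2L &&
                    length(unique(tm)) >= 2L) {
                    tst <- tribeCodonTests(rmat, tm,
                                           codons = cfg$testCodons)
                    ttab <- do.call(rbind, lapply(tst, function(x)
                        cbind(codon = x$codon, H = x$H, p = x$p,
                              x$pairs)))
                    utils::write.table(ttab, put("tribe_tests.tsv"),
                                       sep = "\t", quote = FALSE,
                                       row.names = FALSE)
                }
            }
        }
        NULL
    })

    # -- manifest ----------------------------------------------------
    manifest <- list(
        package = "plastomeDiag",
        version = as.character(utils::packageVersion("plastomeDiag")),
        seed = cfg$seed,
        config = cfg[order(names(cfg))],
        outputs = lapply(sort(basename(written)), function(f)
            list(file = f, md5 = unname(tools::md5sum(
                file.path(cfg$outDir, f))))))
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(c(written, file.path(cfg$outDir, "manifest.json")))
}

#' Write a synthetic fixture bundle
#'
#' Generates a plastome, a grouped alignment over a slice of it, and
#' codon-biased coding sets, writing them in the file dialects the
#' pipeline consumes (FASTA, aligned FASTA, TSV group maps) together
#' with the ground truth as JSON.  The resulting directory can be fed
#' straight to \code{\link{runPipeline}}.
#'
#' @param dir output directory.
#' @param seed integer seed (all generators derive from it).
#' @param lscLen,sscLen,irLen plastome region lengths.
#' @param nPerGroup alignment rows per group.
#' @param snpRate,indelRate noise rates for the alignment.
#' @param plantedPerGroup planted diagnostides per group.
#' @return invisibly, a list with the generated objects, the ground
#'   truth, and a ready \code{config} list for \code{runPipeline}.
#' @export
simulateFixtures <- function(dir, seed = 1L, lscLen = 9000L,
                             sscLen = 2200L, irLen = 2600L,
                             nPerGroup = c(gA = 3L, gB = 3L, gC = 2L),
                             snpRate = 0.002, indelRate = 5e-4,
                             plantedPerGroup = 8L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    genome <- simulatePlastome(lscLen = lscLen, sscLen = sscLen,
                               irLen = irLen, seed = seed)
    fastaPath <- file.path(dir, "genome.fasta")
    writePlastomeFasta(genome, fastaPath)
    gbPath <- file.path(dir, "genome.gb")
    writeGenBank(genome, gbPath)

    base <- as.character(genomeSeq(genome))
    L <- nchar(base)
    planted <- list()
    cols <- .withSeed(seed + 1L, sample.int(
        L, plantedPerGroup * length(nPerGroup)))
    baseChars <- strsplit(base, "", fixed = TRUE)[[1]]
    k <- 0L
    states <- .withSeed(seed + 2L, vapply(cols, function(cc)
        sample(setdiff(.BASES, baseChars[cc]), 1L), character(1)))
    for (g in names(nPerGroup)) {
        idx <- (k + 1L):(k + plantedPerGroup)
        planted[[g]] <- data.frame(column = sort(cols[idx]),
                                   state = states[idx][order(cols[idx])])
        k <- k + plantedPerGroup
    }
    sim <- simulateGroupedAlignment(base, nPerGroup, snpRate = snpRate,
                                    indelRate = indelRate,
                                    planted = planted, seed = seed + 3L)
    alnPath <- file.path(dir, "alignment.fasta")
    rows <- alnRows(sim$alignment)
    Biostrings::writeXStringSet(rows, alnPath)
    groupsPath <- file.path(dir, "groups.tsv")
    gl <- groupLabels(sim$alignment)
    utils::write.table(data.frame(id = names(gl), group = unname(gl)),
                       groupsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)

    cds <- simulateCodingSet(seed = seed + 4L)
    cdsPath <- file.path(dir, "cds.fasta")
    set <- Biostrings::DNAStringSet(cds$cds)
    names(set) <- sprintf("%s_gene%d", cds$speciesId,
                          seq_along(cds$cds))
    Biostrings::writeXStringSet(set, cdsPath)

    truth <- list(
        partition = as.list(attr(genome, "truth")$lengths),
        planted = lapply(planted, function(p)
            list(column = p$column, state = p$state)),
        snps = sim$truth$snps,
        gaps = lapply(sim$truth$gaps, function(g)
            list(start = g$start, length = g$length)),
        expectedRSCU = as.list(cds$expectedRSCU))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = FALSE, digits = NA)

    config <- list(genomes = gbPath, alignment = alnPath,
                   groups = groupsPath, seed = seed,
                   referenceId = names(gl)[1],
                   featuresFrom = genomeId(genome),
                   outDir = file.path(dir, "out"))
    invisible(list(genome = genome, alignment = sim$alignment,
                   truth = truth, config = config))
}
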