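# Synthetic plastomes, grouped alignments with planted variation, and
# codon-biased coding sets.  Every generator is a pure function of its
# seed (a private RNG stream; the global RNG is left untouched).

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Background composition: GC 37%, the typical plastome value.
.randomDNA <- function(n, gc = 0.37) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a quadripartite plastome with planted structure
#'
#' Builds \code{LSC + IRB + SSC + reverseComplement(IRB)} from i.i.d.
#' background sequence (GC 37\% by default), places non-overlapping gene
#' annotations in each region and, when \code{junctionGenes = TRUE}, one
#' gene straddling the LSC/IRB and IRB/SSC junctions (mimicking the
#' rps19/ndhF placement of real plastomes).  The two single-copy boundary
#' characters that would let the inverted-repeat pair extend by chance
#' are resampled, so the planted partition is exactly the maximal one.
#'
#' The planted region lengths are attached as
#' \code{attr(, "truth")$lengths} (LSC, IRB, SSC, IRA).
#'
#' @param lscLen,sscLen,irLen region lengths in bp (defaults emulate a
#'   real plastome: 84,976 / 17,127 / 26,254).
#' @param nGenes named integer vector: genes to place in lsc, ssc, ir.
#' @param geneLen mean gene length in bp (exponential-ish jitter).
#' @param gc background GC fraction.
#' @param junctionGenes plant genes straddling JLB and JSB.
#' @param seed integer seed.
#' @return a \linkS4class{PlastomeGenome} with attribute \code{truth}.
#' @export
simulatePlastome <- function(lscLen = 84976L, sscLen = 17127L,
                             irLen = 26254L,
                             nGenes = c(lsc = 8L, ssc = 3L, ir = 3L),
                             geneLen = 900L, gc = 0.37,
                             junctionGenes = TRUE, seed = 1L) {
    stopifnot(lscLen > 0, sscLen > 0, irLen > 0)
    if (lscLen <= sscLen)
        stop("LSC must be longer than SSC")
    .withSeed(seed, {
        lsc <- strsplit(.randomDNA(lscLen, gc), "", fixed = TRUE)[[1]]
        ssc <- strsplit(.randomDNA(sscLen, gc), "", fixed = TRUE)[[1]]
        irb <- strsplit(.randomDNA(irLen, gc), "", fixed = TRUE)[[1]]
        ira <- .reverseComplementChars(irb)
        # block chance IR extension: outward (last LSC char vs
        # complement of first LSC char, across the circular origin) and
        # inward (first SSC char vs complement of last SSC char)
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        while (lsc[lscLen] == comp[[lsc[1]]])
            lsc[lscLen] <- sample(c("A", "C", "G", "T"), 1)
        while (ssc[1] == comp[[ssc[sscLen]]])
            ssc[1] <- sample(c("A", "C", "G", "T"), 1)
        seq <- paste(c(lsc, irb, ssc, ira), collapse = "")
        n <- lscLen + 2L * irLen + sscLen

        regStart <- c(lsc = 1L, irb = lscLen + 1L,
                      ssc = lscLen + irLen + 1L)
        regLen <- c(lsc = lscLen, irb = irLen, ssc = sscLen)
        rows <- list()
        fid <- 0L
        placeGenes <- function(regionKey, k, rows, fid) {
            if (k <= 0) return(list(rows = rows, fid = fid))
            lo <- regStart[[regionKey]]
            hi <- lo + regLen[[regionKey]] - 1L
            # margin so genes stay clear of junctions
            margin <- min(150L, regLen[[regionKey]] %/% 8L)
            lo <- lo + margin; hi <- hi - margin
            avail <- hi - lo + 1L
            lens <- pmax(30L, pmin(round(geneLen * (0.5 + stats::runif(k))),
                                   avail %/% (2L * k)))
            if (sum(lens + 10L) > avail)
                stop("requested genes do not fit region ", regionKey)
            slack <- avail - sum(lens)
            gaps <- sort(sample.int(slack, k))
            starts <- lo + gaps + c(0L, cumsum(lens[-k]))
            for (j in seq_len(k)) {
                fid <- fid + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    start = starts[j], end = starts[j] + lens[j] - 1L,
                    feature_id = fid,
                    name = sprintf("%sGene%d", regionKey, j),
                    type = if (j %% 4L == 0L) "tRNA" else "CDS",
                    strand = if (j %% 2L == 0L) "-" else "+")
            }
            list(rows = rows, fid = fid)
        }
        r <- placeGenes("lsc", nGenes[["lsc"]], rows, fid)
        r <- placeGenes("ssc", nGenes[["ssc"]], r$rows, r$fid)
        r <- placeGenes("irb", nGenes[["ir"]], r$rows, r$fid)
        rows <- r$rows; fid <- r$fid
        # IR genes are duplicated: mirror each IRB gene into IRA (the
        # position x in IRB maps to n + lscLen + 1 - x in IRA), strand
        # flipped, same name
        irbRows <- Filter(function(d) startsWith(d$name, "irb"), rows)
        for (d in irbRows) {
            fid <- fid + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                start = n + lscLen + 1L - d$end,
                end = n + lscLen + 1L - d$start, feature_id = fid,
                name = d$name, type = d$type,
                strand = if (d$strand == "+") "-" else "+")
        }
        if (junctionGenes) {
            # gene straddling JLB (like rps19) and one straddling JSB
            # (like ndhF); sides chosen small enough to stay in-region
            jlb <- lscLen
            lft <- min(120L, lscLen %/% 10L); rgt <- min(60L, irLen %/% 10L)
            fid <- fid + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                start = jlb - lft + 1L, end = jlb + rgt, feature_id = fid,
                name = "jlbGene", type = "CDS", strand = "+")
            jsb <- lscLen + irLen
            lft <- min(60L, irLen %/% 10L); rgt <- min(200L, sscLen %/% 10L)
            fid <- fid + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                start = jsb - lft + 1L, end = jsb + rgt, feature_id = fid,
                name = "jsbGene", type = "CDS", strand = "+")
        }
        tab <- do.call(rbind, rows)
        feats <- .makeFeatures(seqname = sprintf("synthetic_%d", seed),
                               feature_id = tab$feature_id,
                               name = tab$name, type = tab$type,
                               strand = tab$strand, start = tab$start,
                               end = tab$end)
        g <- PlastomeGenome(id = sprintf("synthetic_%d", seed), seq = seq,
                            circular = TRUE, features = feats)
        attr(g, "truth") <- list(
            lengths = c(LSC = lscLen, IRB = irLen, SSC = sscLen,
                        IRA = irLen))
        g
    })
}

#' Simulate a grouped alignment with planted variation
#'
#' Each row is the base sequence with (i) the group-shared planted
#' diagnostic states applied, (ii) private SNPs at \code{snpRate} per
#' site, and (iii) private gap runs at \code{indelRate} events per site
#' (run length 1 + Poisson(\code{indelMeanLen - 1})).  Planted
#' diagnostide columns are kept free of noise in every row, so a planted
#' column is diagnostic by construction.  Rows keep the base length (gap
#' runs overwrite characters), so the object is a valid alignment.
#'
#' @param base character(1) ungapped base sequence.
#' @param nPerGroup named integer vector, rows per group.
#' @param snpRate per-site substitution probability per row.
#' @param indelRate per-site gap-event probability per row.
#' @param indelMeanLen mean gap-run length (>= 1).
#' @param planted named list: for each group, a data.frame with columns
#'   \code{column} (1-based) and \code{state}; states must differ from
#'   the base at that column, and columns must be unique across groups.
#' @param seed integer seed.
#' @return list with \code{alignment} (a
#'   \linkS4class{GroupedAlignment}) and \code{truth}: planted columns
#'   per group, SNP positions per row, gap events per row.
#' @export
simulateGroupedAlignment <- function(base, nPerGroup,
                                     snpRate = 0, indelRate = 0,
                                     indelMeanLen = 3,
                                     planted = list(), seed = 1L) {
    stopifnot(nzchar(base), all(nPerGroup >= 1))
    L <- nchar(base)
    baseChars <- strsplit(toupper(base), "", fixed = TRUE)[[1]]
    allPlanted <- integer()
    for (g in names(planted)) {
        p <- planted[[g]]
        if (any(p$column > L) || any(p$column < 1))
            stop("planted column outside the base sequence")
        if (any(p$state == baseChars[p$column]))
            stop("planted state equals the background state")
        allPlanted <- c(allPlanted, p$column)
    }
    if (anyDuplicated(allPlanted))
        stop("planted columns must be distinct across groups")
    freeSites <- setdiff(seq_len(L), allPlanted)

    .withSeed(seed, {
        rows <- list(); groups <- character(); truth <- list()
        snpTruth <- list(); gapTruth <- list()
        for (g in names(nPerGroup)) {
            for (k in seq_len(nPerGroup[[g]])) {
                id <- sprintf("%s_%d", g, k)
                chars <- baseChars
                if (!is.null(planted[[g]])) {
                    p <- planted[[g]]
                    chars[p$column] <- p$state
                }
                # private SNPs, off the planted columns
                nSnp <- stats::rbinom(1L, length(freeSites), snpRate)
                snpPos <- sort(sample(freeSites, nSnp))
                for (pos in snpPos)
                    chars[pos] <- sample(setdiff(.BASES, chars[pos]), 1L)
                # private gap runs, clipped away from planted columns
                nEv <- stats::rbinom(1L, length(freeSites), indelRate)
                evStart <- sort(sample(freeSites, nEv))
                evLen <- 1L + stats::rpois(nEv, max(0, indelMeanLen - 1))
                keepEv <- logical(nEv)
                if (nEv) for (e in seq_len(nEv)) {
                    span <- evStart[e]:min(L, evStart[e] + evLen[e] - 1L)
                    if (length(intersect(span, allPlanted)) ||
                        any(chars[span] == "-")) next
                    chars[span] <- "-"
                    evLen[e] <- length(span)
                    keepEv[e] <- TRUE
                }
                rows[[id]] <- paste(chars, collapse = "")
                groups[id] <- g
                snpTruth[[id]] <- snpPos
                gapTruth[[id]] <- data.frame(start = evStart[keepEv],
                                             length = evLen[keepEv])
            }
        }
        aln <- GroupedAlignment(unlist(rows), groups)
        list(alignment = aln,
             truth = list(planted = planted, snps = snpTruth,
                          gaps = gapTruth))
    })
}

#' Simulate a codon-biased coding set
#'
#' Draws codons i.i.d. within each synonymous family from the supplied
#' weight vectors (amino acids picked uniformly per codon slot, with the
#' final codon of each gene drawn from the stop family).  The analytic
#' expectation \code{RSCU(codon j of family i) = n_i * w_ij} is returned
#' as ground truth.
#'
#' @param weights named list: per amino-acid letter (plus \code{"*"} for
#'   the stop family), a named numeric vector of codon weights summing
#'   to 1.  Defaults to uniform weights in every family.
#' @param nGenes,nCodonsPerGene size of the coding set.
#' @param speciesId label for the output.
#' @param seed integer seed.
#' @return list with \code{cds} (character vector of CDS sequences),
#'   \code{expectedRSCU} (named numeric over 64 codons) and
#'   \code{speciesId}.
#' @export
simulateCodingSet <- function(weights = NULL, nGenes = 10L,
                              nCodonsPerGene = 200L, speciesId = "sp1",
                              seed = 1L) {
    fam <- codonFamilies()
    if (is.null(weights))
        weights <- lapply(fam, function(cs)
            stats::setNames(rep(1 / length(cs), length(cs)), cs))
    for (aa in names(fam)) {
        w <- weights[[aa]]
        if (is.null(w) || sum(w) <= 0)
            stop("zero-weight or missing codon family: ", aa)
        if (!setequal(names(w), fam[[aa]]))
            stop("weights for family ", aa,
                 " must cover exactly its codons")
        weights[[aa]] <- w / sum(w)
    }
    nonStop <- setdiff(names(fam), "*")
    expected <- stats::setNames(numeric(64), unlist(fam, use.names = FALSE))
    for (aa in names(fam))
        expected[names(weights[[aa]])] <-
            length(fam[[aa]]) * weights[[aa]]
    .withSeed(seed, {
        cds <- vapply(seq_len(nGenes), function(i) {
            aas <- c(sample(nonStop, nCodonsPerGene - 1L, replace = TRUE),
                     "*")
            codons <- vapply(aas, function(aa)
                sample(names(weights[[aa]]), 1L,
                       prob = weights[[aa]]), character(1))
            paste(codons, collapse = "")
        }, character(1))
        list(cds = cds, expectedRSCU = expected, speciesId = speciesId)
    })
}
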