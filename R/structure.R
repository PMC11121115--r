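# Quadripartite structure: inverted-repeat detection, GC content,
# junction-site context and per-region gene inventory.

# Maximal disjoint exact reverse-complement repeat pair on the circle.
# Seed-and-extend: chunks of the reverse complement (length ~min_len/2,
# so any repeat copy >= minLen fully contains one) are matched exactly
# against the tripled forward strand, then hits are extended base-by-base
# in both directions.  Works on the middle copy of tripled strings so
# extension never runs off an end; positions are reduced mod n at the end.
.maximalInvertedRepeat <- function(s, minLen) {
    n <- nchar(s)
    r <- paste(.reverseComplementChars(strsplit(s, "", fixed = TRUE)[[1]]),
               collapse = "")
    s3 <- paste0(s, s, s)
    r3 <- paste0(r, r, r)
    sv <- strsplit(s3, "", fixed = TRUE)[[1]]
    rv <- strsplit(r3, "", fixed = TRUE)[[1]]
    subj <- Biostrings::DNAString(s3)

    w <- max(32L, minLen %/% 2L)
    chunkStarts <- seq.int(n + 1L, 2L * n, by = w)
    chunkStarts <- chunkStarts[chunkStarts + w - 1L <= 2L * n + w]

    seen <- character()
    cands <- list()
    for (p in chunkStarts) {
        pat <- substring(r3, p, p + w - 1L)
        hits <- Biostrings::start(Biostrings::matchPattern(
            Biostrings::DNAString(pat), subj))
        hits <- unique(((hits - 1L) %% n) + n + 1L)
        for (q in hits) {
            # extend left
            maxa <- n - w
            lm <- sv[(q - maxa):(q - 1L)] == rv[(p - maxa):(p - 1L)]
            bad <- which(!rev(lm))
            a <- if (length(bad)) bad[1] - 1L else maxa
            # extend right
            maxb <- n - w
            rm_ <- sv[(q + w):(q + w + maxb - 1L)] ==
                   rv[(p + w):(p + w + maxb - 1L)]
            bad <- which(!rm_)
            b <- if (length(bad)) bad[1] - 1L else maxb
            L <- min(a + w + b, n)
            if (L < minLen) next
            qs <- ((q - a - 1L) %% n) + 1L          # arc 1 start in s
            pr <- ((p - a - 1L) %% n) + 1L          # arc 2 start in r
            # r position u maps to s position n - u + 1; the r-arc
            # [pr, pr+L-1] covers s positions n-pr-L+2 .. n-pr+1
            js <- ((n - pr - L + 1L) %% n) + 1L
            key <- paste(sort(c(qs, js)), collapse = "_")
            key <- paste(key, L, sep = "_")
            if (key %in% seen) next
            seen <- c(seen, key)
            d <- (js - qs) %% n
            disjoint <- qs != js && d >= L && (n - d) >= L
            if (disjoint)
                cands[[length(cands) + 1L]] <-
                    list(a1 = qs, a2 = js, len = L)
        }
    }
    if (!length(cands)) return(NULL)
    lens <- vapply(cands, `[[`, numeric(1), "len")
    best <- cands[lens == max(lens)]
    keys <- vapply(best, function(x)
        paste(sort(c(x$a1, x$a2)), x$len, collapse = "_"), character(1))
    best <- best[!duplicated(keys)]
    if (length(best) > 1L)
        stop("tie: multiple maximal inverted-repeat pairs of length ",
             best[[1]]$len, " bp at starts ",
             paste(vapply(best, function(x)
                 sprintf("(%d,%d)", x$a1, x$a2), character(1)),
                 collapse = ", "))
    best[[1]]
}

#' Detect the quadripartite structure of a plastome
#'
#' Finds the maximal pair of disjoint exact reverse-complement repeats of
#' at least \code{minLen} bp on the circular genome, then rotates the
#' genome (features included) to the canonical linearization
#' LSC, IRB, SSC, IRA, with the longer single-copy region as LSC starting
#' just after IRA.
#'
#' @param genome a \linkS4class{PlastomeGenome} (circular).
#' @param minLen minimum detectable inverted-repeat length in bp
#'   (default 1000, well below real plastome IRs of ~26 kb and above
#'   spurious short repeats).
#' @return a \linkS4class{QuadripartitePartition}.
#' @examples
#' g <- simulatePlastome(lscLen = 4000, sscLen = 1000, irLen = 800,
#'                       seed = 1)
#' regionLengths(findInvertedRepeats(g, minLen = 500))
#' @export
findInvertedRepeats <- function(genome, minLen = 1000L) {
    stopifnot(is(genome, "PlastomeGenome"))
    s <- as.character(genomeSeq(genome))
    n <- nchar(s)
    if (n < 2L * minLen)
        stop("genome shorter than twice the minimum repeat length")
    hit <- .maximalInvertedRepeat(s, as.integer(minLen))
    if (is.null(hit))
        stop(sprintf(
            "no-IR: no inverted repeat of at least %d bp found in '%s' (non-quadripartite genome)",
            minLen, genomeId(genome)))
    a1 <- hit$a1; a2 <- hit$a2; L <- hit$len
    g1 <- (a2 - (a1 + L)) %% n     # gap after arc1 (to arc2 start)
    g2 <- (a1 - (a2 + L)) %% n     # gap after arc2 (to arc1 start)
    if (g1 >= g2) {                # gap1 is LSC: order LSC, arc2(IRB)...
        lscLen <- g1; sscLen <- g2
        rotStart <- ((a1 + L - 1L) %% n) + 1L
    } else {
        lscLen <- g2; sscLen <- g1
        rotStart <- ((a2 + L - 1L) %% n) + 1L
    }
    rotated <- .rotateGenome(genome, rotStart)
    regions <- GenomicRanges::GRanges(
        seqnames = genomeId(genome),
        ranges = IRanges::IRanges(
            start = cumsum(c(1L, lscLen, L, sscLen))[1:4],
            width = c(lscLen, L, sscLen, L)),
        region = c("LSC", "IRB", "SSC", "IRA"))
    part <- new("QuadripartitePartition", genome = rotated,
                regions = regions, irLen = as.integer(L))
    irb <- Biostrings::subseq(genomeSeq(rotated), lscLen + 1L, lscLen + L)
    ira <- Biostrings::subseq(genomeSeq(rotated), n - L + 1L, n)
    stopifnot(as.character(irb) ==
              as.character(Biostrings::reverseComplement(ira)))
    part
}

# Rotate a circular genome so that circular position `rotStart` becomes
# position 1; features wrapping the new origin are split in two rows.
.rotateGenome <- function(genome, rotStart) {
    n <- length(genome)
    s <- as.character(genomeSeq(genome))
    s3 <- paste0(s, s)
    newSeq <- substring(s3, rotStart, rotStart + n - 1L)
    fr <- features(genome)
    if (length(fr)) {
        st <- ((GenomicRanges::start(fr) - rotStart) %% n) + 1L
        en <- ((GenomicRanges::end(fr) - rotStart) %% n) + 1L
        mc <- S4Vectors::mcols(fr)
        strands <- as.character(GenomicRanges::strand(fr))
        rows <- lapply(seq_along(fr), function(i) {
            if (en[i] >= st[i])
                data.frame(start = st[i], end = en[i],
                           feature_id = mc$feature_id[i], name = mc$name[i],
                           type = mc$type[i], strand = strands[i])
            else  # wraps the new origin
                data.frame(start = c(st[i], 1L), end = c(n, en[i]),
                           feature_id = mc$feature_id[i], name = mc$name[i],
                           type = mc$type[i], strand = strands[i])
        })
        tab <- do.call(rbind, rows)
        fr <- .makeFeatures(seqname = genomeId(genome),
                            feature_id = tab$feature_id, name = tab$name,
                            type = tab$type, strand = tab$strand,
                            start = tab$start, end = tab$end)
    }
    PlastomeGenome(id = genomeId(genome), seq = newSeq,
                   circular = isCircular(genome),
                   features = if (length(fr)) fr else NULL)
}

#' GC content of a sequence or genome
#'
#' (G+C)/(A+C+G+T); IUPAC ambiguity characters and gaps are excluded from
#' both numerator and denominator.
#'
#' @param x a \code{DNAString}, character string, or
#'   \code{PlastomeGenome}.
#' @return fraction in [0, 1].
#' @examples gcContent("ATGC")  # 0.5
#' @export
gcContent <- function(x) {
    if (is(x, "PlastomeGenome")) x <- genomeSeq(x)
    if (is.character(x)) x <- Biostrings::DNAString(toupper(x))
    f <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
    denom <- sum(f)
    if (denom == 0)
        stop("undefined GC content: no unambiguous bases in sequence")
    unname((f[["C"]] + f[["G"]]) / denom)
}

#' Junction-site gene context
#'
#' For each of the four junctions (JLB between LSC and IRB, JSB between
#' SSC and IRB, JSA between SSC and IRA, JLA between LSC and IRA), report
#' the nearest feature and its signed distance in bp: 0 when the feature
#' abuts the junction, positive when separated by that many bases, and
#' negative (minus the shorter split) when the feature straddles the
#' junction, in which case the split lengths on either side are reported.
#'
#' @param partition a \linkS4class{QuadripartitePartition}.
#' @param types feature types considered (default CDS and tRNA/rRNA,
#'   matching the genes conventionally drawn at plastome junctions).
#' @return data.frame with one row per junction: \code{junction},
#'   \code{position} (1-based last base before the junction),
#'   \code{feature}, \code{distance}, \code{side_left}, \code{side_right}.
#' @export
junctionContext <- function(partition,
                            types = c("CDS", "tRNA", "rRNA")) {
    stopifnot(is(partition, "QuadripartitePartition"))
    g <- partitionGenome(partition)
    fr <- features(g)
    fr <- fr[S4Vectors::mcols(fr)$type %in% types]
    if (length(fr) == 0L)
        stop("no features of the requested types are annotated")
    n <- length(g)
    rl <- regionLengths(partition)
    bounds <- c(JLB = unname(rl["LSC"]),
                JSB = unname(rl["LSC"] + rl["IRB"]),
                JSA = unname(rl["LSC"] + rl["IRB"] + rl["SSC"]),
                JLA = n)
    mc <- S4Vectors::mcols(fr)
    st <- GenomicRanges::start(fr); en <- GenomicRanges::end(fr)
    ids <- unique(mc$feature_id)
    # each junction separates two adjacent regions; straddling features
    # are split by region membership
    regStart <- stats::setNames(GenomicRanges::start(regions(partition)),
                                c("LSC", "IRB", "SSC", "IRA"))
    regEnd <- stats::setNames(GenomicRanges::end(regions(partition)),
                              c("LSC", "IRB", "SSC", "IRA"))
    sides <- list(JLB = c("LSC", "IRB"), JSB = c("IRB", "SSC"),
                  JSA = c("SSC", "IRA"), JLA = c("IRA", "LSC"))
    regOverlap <- function(i, regionName)
        sum(pmax(0L, pmin(en[i], regEnd[[regionName]]) -
                      pmax(st[i], regStart[[regionName]]) + 1L))

    out <- lapply(names(bounds), function(jn) {
        b <- bounds[[jn]]
        b1 <- (b %% n) + 1L
        res <- lapply(ids, function(fid) {
            i <- which(mc$feature_id == fid)
            coversB <- any(st[i] <= b & en[i] >= b)
            coversB1 <- any(st[i] <= b1 & en[i] >= b1)
            if (coversB && coversB1) {
                left <- regOverlap(i, sides[[jn]][1])
                right <- regOverlap(i, sides[[jn]][2])
                data.frame(feature = mc$name[i][1],
                           distance = -min(left, right),
                           side_left = left, side_right = right)
            } else {
                dLeft <- min((b - en[i]) %% n)    # feature before junction
                dRight <- min((st[i] - b1) %% n)  # feature after junction
                data.frame(feature = mc$name[i][1],
                           distance = min(dLeft, dRight),
                           side_left = NA_integer_, side_right = NA_integer_)
            }
        })
        res <- do.call(rbind, res)
        best <- res[order(res$distance), , drop = FALSE][1, ]
        cbind(data.frame(junction = jn, position = b), best)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Gene inventory per region
#'
#' Counts distinct features per region and class, assigning each feature
#' to the region holding the larger part of it.  A gene is "duplicated"
#' when the same name occurs (as distinct features) in both inverted
#' repeats.
#'
#' @param partition a \linkS4class{QuadripartitePartition} whose genome is
#'   annotated.
#' @return list with \code{counts} (data.frame region x type),
#'   \code{duplicated} (character vector of gene names) and \code{totals}
#'   (named vector over types).
#' @export
geneInventory <- function(partition) {
    stopifnot(is(partition, "QuadripartitePartition"))
    g <- partitionGenome(partition)
    fr <- features(g)
    regionNames <- c("LSC", "IRB", "SSC", "IRA")
    empty <- data.frame(region = regionNames, CDS = 0L, tRNA = 0L,
                        rRNA = 0L)
    if (length(fr) == 0L)
        return(list(counts = empty, duplicated = character(0),
                    totals = c(CDS = 0L, tRNA = 0L, rRNA = 0L)))
    fr <- fr[S4Vectors::mcols(fr)$type %in% c("CDS", "tRNA", "rRNA")]
    mc <- S4Vectors::mcols(fr)
    reg <- regions(partition)
    ov <- GenomicRanges::findOverlaps(fr, reg)
    ovWidth <- GenomicRanges::width(IRanges::pintersect(
        IRanges::ranges(fr)[S4Vectors::queryHits(ov)],
        IRanges::ranges(reg)[S4Vectors::subjectHits(ov)]))
    # region per feature part, then per feature by max covered width
    tab <- data.frame(fid = mc$feature_id[S4Vectors::queryHits(ov)],
                      region = regionNames[S4Vectors::subjectHits(ov)],
                      w = ovWidth)
    agg <- stats::aggregate(w ~ fid + region, tab, sum)
    agg <- agg[order(agg$fid, -agg$w), ]
    agg <- agg[!duplicated(agg$fid), ]
    info <- data.frame(fid = mc$feature_id, name = mc$name,
                       type = mc$type)
    info <- info[!duplicated(info$fid), ]
    info$region <- agg$region[match(info$fid, agg$fid)]
    counts <- empty
    for (r in regionNames) for (tp in c("CDS", "tRNA", "rRNA"))
        counts[counts$region == r, tp] <-
            sum(info$region == r & info$type == tp, na.rm = TRUE)
    dupNames <- intersect(info$name[info$region == "IRA"],
                          info$name[info$region == "IRB"])
    totals <- c(CDS = sum(info$type == "CDS"),
                tRNA = sum(info$type == "tRNA"),
                rRNA = sum(info$type == "rRNA"))
    list(counts = counts, duplicated = sort(dupNames), totals = totals)
}

#' Tabulate a quadripartite partition
#'
#' One row per region with 1-based inclusive coordinates on the canonical
#' linearization, lengths and GC content (fraction).
#'
#' @param partition a \linkS4class{QuadripartitePartition}.
#' @return data.frame: \code{genome_id}, \code{region}, \code{start},
#'   \code{end}, \code{length}, \code{gc}.
#' @export
partitionTable <- function(partition) {
    stopifnot(is(partition, "QuadripartitePartition"))
    g <- partitionGenome(partition)
    reg <- regions(partition)
    gc <- vapply(seq_along(reg), function(i)
        gcContent(Biostrings::subseq(genomeSeq(g),
                                     GenomicRanges::start(reg)[i],
                                     GenomicRanges::end(reg)[i])),
        numeric(1))
    data.frame(genome_id = genomeId(g),
               region = S4Vectors::mcols(reg)$region,
               start = GenomicRanges::start(reg),
               end = GenomicRanges::end(reg),
               length = GenomicRanges::width(reg),
               gc = round(gc, 3))
}
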