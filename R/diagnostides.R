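# Diagnostic nucleotides ("diagnostides"): columns where a focal group
# is fixed for a base that no other row can carry; window tracks and
# barcode-region ranking built on them.

#' Find the diagnostides of one group (one-vs-rest)
#'
#' Column c is a diagnostide for group G with state s iff every member
#' of G carries the same unambiguous base s at c, and no non-G row's
#' state at c can be s: IUPAC ambiguity codes expand to their base sets,
#' so a non-G \code{R} (= A/G) disqualifies s = A.  Gaps within G
#' disqualify the column; gaps in non-G rows do not by themselves
#' (set \code{requireNonGapOutgroup = TRUE} to make them disqualify).
#'
#' @param aln a \linkS4class{GroupedAlignment}.
#' @param group focal group label (must not cover all rows).
#' @param requireNonGapOutgroup logical; if TRUE a gap in any non-G row
#'   disqualifies the column.
#' @return a \linkS4class{DiagnostideSet}.
#' @export
findDiagnostides <- function(aln, group, requireNonGapOutgroup = FALSE) {
    m <- alnMatrix(aln)
    labels <- groupLabels(aln)
    inG <- labels == group
    if (!any(inG)) stop("empty group: ", group)
    if (all(inG)) stop("group covers all rows: no contrast set")
    mG <- m[inG, , drop = FALSE]
    mO <- m[!inG, , drop = FALSE]
    diagState <- rep(NA_character_, ncol(m))
    nonGapOK <- if (requireNonGapOutgroup)
        colSums(mO == "-") == 0L else TRUE
    for (b in .BASES) {
        fixedG <- colSums(mG == b) == nrow(mG)
        # does any outgroup row's IUPAC set contain b?
        containsB <- vapply(names(.iupacSets), function(ch)
            b %in% .iupacSets[[ch]], logical(1))
        outHasB <- colSums(matrix(containsB[mO], nrow = nrow(mO))) > 0L
        hit <- fixedG & !outHasB & nonGapOK
        diagState[hit] <- b
    }
    idx <- which(!is.na(diagState))
    new("DiagnostideSet", group = group,
        positions = data.frame(column = idx, state = diagState[idx]),
        mode = "one-vs-rest", alnWidth = ncol(m))
}

#' Windowed diagnostide counts per group
#'
#' @param sets list of \linkS4class{DiagnostideSet} objects from the
#'   same alignment.
#' @param aln the source \linkS4class{GroupedAlignment}.
#' @param window,step window size and step in bp (default 500 /
#'   non-overlapping, the scan used for plastome divergence profiles).
#' @param referenceId optional row id to project onto reference
#'   coordinates.
#' @return named list of \linkS4class{WindowTrack}s, one per group.
#' @export
windowDiagnostides <- function(sets, aln, window = 500L, step = window,
                               referenceId = NULL) {
    if (is(sets, "DiagnostideSet")) sets <- list(sets)
    widths <- vapply(sets, function(s) s@alnWidth, integer(1))
    if (length(unique(widths)) > 1L || widths[1] != dim(aln)[2])
        stop("diagnostide sets come from alignments of different lengths")
    out <- lapply(sets, function(s)
        windowCounts(diagnostidePositions(s)$column, aln,
                     window = window, step = step,
                     statistic = "diagnostides",
                     referenceId = referenceId,
                     group = diagnostideGroup(s)))
    names(out) <- vapply(sets, diagnostideGroup, character(1))
    out
}

#' Rank annotated regions as barcode candidates
#'
#' Maps each group's diagnostides (projected onto the reference) to the
#' overlapping gene/intron/spacer, ranks regions per group by
#' diagnostide count, and reports the peak window value and,
#' optionally, the peak nucleotide diversity per region.  The
#' \code{shared} element lists regions in the top \code{k} of every
#' group -- candidate markers that delimit all groups at once.
#'
#' @param sets list of \linkS4class{DiagnostideSet}s.
#' @param aln the source \linkS4class{GroupedAlignment}.
#' @param feats \code{GRanges} of features in reference coordinates.
#' @param referenceId reference row id (default: first row).
#' @param piTrack optional \linkS4class{WindowTrack} of pi in the same
#'   reference space.
#' @param window,step window parameters for the per-region peak value.
#' @param k top-k cutoff for the shared list (default 5).
#' @return list with \code{ranking} (data.frame: group, region, class,
#'   n_diagnostides, window_peak, pi_peak) and \code{shared} (character
#'   vector of region names).
#' @export
rankBarcodeRegions <- function(sets, aln, feats, referenceId = NULL,
                               piTrack = NULL, window = 500L,
                               step = window, k = 5L) {
    if (is(sets, "DiagnostideSet")) sets <- list(sets)
    m <- alnMatrix(aln)
    if (is.null(referenceId)) referenceId <- rownames(m)[1]
    map <- .referenceMap(m[referenceId, ])
    refLen <- max(map)
    spacers <- deriveSpacers(feats, refLen)
    regions <- data.frame(
        region = c(S4Vectors::mcols(feats)$name,
                   S4Vectors::mcols(spacers)$name),
        class = ifelse(
            c(S4Vectors::mcols(feats)$type,
              S4Vectors::mcols(spacers)$type) == "spacer", "noncoding",
            ifelse(c(S4Vectors::mcols(feats)$type,
                     S4Vectors::mcols(spacers)$type) == "intron",
                   "intron", "coding")),
        start = c(GenomicRanges::start(feats),
                  GenomicRanges::start(spacers)),
        end = c(GenomicRanges::end(feats), GenomicRanges::end(spacers)))

    assignRegion <- function(pos) {
        hit <- which(regions$start <= pos & regions$end >= pos)
        if (length(hit)) regions$region[hit[1]] else "unassigned"
    }
    tracks <- windowDiagnostides(sets, aln, window = window, step = step,
                                 referenceId = referenceId)
    peakIn <- function(track, st, en) {
        w <- trackWindows(track)
        sel <- w$end > st - 1L & w$start < en      # overlap, BED coords
        if (any(sel)) max(w$value[sel]) else 0
    }
    rank1 <- lapply(sets, function(s) {
        pos <- map[diagnostidePositions(s)$column]
        pos <- pos[pos >= 1L]
        reg <- vapply(pos, assignRegion, character(1))
        cnt <- table(reg)
        if (!length(cnt))
            return(data.frame(group = character(), region = character(),
                              class = character(),
                              n_diagnostides = integer(),
                              window_peak = numeric(),
                              pi_peak = numeric()))
        d <- data.frame(group = diagnostideGroup(s),
                        region = names(cnt),
                        n_diagnostides = as.integer(cnt))
        d$class <- regions$class[match(d$region, regions$region)]
        d$class[is.na(d$class)] <- "unassigned"
        tr <- tracks[[diagnostideGroup(s)]]
        d$window_peak <- vapply(d$region, function(r) {
            i <- match(r, regions$region)
            if (is.na(i)) return(0)
            peakIn(tr, regions$start[i], regions$end[i])
        }, numeric(1))
        d$pi_peak <- if (is.null(piTrack)) NA_real_ else
            vapply(d$region, function(r) {
                i <- match(r, regions$region)
                if (is.na(i)) return(NA_real_)
                peakIn(piTrack, regions$start[i], regions$end[i])
            }, numeric(1))
        d[order(-d$n_diagnostides, d$region),
          c("group", "region", "class", "n_diagnostides", "window_peak",
            "pi_peak")]
    })
    ranking <- do.call(rbind, rank1)
    rownames(ranking) <- NULL
    topk <- lapply(rank1, function(d)
        utils::head(d$region, k))
    shared <- Reduce(intersect, topk)
    list(ranking = ranking, shared = shared)
}
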