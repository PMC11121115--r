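# SNP/indel calling, sliding-window counts, nucleotide diversity and
# per-region variant percentages over a grouped alignment.

.rowSubset <- function(aln, rows = NULL) {
    m <- alnMatrix(aln)
    if (is.null(rows)) return(m)
    missing <- setdiff(rows, rownames(m))
    if (length(missing))
        stop("rows not in the alignment: ", paste(missing, collapse = ", "))
    m[rows, , drop = FALSE]
}

#' Call SNP columns in a grouped alignment
#'
#' A column is a SNP iff at least two distinct unambiguous bases occur
#' among the selected rows; gaps and IUPAC ambiguity codes are not
#' counted as states.
#'
#' @param aln a \linkS4class{GroupedAlignment}.
#' @param rows character vector of row ids to use (default: all rows).
#' @return data.frame with \code{column} (1-based, increasing),
#'   \code{states} (comma-separated observed bases) and \code{n_states}.
#' @export
callSNPs <- function(aln, rows = NULL) {
    m <- .rowSubset(aln, rows)
    if (nrow(m) < 2L) stop("SNP calling needs at least 2 rows")
    present <- vapply(.BASES, function(b) colSums(m == b) > 0,
                      logical(ncol(m)))
    nStates <- rowSums(present)           # present is cols x 4
    idx <- which(nStates >= 2L)
    if (!length(idx))
        return(data.frame(column = integer(), states = character(),
                          n_states = integer()))
    states <- apply(present[idx, , drop = FALSE], 1L, function(p)
        paste(.BASES[p], collapse = ","))
    data.frame(column = idx, states = states,
               n_states = nStates[idx], row.names = NULL)
}

#' Call indel events against a reference row
#'
#' Per non-reference row, every maximal run of columns where exactly one
#' of (row, reference) is gapped is one event; a gap in the row is a
#' deletion, a gap in the reference an insertion.  For track and region
#' statistics, events identical in (start, length, side) across rows are
#' counted once (\code{unique = TRUE}).
#'
#' @param aln a \linkS4class{GroupedAlignment}.
#' @param referenceId row id of the reference (default: first row).
#' @param rows row ids to scan (default: all rows).
#' @param unique collapse events shared by several rows to one.
#' @return data.frame: \code{row}, \code{start} (1-based alignment
#'   column), \code{length}, \code{side} (\code{deletion}/
#'   \code{insertion}).  With \code{unique = TRUE}, \code{row} lists the
#'   carriers comma-separated.
#' @export
callIndels <- function(aln, referenceId = NULL, rows = NULL,
                       unique = TRUE) {
    m <- .rowSubset(aln, rows)
    if (is.null(referenceId)) referenceId <- rownames(alnMatrix(aln))[1]
    if (!referenceId %in% rownames(alnMatrix(aln)))
        stop("reference row absent from alignment: ", referenceId)
    refGap <- alnMatrix(aln)[referenceId, ] == "-"
    out <- list()
    for (id in setdiff(rownames(m), referenceId)) {
        rowGap <- m[id, ] == "-"
        state <- integer(ncol(m))
        state[rowGap & !refGap] <- 1L   # deletion in row
        state[refGap & !rowGap] <- 2L   # insertion relative to reference
        r <- rle(state)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values != 0L
        if (any(keep))
            out[[id]] <- data.frame(
                row = id, start = starts[keep], length = r$lengths[keep],
                side = c("deletion", "insertion")[r$values[keep]])
    }
    ev <- if (length(out)) do.call(rbind, out) else
        data.frame(row = character(), start = integer(),
                   length = integer(), side = character())
    rownames(ev) <- NULL
    if (unique && nrow(ev)) {
        key <- paste(ev$start, ev$length, ev$side)
        carriers <- vapply(split(ev$row, key), paste, character(1),
                           collapse = ",")
        ev <- ev[!duplicated(key), , drop = FALSE]
        ev$row <- unname(carriers[paste(ev$start, ev$length, ev$side)])
        ev <- ev[order(ev$start, ev$length), , drop = FALSE]
        rownames(ev) <- NULL
    }
    ev
}

#' Sliding-window nucleotide diversity
#'
#' Per window, pi is the mean over all row pairs of the pairwise
#' difference proportion, computed with pairwise deletion: for a pair,
#' only columns where both rows carry unambiguous bases are compared.
#' Windows with no comparable sites for any pair get value 0 and are
#' flagged.
#'
#' @param aln a \linkS4class{GroupedAlignment}.
#' @param rows row ids (default: all).
#' @param window window size in bp (default 500, the usual plastome
#'   scan width).
#' @param step step in bp (default: the window size, non-overlapping).
#' @param deletion \code{"pairwise"} (default) or \code{"complete"}
#'   (columns with any gap/ambiguity in the selected rows are dropped
#'   for every pair).
#' @return a \linkS4class{WindowTrack} with statistic \code{"pi"}.
#' @export
nucleotideDiversity <- function(aln, rows = NULL, window = 500L,
                                step = window,
                                deletion = c("pairwise", "complete")) {
    deletion <- match.arg(deletion)
    m <- .rowSubset(aln, rows)
    n <- nrow(m)
    if (n < 2L) stop("nucleotide diversity needs at least 2 rows")
    nc <- ncol(m)
    grid <- .windowGrid(nc, window, step)
    isBase <- m %in% .BASES
    dim(isBase) <- dim(m)
    if (deletion == "complete") {
        colOK <- colSums(isBase) == n
        isBase <- isBase & rep(colOK, each = n)
    }
    pairs <- utils::combn(n, 2L)
    acc <- matrix(0, nrow(grid), ncol(pairs))   # d_ij per window
    comparable <- matrix(FALSE, nrow(grid), ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
        i <- pairs[1L, k]; j <- pairs[2L, k]
        ok <- isBase[i, ] & isBase[j, ]
        df <- ok & (m[i, ] != m[j, ])
        cumOK <- c(0L, cumsum(ok))
        cumDF <- c(0L, cumsum(df))
        nOK <- cumOK[grid$end + 1L] - cumOK[grid$start + 1L]
        nDF <- cumDF[grid$end + 1L] - cumDF[grid$start + 1L]
        comparable[, k] <- nOK > 0L
        acc[, k] <- ifelse(nOK > 0L, nDF / nOK, 0)
    }
    vals <- rowSums(acc) / ncol(pairs)
    flagged <- rowSums(comparable) == 0L
    .newTrack("pi",
              data.frame(start = grid$start, end = grid$end, value = vals,
                         flagged = flagged),
              window, step)
}

#' Windowed counts of SNP columns or indel events
#'
#' Counts, per window, SNP columns (or unique indel event starts)
#' falling in the window, optionally after projecting alignment columns
#' onto the coordinates of a named reference row (columns gapped in the
#' reference collapse onto the preceding reference position).
#'
#' @param positions integer vector of 1-based alignment columns (SNP
#'   columns or indel event starts), sorted.
#' @param aln the source \linkS4class{GroupedAlignment} (needed for the
#'   domain length and for projection).
#' @param window,step window size and step in bp.
#' @param statistic \code{"snp_count"} or \code{"indel_count"}.
#' @param referenceId if non-NULL, project onto this row's ungapped
#'   coordinates.
#' @param group optional group label stored on the track.
#' @return a \linkS4class{WindowTrack}.
#' @export
windowCounts <- function(positions, aln, window = 100L, step = window,
                         statistic = c("snp_count", "indel_count",
                                       "diagnostides"),
                         referenceId = NULL, group = "") {
    statistic <- match.arg(statistic)
    if (step <= 0) stop("window step must be positive")
    nc <- dim(aln)[2]
    space <- "alignment"
    refName <- "alignment"
    if (!is.null(referenceId)) {
        m <- alnMatrix(aln)
        if (!referenceId %in% rownames(m))
            stop("reference row absent: ", referenceId)
        map <- .referenceMap(m[referenceId, ])
        positions <- map[positions]
        positions <- positions[positions >= 1L]
        nc <- max(map)
        space <- "reference"
        refName <- referenceId
    }
    grid <- .windowGrid(nc, window, step)
    counts <- vapply(seq_len(nrow(grid)), function(i)
        sum(positions > grid$start[i] & positions <= grid$end[i]),
        numeric(1))
    .newTrack(statistic,
              data.frame(start = grid$start, end = grid$end,
                         value = counts, flagged = FALSE),
              window, step, refName = refName, group = group,
              space = space)
}

#' Derive intergenic spacers from a feature annotation
#'
#' Inter-feature intervals on the reference coordinate system, named
#' \code{"A--B"} after the flanking features.  Zero-length gaps
#' (abutting or overlapping features) yield no spacer.
#'
#' @param feats a \code{GRanges} of features (as in
#'   \linkS4class{PlastomeGenome}).
#' @param genomeLength reference length in bp.
#' @return a \code{GRanges} of spacers with mcols \code{name},
#'   \code{type = "spacer"}.
#' @export
deriveSpacers <- function(feats, genomeLength) {
    if (length(feats) == 0L) stop("no features to derive spacers from")
    o <- order(GenomicRanges::start(feats))
    st <- GenomicRanges::start(feats)[o]
    en <- GenomicRanges::end(feats)[o]
    nm <- S4Vectors::mcols(feats)$name[o]
    # merge overlapping parts, keeping flank names
    spacers <- list()
    curEnd <- en[1]; curName <- nm[1]
    for (i in seq_along(st)[-1]) {
        if (st[i] > curEnd + 1L)
            spacers[[length(spacers) + 1L]] <- data.frame(
                start = curEnd + 1L, end = st[i] - 1L,
                name = paste0(curName, "--", nm[i]))
        if (en[i] > curEnd) { curEnd <- en[i]; curName <- nm[i] }
    }
    if (curEnd < genomeLength)
        spacers[[length(spacers) + 1L]] <- data.frame(
            start = curEnd + 1L, end = genomeLength,
            name = paste0(curName, "--end"))
    if (st[1] > 1L)
        spacers[[length(spacers) + 1L]] <- data.frame(
            start = 1L, end = st[1] - 1L,
            name = paste0("start--", nm[1]))
    tab <- do.call(rbind, spacers)
    if (is.null(tab))
        return(GenomicRanges::GRanges(feature_id = integer(),
                                      name = character(),
                                      type = character(),
                                      part = integer()))
    tab <- tab[order(tab$start), , drop = FALSE]
    .makeFeatures(seqname = "reference",
                  feature_id = seq_len(nrow(tab)) + 10000L,
                  name = tab$name, type = "spacer", strand = "+",
                  start = tab$start, end = tab$end)
}

#' Per-region SNP and indel percentages
#'
#' Projects SNP columns and unique indel event starts onto the reference
#' row's coordinates and reports, per annotated region (genes, introns
#' and derived spacers), \code{100 * count / region_length}, ranked by
#' descending SNP percentage.
#'
#' @param aln a \linkS4class{GroupedAlignment}.
#' @param feats \code{GRanges} of features in reference coordinates.
#' @param referenceId reference row id (default: first row).
#' @param rows rows used for variant calling (default: all).
#' @return data.frame: \code{region}, \code{class} (coding/noncoding/
#'   intron), \code{length}, \code{n_snp}, \code{snp_pct},
#'   \code{n_indel}, \code{indel_pct}.
#' @export
regionPercentages <- function(aln, feats, referenceId = NULL,
                              rows = NULL) {
    m <- alnMatrix(aln)
    if (is.null(referenceId)) referenceId <- rownames(m)[1]
    map <- .referenceMap(m[referenceId, ])
    refLen <- max(map)

    snps <- callSNPs(aln, rows)
    indels <- callIndels(aln, referenceId = referenceId, rows = rows)
    snpPos <- unique(map[snps$column]); snpPos <- snpPos[snpPos >= 1L]
    indPos <- unique(map[indels$start]); indPos <- indPos[indPos >= 1L]

    spacers <- deriveSpacers(feats, refLen)
    cls <- function(type) ifelse(type == "spacer", "noncoding",
                          ifelse(type == "intron", "intron", "coding"))
    all <- data.frame(
        region = c(S4Vectors::mcols(feats)$name,
                   S4Vectors::mcols(spacers)$name),
        class = cls(c(S4Vectors::mcols(feats)$type,
                      S4Vectors::mcols(spacers)$type)),
        start = c(GenomicRanges::start(feats),
                  GenomicRanges::start(spacers)),
        end = c(GenomicRanges::end(feats), GenomicRanges::end(spacers)))
    # aggregate multi-part features by name
    agg <- lapply(split(all, all$region), function(d) {
        len <- sum(d$end - d$start + 1L)
        if (len <= 0) return(NULL)
        nS <- sum(vapply(snpPos, function(p)
            any(p >= d$start & p <= d$end), logical(1)))
        nI <- sum(vapply(indPos, function(p)
            any(p >= d$start & p <= d$end), logical(1)))
        data.frame(region = d$region[1], class = d$class[1], length = len,
                   n_snp = nS, snp_pct = 100 * nS / len,
                   n_indel = nI, indel_pct = 100 * nI / len)
    })
    out <- do.call(rbind, agg)
    out <- out[order(-out$snp_pct, out$region), , drop = FALSE]
    rownames(out) <- NULL
    out
}
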