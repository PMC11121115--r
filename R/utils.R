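# Shared low-level helpers: alphabets, coordinate conversion, constructors.

# IUPAC base sets; gap and missing map to the empty set so that set
# membership tests ("can this row carry base s?") come out FALSE.
.iupacSets <- local({
    m <- as.list(Biostrings::IUPAC_CODE_MAP)
    m <- lapply(m, function(x) strsplit(x, "", fixed = TRUE)[[1]])
    m[["-"]] <- character()
    m[["."]] <- character()
    m
})

.BASES <- c("A", "C", "G", "T")

.isIupac <- function(chars) chars %in% c(names(.iupacSets))

#' Convert internal (BED-style) to human-facing (GenBank-style) coordinates
#'
#' Window tracks and other BED-like outputs use 0-based half-open
#' coordinates; reports for humans use 1-based inclusive coordinates.  All
#' conversions in the package go through this pair of helpers.
#'
#' @param start0,end0 numeric vectors, 0-based half-open interval(s).
#' @return \code{bedToGenbank}: data.frame with 1-based inclusive
#'   \code{start}, \code{end}.
#' @examples
#' bedToGenbank(0, 10)   # 1..10
#' genbankToBed(1, 10)   # 0, 10
#' @export
bedToGenbank <- function(start0, end0) {
    stopifnot(all(end0 > start0))
    data.frame(start = start0 + 1, end = end0)
}

#' @rdname bedToGenbank
#' @param start1,end1 numeric vectors, 1-based inclusive interval(s).
#' @export
genbankToBed <- function(start1, end1) {
    stopifnot(all(end1 >= start1))
    data.frame(start = start1 - 1, end = end1)
}

# Constructor used throughout: validates and uppercases.
#' Create a PlastomeGenome
#'
#' @param id genome identifier.
#' @param seq character(1) or \code{DNAString}; uppercased on input.
#' @param circular logical(1); plastomes default to circular.
#' @param features a \code{GRanges} with mcols \code{feature_id},
#'   \code{name}, \code{type}, or NULL for no annotation.
#' @return a \linkS4class{PlastomeGenome}.
#' @export
PlastomeGenome <- function(id, seq, circular = TRUE, features = NULL) {
    if (is.character(seq)) {
        seq <- toupper(seq)
        bad <- which(!strsplit(seq, "", fixed = TRUE)[[1]] %in%
                     names(.iupacSets))
        if (length(bad))
            stop(sprintf("non-IUPAC character '%s' at position %d of '%s'",
                 substr(seq, bad[1], bad[1]), bad[1], id))
        seq <- Biostrings::DNAString(seq)
    }
    if (is.null(features))
        features <- GenomicRanges::GRanges(
            seqnames = character(), ranges = IRanges::IRanges(),
            feature_id = integer(), name = character(), type = character(),
            part = integer())
    new("PlastomeGenome", id = id, seq = seq, circular = circular,
        features = features)
}

# Build a feature GRanges from parallel vectors (starts/ends 1-based
# inclusive).  `part` defaults to within-feature order of appearance.
.makeFeatures <- function(seqname, feature_id, name, type, strand,
                          start, end, part = NULL) {
    if (is.null(part))
        part <- stats::ave(seq_along(feature_id), feature_id,
                           FUN = seq_along)
    GenomicRanges::GRanges(
        seqnames = seqname,
        ranges = IRanges::IRanges(start = start, end = end),
        strand = strand,
        feature_id = as.integer(feature_id), name = name, type = type,
        part = as.integer(part))
}

#' Create a GroupedAlignment
#'
#' @param aln named \code{DNAStringSet} (equal widths) or named character
#'   vector of aligned sequences (gaps as \code{"-"}).
#' @param groups named character vector mapping row ids to group labels.
#' @return a \linkS4class{GroupedAlignment}.
#' @export
GroupedAlignment <- function(aln, groups) {
    if (is.character(aln))
        aln <- Biostrings::DNAStringSet(toupper(aln))
    new("GroupedAlignment", aln = aln, groups = groups)
}

# Internal WindowTrack constructor (start/end 0-based half-open).
.newTrack <- function(statistic, windows, window, step, refName = "alignment",
                      group = "", space = "alignment") {
    new("WindowTrack", statistic = statistic, refName = refName,
        group = group, window = as.integer(window), step = as.integer(step),
        space = space, windows = windows)
}

# Window grid over a 1..n coordinate domain: 0-based half-open starts at
# 0, step, 2*step, ... last window may be truncated at n.
.windowGrid <- function(n, window, step) {
    if (step <= 0) stop("window step must be positive")
    if (window < 1) stop("window size must be at least 1")
    starts <- seq.int(0L, max(0L, n - 1L), by = step)
    starts <- starts[starts < n]
    data.frame(start = starts, end = pmin(starts + window, n))
}

# Reference-projection map: alignment column (1-based) -> position on the
# (ungapped) reference row, 1-based; columns gapped in the reference
# collapse onto the preceding reference position (0 before the first).
.referenceMap <- function(refChars) {
    cumsum(refChars != "-")
}

.reverseComplementChars <- function(chars) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-",
              R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
              B = "V", V = "B", D = "H", H = "D")
    rev(unname(comp[chars]))
}
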