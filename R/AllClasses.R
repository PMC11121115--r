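#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
NULL

#' PlastomeGenome: an annotated (usually circular) plastid genome
#'
#' Holds one plastome: an identifier, the sequence as a
#' \link[Biostrings]{DNAString}, a circularity flag, and feature annotations
#' as a \link[GenomicRanges]{GRanges}.  Multi-part features (GenBank
#' \code{join()} locations, or features split because they wrap the circular
#' origin) occupy several rows sharing one \code{feature_id}; metadata
#' columns are \code{feature_id}, \code{name}, \code{type} (one of
#' \code{CDS}, \code{tRNA}, \code{rRNA}, \code{intron}, \code{spacer}) and
#' \code{part} (1-based part index along the feature in transcription
#' order).
#'
#' Coordinates follow the GRanges convention: 1-based, inclusive.
#'
#' @slot id character(1) genome identifier.
#' @slot seq a \code{DNAString}; stored uppercase, IUPAC alphabet.
#' @slot circular logical(1); plastomes default to circular.
#' @slot features a \code{GRanges} of annotations (may be empty).
#'
#' @export
setClass("PlastomeGenome",
    representation(id = "character", seq = "ANY", circular = "logical",
                   features = "ANY"))

setValidity("PlastomeGenome", function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (!is(object@seq, "DNAString"))
        msg <- c(msg, "'seq' must be a DNAString")
    else if (length(object@seq) == 0L)
        msg <- c(msg, "'seq' must be non-empty")
    if (!is(object@features, "GRanges"))
        msg <- c(msg, "'features' must be a GRanges")
    else if (length(object@features) > 0L) {
        need <- c("feature_id", "name", "type")
        if (!all(need %in% colnames(mcols(object@features))))
            msg <- c(msg, sprintf("features need mcols: %s",
                                  paste(need, collapse = ", ")))
        else {
            if (min(start(object@features)) < 1L ||
                max(end(object@features)) > length(object@seq))
                msg <- c(msg, "feature intervals fall outside the sequence")
            bad <- !mcols(object@features)$type %in%
                c("CDS", "tRNA", "rRNA", "intron", "spacer", "gene")
            if (any(bad))
                msg <- c(msg, "unknown feature type(s)")
        }
    }
    if (length(msg)) msg else TRUE
})

#' QuadripartitePartition: LSC/IRB/SSC/IRA intervals of a plastome
#'
#' Result of \code{\link{findInvertedRepeats}}.  The genome inside is the
#' canonically oriented linearization (LSC first, then IRB, SSC, IRA, so
#' LSC starts just after IRA on the circle); \code{regions} tiles it
#' exactly with four ranges named \code{LSC}, \code{IRB}, \code{SSC},
#' \code{IRA}.
#'
#' @slot genome the canonically rotated \linkS4class{PlastomeGenome}.
#' @slot regions a \code{GRanges} with the four region intervals, metadata
#'   column \code{region}.
#' @slot irLen integer(1), length of each inverted repeat copy in bp.
#'
#' @export
setClass("QuadripartitePartition",
    representation(genome = "PlastomeGenome", regions = "ANY",
                   irLen = "integer"))

setValidity("QuadripartitePartition", function(object) {
    msg <- character()
    reg <- object@regions
    if (!is(reg, "GRanges") || length(reg) != 4L)
        return("'regions' must be a GRanges of length 4")
    nm <- mcols(reg)$region
    if (!identical(nm, c("LSC", "IRB", "SSC", "IRA")))
        msg <- c(msg, "regions must be LSC, IRB, SSC, IRA in order")
    n <- length(object@genome@seq)
    if (start(reg)[1] != 1L || end(reg)[4] != n ||
        any(start(reg)[-1] != end(reg)[-4] + 1L))
        msg <- c(msg, "regions must tile the genome exactly")
    if (width(reg)[2] != object@irLen || width(reg)[4] != object@irLen)
        msg <- c(msg, "IR widths must equal irLen")
    if (width(reg)[1] < width(reg)[3])
        msg <- c(msg, "LSC must be at least as long as SSC")
    if (length(msg)) msg else TRUE
})

#' GroupedAlignment: a multiple alignment with per-row group labels
#'
#' The substrate for SNP/indel calling, nucleotide diversity and
#' diagnostide analysis.  Rows are stored as a gap-aware
#' \link[Biostrings]{DNAStringSet} of equal widths; \code{groups} maps each
#' row id to its group label (genus, tribe, ...).
#'
#' @slot aln a \code{DNAStringSet}, all elements of equal width, names are
#'   the row ids.
#' @slot groups named character vector, one label per row id.
#'
#' @export
setClass("GroupedAlignment",
    representation(aln = "ANY", groups = "character"))

setValidity("GroupedAlignment", function(object) {
    msg <- character()
    a <- object@aln
    if (!is(a, "DNAStringSet"))
        return("'aln' must be a DNAStringSet")
    if (length(a) < 2L)
        msg <- c(msg, "an alignment needs at least 2 rows")
    if (length(unique(Biostrings::width(a))) > 1L)
        msg <- c(msg, "all rows must have equal length (ragged alignment)")
    ids <- names(a)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "rows must carry unique ids")
    else {
        miss <- setdiff(ids, names(object@groups))
        if (length(miss))
            msg <- c(msg, paste0("rows without a group label: ",
                                 paste(miss, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' WindowTrack: a per-window statistic along a reference or alignment
#'
#' Windowed values of one statistic (\code{snp_count}, \code{indel_count},
#' \code{pi} or \code{diagnostides}).  Window coordinates are kept in the
#' BED convention (0-based, half-open) so that \code{\link{writeTrack}}
#' round-trips losslessly; \code{space} records whether they index
#' alignment columns or positions on a named reference row.
#'
#' @slot statistic character(1), one of \code{snp_count},
#'   \code{indel_count}, \code{pi}, \code{diagnostides}.
#' @slot refName character(1), reference (or alignment) name the
#'   coordinates refer to.
#' @slot group character(1), group label the track describes ("" if none).
#' @slot window,step integer(1), window size and step in bp.
#' @slot space character(1), \code{"alignment"} or \code{"reference"}.
#' @slot windows data.frame with columns \code{start}, \code{end}
#'   (0-based half-open), \code{value}, and logical \code{flagged} (windows
#'   with no comparable sites).
#'
#' @export
setClass("WindowTrack",
    representation(statistic = "character", refName = "character",
                   group = "character", window = "integer", step = "integer",
                   space = "character", windows = "data.frame"))

setValidity("WindowTrack", function(object) {
    msg <- character()
    if (!object@statistic %in% c("snp_count", "indel_count", "pi",
                                 "diagnostides"))
        msg <- c(msg, "unknown statistic")
    w <- object@windows
    if (!all(c("start", "end", "value", "flagged") %in% names(w)))
        msg <- c(msg, "windows needs columns start, end, value, flagged")
    else if (nrow(w)) {
        if (is.unsorted(w$start))
            msg <- c(msg, "windows must be ordered")
        if (any(w$end - w$start > object@window))
            msg <- c(msg, "window wider than the declared size")
        if (any(w$value < 0, na.rm = TRUE))
            msg <- c(msg, "values must be non-negative")
        if (object@statistic == "pi" && any(w$value > 1, na.rm = TRUE))
            msg <- c(msg, "pi values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' DiagnostideSet: diagnostic nucleotides of one group
#'
#' Columns of a grouped alignment where the focal group is fixed for an
#' unambiguous base that no other row can carry (one-vs-rest contrast).
#'
#' @slot group character(1) focal group label.
#' @slot positions data.frame with columns \code{column} (1-based alignment
#'   column, strictly increasing) and \code{state} (the diagnostic base).
#' @slot mode character(1), currently \code{"one-vs-rest"}.
#' @slot alnWidth integer(1) width of the source alignment.
#'
#' @export
setClass("DiagnostideSet",
    representation(group = "character", positions = "data.frame",
                   mode = "character", alnWidth = "integer"))

setValidity("DiagnostideSet", function(object) {
    p <- object@positions
    if (!all(c("column", "state") %in% names(p)))
        return("positions needs columns 'column' and 'state'")
    if (nrow(p) && any(diff(p$column) <= 0))
        return("columns must be strictly increasing")
    if (nrow(p) && !all(p$state %in% c("A", "C", "G", "T")))
        return("diagnostic states must be unambiguous bases")
    TRUE
})
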