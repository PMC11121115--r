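# Accessors and show methods for the core classes.

#' @rdname PlastomeGenome-class
#' @param object,x a \code{PlastomeGenome}
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname PlastomeGenome-class
#' @export
setMethod("genomeId", "PlastomeGenome", function(x) x@id)

#' @rdname PlastomeGenome-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname PlastomeGenome-class
#' @export
setMethod("genomeSeq", "PlastomeGenome", function(x) x@seq)

#' @rdname PlastomeGenome-class
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname PlastomeGenome-class
#' @export
setMethod("features", "PlastomeGenome", function(x) x@features)

#' @rdname PlastomeGenome-class
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname PlastomeGenome-class
#' @export
setMethod("isCircular", "PlastomeGenome", function(x) x@circular)

setMethod("length", "PlastomeGenome", function(x) length(x@seq))

setMethod("show", "PlastomeGenome", function(object) {
    cat(sprintf("PlastomeGenome '%s': %s bp, %s, %d feature part(s)\n",
        object@id, format(length(object@seq), big.mark = ","),
        if (object@circular) "circular" else "linear",
        length(object@features)))
})

#' @rdname QuadripartitePartition-class
#' @param x,object a \code{QuadripartitePartition}
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname QuadripartitePartition-class
#' @export
setMethod("regions", "QuadripartitePartition", function(x) x@regions)

#' @rdname QuadripartitePartition-class
#' @export
setGeneric("irLength", function(x) standardGeneric("irLength"))
#' @rdname QuadripartitePartition-class
#' @export
setMethod("irLength", "QuadripartitePartition", function(x) x@irLen)

#' Region lengths of a quadripartite partition
#'
#' @param x a \code{QuadripartitePartition}
#' @return named integer vector with elements LSC, IRB, SSC, IRA.
#' @rdname QuadripartitePartition-class
#' @export
setGeneric("regionLengths", function(x) standardGeneric("regionLengths"))
#' @rdname QuadripartitePartition-class
#' @export
setMethod("regionLengths", "QuadripartitePartition", function(x) {
    stats::setNames(GenomicRanges::width(x@regions),
                    S4Vectors::mcols(x@regions)$region)
})

#' @rdname QuadripartitePartition-class
#' @export
setGeneric("partitionGenome", function(x) standardGeneric("partitionGenome"))
#' @rdname QuadripartitePartition-class
#' @export
setMethod("partitionGenome", "QuadripartitePartition", function(x) x@genome)

setMethod("show", "QuadripartitePartition", function(object) {
    rl <- regionLengths(object)
    cat(sprintf(
        "QuadripartitePartition of '%s' (%s bp): LSC %s | IRB %s | SSC %s | IRA %s\n",
        object@genome@id, format(sum(rl), big.mark = ","),
        format(rl[["LSC"]], big.mark = ","), format(rl[["IRB"]], big.mark = ","),
        format(rl[["SSC"]], big.mark = ","), format(rl[["IRA"]], big.mark = ",")))
})

#' @rdname GroupedAlignment-class
#' @param x,object a \code{GroupedAlignment}
#' @export
setGeneric("alnRows", function(x) standardGeneric("alnRows"))
#' @rdname GroupedAlignment-class
#' @export
setMethod("alnRows", "GroupedAlignment", function(x) x@aln)

#' @rdname GroupedAlignment-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname GroupedAlignment-class
#' @export
setMethod("groupLabels", "GroupedAlignment", function(x)
    x@groups[names(x@aln)])

#' Alignment as a character matrix
#'
#' Rows are sequences (rownames = ids), columns are alignment positions
#' (1-based).  Gap is \code{"-"}.
#'
#' @param x a \code{GroupedAlignment}
#' @rdname GroupedAlignment-class
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))
#' @rdname GroupedAlignment-class
#' @export
setMethod("alnMatrix", "GroupedAlignment", function(x) {
    m <- do.call(rbind, strsplit(as.character(x@aln), "", fixed = TRUE))
    rownames(m) <- names(x@aln)
    m
})

setMethod("dim", "GroupedAlignment", function(x)
    c(length(x@aln), if (length(x@aln)) Biostrings::width(x@aln)[1] else 0L))

setMethod("show", "GroupedAlignment", function(object) {
    g <- table(object@groups[names(object@aln)])
    cat(sprintf("GroupedAlignment: %d rows x %d columns; groups: %s\n",
        length(object@aln), Biostrings::width(object@aln)[1],
        paste(sprintf("%s (%d)", names(g), g), collapse = ", ")))
})

#' @rdname WindowTrack-class
#' @param x,object a \code{WindowTrack}
#' @export
setGeneric("trackWindows", function(x) standardGeneric("trackWindows"))
#' @rdname WindowTrack-class
#' @export
setMethod("trackWindows", "WindowTrack", function(x) x@windows)

#' @rdname WindowTrack-class
#' @export
setGeneric("trackStatistic", function(x) standardGeneric("trackStatistic"))
#' @rdname WindowTrack-class
#' @export
setMethod("trackStatistic", "WindowTrack", function(x) x@statistic)

setMethod("length", "WindowTrack", function(x) nrow(x@windows))

setMethod("show", "WindowTrack", function(object) {
    cat(sprintf(
        "WindowTrack '%s'%s on %s (%s space): %d windows of %d bp, step %d; max value %s\n",
        object@statistic,
        if (nzchar(object@group)) sprintf(" [%s]", object@group) else "",
        object@refName, object@space, nrow(object@windows), object@window,
        object@step,
        if (nrow(object@windows)) format(max(object@windows$value)) else "NA"))
})

#' @rdname DiagnostideSet-class
#' @param x,object a \code{DiagnostideSet}
#' @export
setGeneric("diagnostidePositions",
           function(x) standardGeneric("diagnostidePositions"))
#' @rdname DiagnostideSet-class
#' @export
setMethod("diagnostidePositions", "DiagnostideSet", function(x) x@positions)

#' @rdname DiagnostideSet-class
#' @export
setGeneric("diagnostideGroup", function(x) standardGeneric("diagnostideGroup"))
#' @rdname DiagnostideSet-class
#' @export
setMethod("diagnostideGroup", "DiagnostideSet", function(x) x@group)

setMethod("length", "DiagnostideSet", function(x) nrow(x@positions))

setMethod("show", "DiagnostideSet", function(object) {
    cat(sprintf("DiagnostideSet for '%s' (%s): %d diagnostic column(s)\n",
        object@group, object@mode, nrow(object@positions)))
})
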