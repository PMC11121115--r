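# Grouped-alignment input and BED-like track I/O.

#' Read a grouped multiple alignment
#'
#' Reads an aligned FASTA (equal row lengths, gaps as \code{-}) and a
#' two-column tab-separated file mapping sequence id to group label
#' (genus, tribe, ...).  Every row must be labelled.
#'
#' @param fastaPath aligned FASTA path.
#' @param groupsPath two-column TSV path (id, group), no header required;
#'   a header line \code{id<TAB>group} is tolerated.
#' @return a \linkS4class{GroupedAlignment}.
#' @export
readGroupedAlignment <- function(fastaPath, groupsPath) {
    set <- tryCatch(Biostrings::readBStringSet(fastaPath),
        error = function(e) stop("not FASTA-formatted: ", fastaPath))
    if (length(set) < 2L) stop("alignment needs at least 2 sequences")
    ids <- sub("\\s.*$", "", names(set))
    if (anyDuplicated(ids))
        stop("duplicate id(s) in alignment FASTA: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (length(unique(Biostrings::width(set))) > 1L)
        stop("ragged alignment: rows have unequal lengths")

    tab <- utils::read.table(groupsPath, sep = "\t", header = FALSE,
                             col.names = c("id", "group"),
                             colClasses = "character", comment.char = "")
    if (nrow(tab) && identical(tolower(tab$id[1]), "id"))
        tab <- tab[-1, , drop = FALSE]
    groups <- stats::setNames(tab$group, tab$id)

    missing <- setdiff(ids, names(groups))
    if (length(missing))
        stop("sequence(s) missing from the group file: ",
             paste(missing, collapse = ", "))
    seqs <- stats::setNames(toupper(as.character(set)), ids)
    GroupedAlignment(seqs, groups)
}

#' Write a WindowTrack as a BED-like TSV
#'
#' Columns: \code{ref_name}, \code{start}, \code{end} (0-based half-open),
#' \code{statistic}, \code{value}, \code{group}, \code{flagged}.  The file
#' round-trips losslessly through \code{\link{readTrack}}.
#'
#' @param track a \linkS4class{WindowTrack} with at least one window.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTrack <- function(track, path) {
    stopifnot(is(track, "WindowTrack"))
    w <- trackWindows(track)
    if (nrow(w) == 0L) stop("refusing to write an empty track")
    out <- data.frame(ref_name = track@refName, start = w$start, end = w$end,
                      statistic = track@statistic, value = w$value,
                      group = track@group, flagged = w$flagged,
                      window = track@window, step = track@step,
                      space = track@space)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTrack
#' @export
readTrack <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = c(ref_name = "character",
                                            statistic = "character",
                                            group = "character",
                                            space = "character"))
    .newTrack(statistic = tab$statistic[1],
              windows = data.frame(start = tab$start, end = tab$end,
                                   value = tab$value,
                                   flagged = as.logical(tab$flagged)),
              window = tab$window[1], step = tab$step[1],
              refName = tab$ref_name[1], group = tab$group[1],
              space = tab$space[1])
}
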