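# FASTA input/output via Biostrings.

#' Read plastome sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the IUPAC DNA alphabet;
#' entry order is preserved.  Plastomes are assumed circular unless
#' \code{circular = FALSE}.
#'
#' @param path path to a FASTA file.
#' @param circular logical(1), circularity flag stored on each record.
#' @return a list of \linkS4class{PlastomeGenome} objects (no features).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acgt"), tf)
#' readPlastomeFasta(tf)[[1]]
#' @export
readPlastomeFasta <- function(path, circular = TRUE) {
    if (!file.exists(path)) stop("no such file: ", path)
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("not FASTA-formatted: ", path))
    if (length(set) == 0L) stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(set))
    lapply(seq_along(set), function(i) {
        s <- toupper(as.character(set[[i]]))
        chars <- strsplit(s, "", fixed = TRUE)[[1]]
        bad <- which(!.isIupac(chars) | chars %in% c("-", "."))
        if (length(bad))
            stop(sprintf(
                "non-IUPAC character '%s' at position %d of record '%s'",
                chars[bad[1]], bad[1], ids[i]))
        PlastomeGenome(id = ids[i], seq = s, circular = circular)
    })
}

#' Write plastome sequences to FASTA
#'
#' @param genomes a \code{PlastomeGenome} or list of them.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePlastomeFasta <- function(genomes, path) {
    if (is(genomes, "PlastomeGenome")) genomes <- list(genomes)
    set <- Biostrings::DNAStringSet(lapply(genomes, genomeSeq))
    names(set) <- vapply(genomes, genomeId, character(1))
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}
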