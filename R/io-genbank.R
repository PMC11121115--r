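# Minimal GenBank flat-file reader: LOCUS, FEATURES (CDS/tRNA/rRNA with
# join()/complement() locations), ORIGIN.  Gene names are taken from the
# /gene qualifier, falling back to /product.

# Parse one location string into strand + interval table (1-based).
.parseLocation <- function(loc) {
    strand <- if (grepl("complement(", loc, fixed = TRUE)) "-" else "+"
    loc <- gsub("[<>]", "", loc)
    m <- gregexpr("\\d+\\.\\.\\d+|\\d+", loc)[[1]]
    toks <- regmatches(loc, list(m))[[1]]
    if (!length(toks)) stop("unparseable feature location: ", loc)
    parts <- lapply(toks, function(t) {
        ab <- as.integer(strsplit(t, "..", fixed = TRUE)[[1]])
        if (length(ab) == 1L) ab <- c(ab, ab)
        ab
    })
    start <- vapply(parts, `[`, integer(1), 1L)
    end <- vapply(parts, `[`, integer(1), 2L)
    if (any(end < start)) stop("feature end before start in: ", loc)
    # transcription order of parts: as written for +, reversed for -
    part <- if (strand == "+") seq_along(start) else rev(seq_along(start))
    o <- order(start)
    data.frame(start = start[o], end = end[o], part = part[o],
               strand = strand)
}

#' Read annotated plastomes from a GenBank flat file
#'
#' Parses LOCUS/FEATURES/ORIGIN sections of one or more concatenated
#' GenBank records.  CDS, tRNA, rRNA (and intron, where annotated)
#' features are retained; \code{join()} locations become multi-interval
#' features, \code{complement()} sets the minus strand.  GenBank's 1-based
#' inclusive coordinates are kept as-is (the package-wide convention).
#'
#' @param path path to a GenBank flat file.
#' @return a list of \linkS4class{PlastomeGenome} objects.
#' @export
readGenBank <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    starts <- grep("^LOCUS", lines)
    if (!length(starts)) stop("not a GenBank flat file (no LOCUS): ", path)
    ends <- c(starts[-1] - 1L, length(lines))
    lapply(seq_along(starts), function(k)
        .parseGenBankRecord(lines[starts[k]:ends[k]]))
}

.parseGenBankRecord <- function(lines) {
    locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    id <- locus[2]
    circular <- any(grepl("circular", lines[1], ignore.case = TRUE))

    ori <- grep("^ORIGIN", lines)
    if (!length(ori))
        stop(sprintf("record '%s' has no ORIGIN sequence", id))
    endRec <- grep("^//", lines)
    endRec <- if (length(endRec)) endRec[1] else length(lines) + 1L
    seqLines <- lines[(ori[1] + 1L):(endRec - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
    if (!nzchar(seq))
        stop(sprintf("record '%s' has no ORIGIN sequence", id))

    featStart <- grep("^FEATURES", lines)
    featTab <- if (length(featStart))
        lines[(featStart[1] + 1L):(ori[1] - 1L)] else character()

    keep <- c("CDS", "tRNA", "rRNA", "intron")
    feats <- list()
    i <- 1L
    fid <- 0L
    while (i <= length(featTab)) {
        ln <- featTab[i]
        if (grepl("^ {5}\\S", ln)) {
            key <- sub("^ {5}(\\S+).*$", "\\1", ln)
            loc <- trimws(sub("^ {5}\\S+\\s*", "", ln))
            i <- i + 1L
            # location continuation lines (indented, not qualifiers)
            while (i <= length(featTab) &&
                   !grepl("^ {5}\\S", featTab[i]) &&
                   !grepl("^\\s*/", featTab[i]) &&
                   nzchar(trimws(featTab[i]))) {
                loc <- paste0(loc, trimws(featTab[i]))
                i <- i + 1L
            }
            quals <- character()
            while (i <= length(featTab) && !grepl("^ {5}\\S", featTab[i])) {
                quals <- c(quals, trimws(featTab[i]))
                i <- i + 1L
            }
            if (key %in% keep) {
                getQ <- function(q) {
                    hit <- grep(sprintf("^/%s=", q), quals, value = TRUE)
                    if (!length(hit)) return(NA_character_)
                    gsub("^/[a-z_]+=|\"", "", hit[1])
                }
                nm <- getQ("gene")
                if (is.na(nm)) nm <- getQ("product")
                if (is.na(nm)) nm <- sprintf("%s_%d", key, fid + 1L)
                iv <- .parseLocation(loc)
                fid <- fid + 1L
                feats[[length(feats) + 1L]] <- cbind(
                    iv, data.frame(feature_id = fid, name = nm, type = key))
            }
        } else i <- i + 1L
    }

    gr <- if (length(feats)) {
        tab <- do.call(rbind, feats)
        .makeFeatures(seqname = id, feature_id = tab$feature_id,
                      name = tab$name, type = tab$type,
                      strand = tab$strand, start = tab$start, end = tab$end,
                      part = tab$part)
    } else NULL
    PlastomeGenome(id = id, seq = seq, circular = circular, features = gr)
}

#' Write an annotated plastome as a GenBank flat file
#'
#' Emits LOCUS, a FEATURES table (multi-part features as \code{join()},
#' minus strand as \code{complement()}, names as \code{/gene}) and the
#' ORIGIN sequence in standard 60-base lines.  Round-trips through
#' \code{\link{readGenBank}}.
#'
#' @param genome a \linkS4class{PlastomeGenome}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGenBank <- function(genome, path) {
    stopifnot(is(genome, "PlastomeGenome"))
    s <- as.character(genomeSeq(genome))
    n <- nchar(s)
    lines <- c(sprintf("LOCUS       %s%20d bp    DNA     %s PLN",
                       genomeId(genome), n,
                       if (isCircular(genome)) "circular" else "linear"),
               "FEATURES             Location/Qualifiers")
    fr <- features(genome)
    if (length(fr)) {
        mc <- S4Vectors::mcols(fr)
        for (fid in unique(mc$feature_id)) {
            i <- which(mc$feature_id == fid)
            i <- i[order(mc$part[i])]
            parts <- sprintf("%d..%d", GenomicRanges::start(fr)[i],
                             GenomicRanges::end(fr)[i])
            loc <- if (length(parts) > 1L)
                sprintf("join(%s)", paste(parts, collapse = ",")) else
                parts
            if (as.character(GenomicRanges::strand(fr))[i[1]] == "-")
                loc <- sprintf("complement(%s)", loc)
            lines <- c(lines,
                       sprintf("     %-16s%s", mc$type[i[1]], loc),
                       sprintf("                     /gene=\"%s\"",
                               mc$name[i[1]]))
        }
    }
    lines <- c(lines, "ORIGIN")
    starts <- seq(1L, n, by = 60L)
    lines <- c(lines, vapply(starts, function(st) {
        chunk <- substring(s, st, min(st + 59L, n))
        tens <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10),
                               nchar(chunk)))
        sprintf("%9d %s", st, paste(tolower(tens), collapse = " "))
    }, character(1)), "//")
    writeLines(lines, path)
    invisible(path)
}
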