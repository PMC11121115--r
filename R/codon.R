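# Codon counting and relative synonymous codon usage (RSCU).

#' Synonymous codon families of the standard genetic code
#'
#' The three stop codons \{TAA, TAG, TGA\} form a family of their own
#' (letter \code{"*"}), so stop-codon usage gets an RSCU value like any
#' other codon.  DNA alphabet (T, not U).
#'
#' @return named list: per amino-acid letter, the character vector of
#'   its codons.
#' @export
codonFamilies <- function() {
    gc <- Biostrings::GENETIC_CODE
    split(names(gc), unname(gc))
}

#' Count codons in CDS sequences or an annotated genome
#'
#' For a \linkS4class{PlastomeGenome}: per CDS feature, parts are
#' spliced in ascending position, minus-strand features are
#' reverse-complemented, the sequence is trimmed to a multiple of 3 and
#' codons containing ambiguity characters are skipped (their number is
#' reported in \code{attr(, "skipped")}).  Features duplicated in the
#' inverted repeats count once per annotated occurrence unless
#' \code{dedupeByName = TRUE}.
#'
#' @param x a \code{PlastomeGenome} with CDS features, or a character
#'   vector of CDS sequences.
#' @param dedupeByName count only the first feature per gene name.
#' @return named integer vector of length 64 (counts per codon), with
#'   attribute \code{skipped}.
#' @export
codonCounts <- function(x, dedupeByName = FALSE) {
    if (is(x, "PlastomeGenome")) {
        fr <- features(x)
        fr <- fr[S4Vectors::mcols(fr)$type == "CDS"]
        if (length(fr) == 0L) stop("no CDS features annotated")
        mc <- S4Vectors::mcols(fr)
        ids <- unique(mc$feature_id)
        if (dedupeByName) {
            nm <- mc$name[match(ids, mc$feature_id)]
            ids <- ids[!duplicated(nm)]
        }
        seqs <- vapply(ids, function(fid) {
            i <- which(mc$feature_id == fid)
            i <- i[order(GenomicRanges::start(fr)[i])]
            parts <- vapply(i, function(j)
                as.character(Biostrings::subseq(
                    genomeSeq(x), GenomicRanges::start(fr)[j],
                    GenomicRanges::end(fr)[j])), character(1))
            s <- paste(parts, collapse = "")
            if (as.character(GenomicRanges::strand(fr))[i[1]] == "-")
                s <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(s)))
            s
        }, character(1))
        x <- seqs
    }
    codons <- names(Biostrings::GENETIC_CODE)
    counts <- stats::setNames(integer(64), codons)
    skipped <- 0L
    for (s in x) {
        s <- toupper(s)
        L <- (nchar(s) %/% 3L) * 3L
        if (L == 0L) next
        cs <- substring(s, seq(1L, L, 3L), seq(3L, L, 3L))
        ok <- cs %in% codons
        skipped <- skipped + sum(!ok)
        tab <- table(cs[ok])
        counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
    attr(counts, "skipped") <- skipped
    counts
}

#' Relative synonymous codon usage
#'
#' \code{RSCU_ij = X_ij / ((1/n_i) * sum_j X_ij)}: the observed count of
#' codon j of synonymous family i divided by the count expected if all
#' n_i codons of the family were used equally.  Families with zero total
#' count give \code{NA} (undefined), never 0.  Per species and family,
#' the RSCU values sum to n_i whenever the family was observed.
#'
#' @param counts named integer vector of 64 codon counts, or a species x
#'   64 matrix (colnames = codons).
#' @return numeric vector or matrix of the same shape, RSCU values.
#' @examples
#' x <- setNames(integer(64), names(Biostrings::GENETIC_CODE))
#' x[c("GCT", "GCC", "GCA", "GCG")] <- c(2, 1, 1, 0)
#' rscu(x)[c("GCT", "GCC", "GCA", "GCG")]  # 2, 1, 1, 0
#' @export
rscu <- function(counts) {
    if (is.matrix(counts)) {
        out <- t(apply(counts, 1L, rscu))
        colnames(out) <- colnames(counts)
        return(out)
    }
    fams <- codonFamilies()
    out <- stats::setNames(rep(NA_real_, length(counts)), names(counts))
    for (aa in names(fams)) {
        cs <- fams[[aa]]
        tot <- sum(counts[cs])
        out[cs] <- if (tot > 0) counts[cs] / (tot / length(cs)) else
            NA_real_
    }
    out
}

#' Genus-level RSCU (pool counts, then compute)
#'
#' Codon counts are summed within each genus and RSCU is computed from
#' the pooled counts -- not by averaging per-species RSCU values, which
#' is a different (and biased) quantity.
#'
#' @param countsMatrix species x 64 codon count matrix.
#' @param genusMap named character vector mapping species to genus.
#' @return genus x 64 RSCU matrix.
#' @export
genusRSCU <- function(countsMatrix, genusMap) {
    missing <- setdiff(rownames(countsMatrix), names(genusMap))
    if (length(missing))
        stop("species without a genus: ", paste(missing, collapse = ", "))
    g <- genusMap[rownames(countsMatrix)]
    if (any(!table(g) >= 1L)) stop("empty genus")
    pooled <- rowsum(countsMatrix, group = g)
    rscu(as.matrix(pooled))
}
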