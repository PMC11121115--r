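# Tribe-level rank tests on per-codon RSCU values: Kruskal-Wallis across
# tribes, pairwise Dunn post hoc with multiple-comparison adjustment.

#' Pairwise Dunn post hoc test
#'
#' Rank-sum z statistics after a Kruskal-Wallis test: all values are
#' ranked jointly (average ranks for ties) and, for groups i, j,
#' \deqn{z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))}
#' with tie correction \eqn{T = \sum (t^3 - t)} over tied value groups.
#' Two-sided p values from the standard normal, adjusted per
#' \code{method} (Bonferroni by default, conservative and standard).
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @param method p adjustment method (see \code{\link[stats]{p.adjust}}).
#' @return data.frame: \code{group1}, \code{group2}, \code{z}, \code{p},
#'   \code{p_adj}.
#' @export
dunnTest <- function(values, groups, method = "bonferroni") {
    groups <- as.character(groups)
    ok <- !is.na(values)
    values <- values[ok]; groups <- groups[ok]
    N <- length(values)
    r <- rank(values)
    ties <- table(values)
    T <- sum(ties^3 - ties)
    sigma2 <- N * (N + 1) / 12 - T / (12 * (N - 1))
    gl <- sort(unique(groups))
    rbar <- vapply(gl, function(g) mean(r[groups == g]), numeric(1))
    ns <- vapply(gl, function(g) sum(groups == g), numeric(1))
    pairs <- utils::combn(gl, 2L)
    z <- vapply(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1L, k]; j <- pairs[2L, k]
        (rbar[[i]] - rbar[[j]]) /
            sqrt(sigma2 * (1 / ns[[i]] + 1 / ns[[j]]))
    }, numeric(1))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p,
               p_adj = stats::p.adjust(p, method = method))
}

# Tiers: *, **, *** from the adjusted p; the top tier is reserved for
# pairs whose value ranges do not overlap at all (complete separation).
.starTier <- function(pAdj, separated) {
    base <- ifelse(pAdj < 1e-3, "***",
            ifelse(pAdj < 1e-2, "**",
            ifelse(pAdj < 5e-2, "*", "ns")))
    ifelse(separated & pAdj < 5e-2, "****", base)
}

#' Tribe-level rank tests on chosen codons
#'
#' For each codon, tests whether its RSCU values differ between tribes:
#' Kruskal-Wallis H (with tie correction, via
#' \code{\link[stats]{kruskal.test}}) followed by pairwise Dunn z tests
#' with adjustment, and significance tiers from the adjusted p (*
#' <.05, ** <.01, *** <.001, **** <.0001).  If a codon's values are
#' constant across all species, H is undefined and the codon is
#' reported with p = 1 and a flag.
#'
#' @param rscuMatrix species x codon RSCU matrix.
#' @param tribeMap named character vector mapping species to tribe;
#'   needs >= 2 tribes with >= 2 species each.
#' @param codons codons to test (default: the stop codon TAG plus the
#'   alanine/phenylalanine/glycine codons most informative between
#'   Rubiaceae tribes).
#' @param method p adjustment for the Dunn pairs.
#' @return list per codon: \code{H}, \code{p}, \code{flagged}, and
#'   \code{pairs} (data.frame with z, p, p_adj, tier).
#' @export
tribeCodonTests <- function(rscuMatrix, tribeMap,
                            codons = c("GCC", "GCT", "TTC", "GGT",
                                       "GGG", "TAG"),
                            method = "bonferroni") {
    sp <- intersect(rownames(rscuMatrix), names(tribeMap))
    tribes <- tribeMap[sp]
    tt <- table(tribes)
    if (length(tt) < 2L || any(tt < 2L))
        stop("need at least 2 tribes with at least 2 species each")
    out <- lapply(codons, function(cd) {
        if (!cd %in% colnames(rscuMatrix))
            stop("codon not in matrix: ", cd)
        v <- rscuMatrix[sp, cd]
        keep <- !is.na(v)
        if (length(unique(v[keep])) < 2L) {
            pairs <- utils::combn(sort(unique(tribes)), 2L)
            return(list(codon = cd, H = NA_real_, p = 1, flagged = TRUE,
                        pairs = data.frame(group1 = pairs[1L, ],
                                           group2 = pairs[2L, ],
                                           z = 0, p = 1, p_adj = 1,
                                           tier = "ns")))
        }
        kw <- stats::kruskal.test(v[keep], factor(tribes[keep]))
        dn <- dunnTest(v[keep], tribes[keep], method = method)
        sep <- vapply(seq_len(nrow(dn)), function(i) {
            a <- v[keep][tribes[keep] == dn$group1[i]]
            b <- v[keep][tribes[keep] == dn$group2[i]]
            max(a) < min(b) || max(b) < min(a)
        }, logical(1))
        dn$tier <- .starTier(dn$p_adj, sep)
        list(codon = cd, H = unname(kw$statistic), p = kw$p.value,
             flagged = FALSE, pairs = dn)
    })
    names(out) <- codons
    out
}
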