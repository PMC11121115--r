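# RSCU-based hierarchical clustering and dendrogram-vs-phylogeny
# comparison.

#' Cluster species by RSCU profile
#'
#' Euclidean distance between species' 64-codon RSCU vectors, then
#' agglomerative clustering (complete linkage by default, the convention
#' of heatmap tooling; switchable).  Undefined RSCU values (unobserved
#' families) are imputed with 1, the no-preference value, so they carry
#' no signal.  Rows are sorted by species id before clustering, making
#' the leaf order deterministic.
#'
#' @param rscuMatrix species x codon RSCU matrix.
#' @param linkage one of \code{"complete"}, \code{"average"},
#'   \code{"ward.D2"}.
#' @return an \code{hclust} object.
#' @export
clusterRSCU <- function(rscuMatrix, linkage = c("complete", "average",
                                                "ward.D2")) {
    linkage <- match.arg(linkage)
    if (nrow(rscuMatrix) < 2L) stop("clustering needs at least 2 species")
    m <- rscuMatrix[order(rownames(rscuMatrix)), , drop = FALSE]
    m[is.na(m)] <- 1
    stats::hclust(stats::dist(m, method = "euclidean"), method = linkage)
}

# All leaf sets of the internal nodes of an hclust tree.
.hclustClusters <- function(hc) {
    n <- length(hc$labels)
    sets <- vector("list", nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
        kids <- hc$merge[i, ]
        sets[[i]] <- c(
            if (kids[1] < 0) hc$labels[-kids[1]] else sets[[kids[1]]],
            if (kids[2] < 0) hc$labels[-kids[2]] else sets[[kids[2]]])
    }
    c(as.list(hc$labels), sets)
}

# All leaf sets of the clades of an ape phylo tree.
.phyloClades <- function(tree) {
    n <- length(tree$tip.label)
    sets <- lapply(seq_len(n), function(i) tree$tip.label[i])
    internal <- sort(unique(tree$edge[, 1]))
    desc <- function(node) {
        if (node <= n) return(tree$tip.label[node])
        kids <- tree$edge[tree$edge[, 1] == node, 2]
        unlist(lapply(kids, desc))
    }
    c(sets, lapply(internal, desc))
}

.bestSet <- function(sets, target) {
    f1 <- vapply(sets, function(s) {
        tp <- length(intersect(s, target))
        if (tp == 0) return(0)
        prec <- tp / length(s)
        rec <- tp / length(target)
        2 * prec * rec / (prec + rec)
    }, numeric(1))
    sizes <- lengths(sets)
    best <- which(f1 == max(f1))
    best <- best[which.min(sizes[best])]
    sets[[best]]
}

#' Compare RSCU clusters to phylogenetic clades
#'
#' For each tribe, finds the smallest dendrogram cluster and the
#' smallest tree clade maximizing F1 against the tribe's species set,
#' then reports the species whose membership differs: tribe members
#' inside the phylogenetic clade but outside the RSCU cluster ("left the
#' cluster"), and foreign species pulled into the RSCU cluster that the
#' clade does not contain.
#'
#' @param hc an \code{hclust} from \code{\link{clusterRSCU}}.
#' @param tree an \code{ape::phylo} phylogeny (or path to a newick
#'   file).
#' @param tribeMap named character vector mapping species to tribe.
#' @return list per tribe with elements \code{left} and
#'   \code{intruders}; tribes missing from either tree are skipped with
#'   a warning.  Empty when clusters and clades agree.
#' @export
compareClustersToClades <- function(hc, tree, tribeMap) {
    if (is.character(tree)) tree <- ape::read.tree(tree)
    shared <- intersect(hc$labels, tree$tip.label)
    dendSets <- .hclustClusters(hc)
    dendSets <- lapply(dendSets, intersect, shared)
    cladeSets <- .phyloClades(tree)
    cladeSets <- lapply(cladeSets, intersect, shared)
    dendSets <- dendSets[lengths(dendSets) > 0]
    cladeSets <- cladeSets[lengths(cladeSets) > 0]
    out <- list()
    for (tribe in unique(tribeMap)) {
        members <- intersect(names(tribeMap)[tribeMap == tribe], shared)
        if (length(members) < 2L) {
            warning("tribe with fewer than 2 shared species skipped: ",
                    tribe)
            next
        }
        D <- .bestSet(dendSets, members)
        P <- .bestSet(cladeSets, members)
        left <- setdiff(intersect(members, P), D)
        intruders <- setdiff(setdiff(D, members), P)
        if (length(left) || length(intruders))
            out[[tribe]] <- list(left = sort(left),
                                 intruders = sort(intruders))
    }
    out
}
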