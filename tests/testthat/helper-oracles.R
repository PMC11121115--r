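# Independent brute-force oracles and small fixture builders.  These
# deliberately avoid the package's internal algorithms: the IR oracle is
# a diagonal run-length scan, the pi/window oracles recount each window
# by direct subsetting.

revcompChars <- function(chars) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rev(unname(comp[chars]))
}

# Maximal disjoint exact inverted-repeat pair on a circular sequence,
# by scanning every diagonal of (doubled s) x (doubled revcomp) with
# run-length encoding.  O(n^2); for small genomes only.
bruteMaxInvertedRepeat <- function(s, minLen) {
    sv <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(sv)
    rv <- revcompChars(sv)
    sv2 <- c(sv, sv)
    rv2 <- c(rv, rv)
    best <- NULL
    for (off in 0:(2 * n - 1)) {
        # compare sv2[i] with rv2[((i - 1 + off) %% 2n) + 1]
        j <- ((seq_len(2 * n) - 1 + off) %% (2 * n)) + 1
        eq <- sv2 == rv2[j]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        for (k in which(r$values & r$lengths >= minLen)) {
            i0 <- starts[k]
            L <- min(r$lengths[k], n)
            if (i0 > n) next          # same run appears with i0 <= n
            # map to circular arcs
            a1 <- ((i0 - 1) %% n) + 1
            jr <- ((i0 - 1 + off) %% (2 * n)) + 1   # run start in rv2
            pr <- ((jr - 1) %% n) + 1
            a2 <- ((n - pr - L + 1) %% n) + 1
            d <- (a2 - a1) %% n
            if (a1 != a2 && d >= L && (n - d) >= L) {
                if (is.null(best) || L > best$len)
                    best <- list(a1 = a1, a2 = a2, len = L)
            }
        }
    }
    best
}

# Per-window pi by direct recounting (no cumulative sums).
brutePi <- function(m, window, step) {
    n <- nrow(m); nc <- ncol(m)
    starts <- seq(0, nc - 1, by = step)
    starts <- starts[starts < nc]
    pairs <- utils::combn(n, 2)
    vapply(starts, function(s0) {
        cols <- (s0 + 1):min(s0 + window, nc)
        d <- vapply(seq_len(ncol(pairs)), function(k) {
            a <- m[pairs[1, k], cols]; b <- m[pairs[2, k], cols]
            ok <- a %in% c("A", "C", "G", "T") &
                  b %in% c("A", "C", "G", "T")
            if (!sum(ok)) return(0)
            sum(a[ok] != b[ok]) / sum(ok)
        }, numeric(1))
        sum(d) / length(d)
    }, numeric(1))
}

# Per-window position counts by direct recounting.
bruteWindowCounts <- function(positions, domain, window, step) {
    starts <- seq(0, domain - 1, by = step)
    starts <- starts[starts < domain]
    vapply(starts, function(s0)
        sum(positions > s0 & positions <= min(s0 + window, domain)),
        numeric(1))
}

# Column-by-column diagnostide scan (loops, IUPAC expansion by hand).
bruteDiagnostides <- function(m, labels, group) {
    iupac <- c(Biostrings::IUPAC_CODE_MAP, "-" = "")
    inG <- labels == group
    hits <- list()
    for (cc in seq_len(ncol(m))) {
        gs <- unique(m[inG, cc])
        if (length(gs) != 1 || !gs %in% c("A", "C", "G", "T")) next
        outChars <- m[!inG, cc]
        canBe <- vapply(outChars, function(ch)
            grepl(gs, iupac[[ch]], fixed = TRUE), logical(1))
        if (!any(canBe))
            hits[[length(hits) + 1]] <- data.frame(column = cc,
                                                   state = gs)
    }
    if (length(hits)) do.call(rbind, hits) else
        data.frame(column = integer(), state = character())
}

# Build a GroupedAlignment straight from a character matrix.
alnFromMatrix <- function(m, groups) {
    rows <- apply(m, 1, paste, collapse = "")
    if (is.null(names(rows))) names(rows) <- names(groups)
    GroupedAlignment(rows, groups)
}

# Random ape tree whose tips are grouped into clean tribes (each tribe
# a clade), for clade-consistency tests.
randomTribeTree <- function(nTribes = 3, perTribe = 4) {
    subtrees <- lapply(seq_len(nTribes), function(i) {
        t <- ape::rtree(perTribe, tip.label = sprintf(
            "t%d_s%d", i, seq_len(perTribe)))
        t
    })
    tree <- subtrees[[1]]
    for (i in 2:nTribes) tree <- ape::bind.tree(tree, subtrees[[i]],
                                                where = 0)
    tree
}

# Build an hclust whose topology mirrors a given tribe structure by
# placing tribe members at small distances and tribes far apart.
hcFromTribes <- function(tribeMap, graft = NULL) {
    sp <- names(tribeMap)
    tribes <- unique(tribeMap)
    centers <- stats::setNames(seq_along(tribes) * 100, tribes)
    x <- centers[tribeMap] + seq_along(sp) * 0.01
    names(x) <- sp
    if (!is.null(graft))     # move one species into another tribe
        x[graft["species"]] <- centers[graft["tribe"]] + 0.5
    m <- cbind(x, 0)
    rownames(m) <- sp
    stats::hclust(stats::dist(m), method = "complete")
}

treeFromTribes <- function(tribeMap) {
    tribes <- unique(tribeMap)
    sub <- lapply(tribes, function(tr) {
        tips <- names(tribeMap)[tribeMap == tr]
        ape::read.tree(text = paste0("(", paste(tips, collapse = ","),
                                     ");"))
    })
    tree <- sub[[1]]
    for (i in seq_along(sub)[-1])
        tree <- ape::bind.tree(tree, sub[[i]], where = 0)
    tree
}

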