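test_that("the diagnostide predicate handles fixation, sharing, ambiguity and gaps", {
    groups <- c(a1 = "G", a2 = "G", b1 = "O", b2 = "O")
    # column 1: G fixed A, rest C/T -> diagnostide A
    # column 2: G fixed A, shared with one outgroup row -> no
    # column 3: outgroup R (= A/G) contains the focal A -> no
    # column 4: gap inside G -> no
    # column 5: gap in outgroup only -> yes by default
    m <- rbind(a1 = c("A", "A", "A", "-", "T"),
               a2 = c("A", "A", "A", "A", "T"),
               b1 = c("C", "A", "R", "C", "-"),
               b2 = c("T", "C", "C", "C", "G"))
    aln <- alnFromMatrix(m, groups)
    ds <- findDiagnostides(aln, "G")
    expect_equal(diagnostidePositions(ds),
                 data.frame(column = c(1L, 5L), state = c("A", "T")))
    # strict mode: outgroup gaps disqualify
    dsStrict <- findDiagnostides(aln, "G", requireNonGapOutgroup = TRUE)
    expect_equal(diagnostidePositions(dsStrict)$column, 1L)
    expect_error(findDiagnostides(aln, "nope"), "empty group")
    allG <- alnFromMatrix(m[1:2, ], c(a1 = "G", a2 = "G"))
    expect_error(findDiagnostides(allG, "G"), "contrast")
})

test_that("planted diagnostides are recovered exactly, clean and noisy", {
    set.seed(202)
    base <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                  collapse = "")
    baseChars <- strsplit(base, "")[[1]]
    cols <- sort(sample(800, 18))
    states <- vapply(cols, function(cc)
        sample(setdiff(c("A", "C", "G", "T"), baseChars[cc]), 1),
        character(1))
    planted <- list(
        gA = data.frame(column = cols[1:6], state = states[1:6]),
        gB = data.frame(column = cols[7:12], state = states[7:12]),
        gC = data.frame(column = cols[13:18], state = states[13:18]))

    for (snpRate in c(0, 0.01)) {
        sim <- simulateGroupedAlignment(base, c(gA = 3, gB = 3, gC = 2),
                                        snpRate = snpRate,
                                        planted = planted, seed = 31)
        for (g in names(planted)) {
            got <- diagnostidePositions(findDiagnostides(sim$alignment,
                                                         g))
            truth <- planted[[g]]
            # recall is always 1: every planted column is recovered
            expect_true(all(truth$column %in% got$column))
            expect_equal(got$state[match(truth$column, got$column)],
                         truth$state)
            if (snpRate == 0) {
                # and with no noise, precision is 1 as well
                expect_equal(got$column, truth$column)
            } else {
                # extra calls can only come from noise columns, never
                # from other groups' planted columns
                other <- setdiff(cols, truth$column)
                expect_length(intersect(got$column, other), 0)
            }
        }
    }
})

test_that("diagnostides match the brute-force column scan and 2-group symmetry", {
    set.seed(303)
    for (rep in 1:5) {
        base <- paste(sample(c("A", "C", "G", "T"), 300,
                             replace = TRUE), collapse = "")
        sim <- simulateGroupedAlignment(base, c(g1 = 3, g2 = 3),
                                        snpRate = 0.05,
                                        indelRate = 0.01,
                                        seed = 400 + rep)
        m <- alnMatrix(sim$alignment)
        labels <- groupLabels(sim$alignment)
        for (g in c("g1", "g2")) {
            got <- diagnostidePositions(findDiagnostides(sim$alignment,
                                                         g))
            oracle <- bruteDiagnostides(m, labels, g)
            expect_equal(got$column, oracle$column)
            expect_equal(got$state, oracle$state)
        }
        # a column diagnostic for g1 with state s implies s absent
        # from g2 at that column
        d1 <- diagnostidePositions(findDiagnostides(sim$alignment,
                                                    "g1"))
        if (nrow(d1))
            for (i in seq_len(nrow(d1)))
                expect_false(d1$state[i] %in%
                             m[labels == "g2", d1$column[i]])
    }
})

test_that("the diagnostide predicate is monotone in the outgroup", {
    set.seed(404)
    base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
    sim <- simulateGroupedAlignment(base, c(gA = 3, gB = 2, gC = 2),
                                    snpRate = 0.05, seed = 41)
    aln <- sim$alignment
    full <- diagnostidePositions(findDiagnostides(aln, "gA"))$column
    # removing a non-focal row never removes a diagnostide
    ids <- setdiff(names(alnRows(aln)), "gC_2")
    m <- alnMatrix(aln)[ids, ]
    sub <- alnFromMatrix(m, groupLabels(aln)[ids])
    reduced <- diagnostidePositions(findDiagnostides(sub, "gA"))$column
    expect_true(all(full %in% reduced))
    # equivalently: adding a non-focal row never adds one
    expect_true(all(setdiff(reduced, full) %in% reduced))
})

test_that("window tracks of diagnostides sum to the set size", {
    set.seed(505)
    base <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
                  collapse = "")
    baseChars <- strsplit(base, "")[[1]]
    cols <- sort(sample(1200, 15))
    states <- vapply(cols, function(cc)
        sample(setdiff(c("A", "C", "G", "T"), baseChars[cc]), 1),
        character(1))
    sim <- simulateGroupedAlignment(base, c(gA = 2, gB = 2),
        planted = list(gA = data.frame(column = cols, state = states)),
        seed = 51)
    ds <- findDiagnostides(sim$alignment, "gA")
    trs <- windowDiagnostides(ds, sim$alignment, window = 500,
                              step = 500)
    expect_named(trs, "gA")
    expect_equal(sum(trackWindows(trs$gA)$value), length(ds))
    # a single diagnostide at column 700 falls in the second 500 bp
    # window
    one <- new("DiagnostideSet", group = "gA",
               positions = data.frame(column = 700L, state = "A"),
               mode = "one-vs-rest", alnWidth = 1200L)
    tr1 <- windowDiagnostides(one, sim$alignment, window = 500,
                              step = 500)$gA
    expect_equal(trackWindows(tr1)$value, c(0, 1, 0))
})

test_that("barcode ranking finds planted spacer hotspots and shared regions", {
    set.seed(606)
    base <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                  collapse = "")
    baseChars <- strsplit(base, "")[[1]]
    # plant gA and gB diagnostides inside the spacer 401..600
    colsA <- sort(sample(401:500, 6)); colsB <- sort(sample(501:600, 6))
    mkStates <- function(cols) vapply(cols, function(cc)
        sample(setdiff(c("A", "C", "G", "T"), baseChars[cc]), 1),
        character(1))
    sim <- simulateGroupedAlignment(base, c(gA = 2, gB = 2, gC = 2),
        planted = list(
            gA = data.frame(column = colsA, state = mkStates(colsA)),
            gB = data.frame(column = colsB, state = mkStates(colsB))),
        seed = 61)
    feats <- plastomeDiag:::.makeFeatures(
        seqname = "ref", feature_id = 1:2, name = c("trnX", "psbY"),
        type = c("tRNA", "CDS"), strand = "+",
        start = c(101L, 601L), end = c(400L, 900L))
    sets <- lapply(c("gA", "gB"), function(g)
        findDiagnostides(sim$alignment, g))
    rk <- rankBarcodeRegions(sets, sim$alignment, feats,
                             referenceId = "gC_1", window = 200,
                             step = 200)
    topA <- rk$ranking[rk$ranking$group == "gA", ][1, ]
    topB <- rk$ranking[rk$ranking$group == "gB", ][1, ]
    expect_equal(topA$region, "trnX--psbY")
    expect_equal(topB$region, "trnX--psbY")
    expect_equal(topA$n_diagnostides, 6L)
    expect_gte(topA$window_peak, 1)
    expect_true("trnX--psbY" %in% rk$shared)
})
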