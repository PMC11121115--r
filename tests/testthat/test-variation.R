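test_that("SNP columns are polymorphic unambiguous-base columns only", {
    aln <- GroupedAlignment(c(r1 = "ACGT", r2 = "ACGT"),
                            c(r1 = "g", r2 = "g"))
    expect_equal(nrow(callSNPs(aln)), 0)

    aln2 <- GroupedAlignment(c(r1 = "ACGT", r2 = "ACCT"),
                             c(r1 = "g", r2 = "g"))
    s <- callSNPs(aln2)
    expect_equal(s$column, 3L)      # 1-based column
    expect_equal(s$states, "C,G")

    # gaps and ambiguity codes are not states
    aln3 <- GroupedAlignment(c(r1 = "A-RT", r2 = "A-NT", r3 = "A-GT"),
                             c(r1 = "g", r2 = "g", r3 = "h"))
    expect_equal(nrow(callSNPs(aln3)), 0)
})

test_that("planted substitutions are recovered as exactly those SNP columns", {
    set.seed(101)
    base <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                  collapse = "")
    cols <- sort(sample(1000, 17))
    baseChars <- strsplit(base, "")[[1]]
    states <- vapply(cols, function(cc)
        sample(setdiff(c("A", "C", "G", "T"), baseChars[cc]), 1),
        character(1))
    sim <- simulateGroupedAlignment(base, c(gA = 1, gB = 1),
        planted = list(gB = data.frame(column = cols, state = states)),
        seed = 6)
    expect_equal(callSNPs(sim$alignment)$column, cols)
})

test_that("indel events are maximal one-sided gap runs", {
    aln <- GroupedAlignment(
        c(ref = "ACGTACGTAC", r2 = "AC-----TAC", r3 = "ACGTACGTAC"),
        c(ref = "g", r2 = "g", r3 = "g"))
    ev <- callIndels(aln, referenceId = "ref", unique = FALSE)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$start, 3L)
    expect_equal(ev$length, 5L)
    expect_equal(ev$side, "deletion")

    # gap in the reference = insertion in the row
    aln2 <- GroupedAlignment(c(ref = "AC---GT", r2 = "ACTTAGT"),
                             c(ref = "g", r2 = "g"))
    ev2 <- callIndels(aln2, referenceId = "ref")
    expect_equal(ev2$side, "insertion")
    expect_equal(c(ev2$start, ev2$length), c(3L, 3L))

    # both-gap columns belong to no event
    aln3 <- GroupedAlignment(c(ref = "A--GT", r2 = "A--GT"),
                             c(ref = "g", r2 = "g"))
    expect_equal(nrow(callIndels(aln3, referenceId = "ref")), 0)

    expect_error(callIndels(aln, referenceId = "nope"), "absent")
})

test_that("events shared by several rows collapse to unique events", {
    aln <- GroupedAlignment(
        c(ref = "ACGTACGTAC", r2 = "AC--ACGTAC", r3 = "AC--ACGTAC",
          r4 = "ACGTAC--AC"),
        c(ref = "g", r2 = "g", r3 = "g", r4 = "h"))
    evAll <- callIndels(aln, referenceId = "ref", unique = FALSE)
    expect_equal(nrow(evAll), 3)
    ev <- callIndels(aln, referenceId = "ref", unique = TRUE)
    expect_equal(nrow(ev), 2)
    expect_equal(ev$row[ev$start == 3], "r2,r3")
})

test_that("planted gap events are recovered with exact coordinates", {
    set.seed(55)
    base <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                  collapse = "")
    sim <- simulateGroupedAlignment(base, c(gA = 1, gB = 3),
                                    indelRate = 0.004, seed = 14)
    ev <- callIndels(sim$alignment, referenceId = "gA_1", unique = FALSE)
    refGaps <- sim$truth$gaps$gA_1
    # reference-row gaps show up as one insertion per event in every
    # other row
    ins <- ev[ev$row == "gB_1" & ev$side == "insertion", ]
    expect_equal(sort(ins$start), sort(refGaps$start))
    # each row's own planted gap runs come back as deletions with
    # exact coordinates (none of them touch a reference gap here)
    for (id in c("gB_1", "gB_2", "gB_3")) {
        truth <- sim$truth$gaps[[id]]
        truth <- truth[order(truth$start), ]
        rownames(truth) <- NULL
        got <- ev[ev$row == id & ev$side == "deletion",
                  c("start", "length")]
        got <- got[order(got$start), ]
        rownames(got) <- NULL
        expect_equal(got, truth)
    }
})

test_that("pi matches hand-enumerated and oracle values", {
    # identical rows: pi = 0 everywhere
    aln0 <- GroupedAlignment(c(a = strrep("ACGT", 25),
                               b = strrep("ACGT", 25)),
                             c(a = "g", b = "g"))
    expect_true(all(trackWindows(
        nucleotideDiversity(aln0, window = 20))$value == 0))

    # 3 rows x 10 sites, rows 1 = 2, row 3 differs at 2 sites:
    # pi = (0 + 0.2 + 0.2) / 3
    m <- rbind(a = strsplit("ACGTACGTAC", "")[[1]],
               b = strsplit("ACGTACGTAC", "")[[1]],
               c = strsplit("TCGTACGTAG", "")[[1]])
    aln <- alnFromMatrix(m, c(a = "g", b = "g", c = "g"))
    tr <- nucleotideDiversity(aln, window = 10)
    expect_equal(trackWindows(tr)$value, 0.4 / 3)

    # two rows: pi equals the pairwise difference proportion exactly
    m2 <- m[1:2, ]; m2[2, c(3, 7)] <- c("A", "T")
    aln2 <- alnFromMatrix(m2, c(a = "g", b = "g"))
    expect_equal(trackWindows(nucleotideDiversity(aln2,
                                                  window = 10))$value,
                 0.2)
})

test_that("pi is invariant to row order and reverse complement", {
    set.seed(77)
    base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
    sim <- simulateGroupedAlignment(base, c(g1 = 3, g2 = 2),
                                    snpRate = 0.03, seed = 19)
    aln <- sim$alignment
    v1 <- trackWindows(nucleotideDiversity(aln, window = 100))$value
    ids <- rev(names(alnRows(aln)))
    v2 <- trackWindows(nucleotideDiversity(aln, rows = ids,
                                           window = 100))$value
    expect_equal(v2, v1)
    rcRows <- vapply(as.character(alnRows(aln)), function(s)
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s))), character(1))
    names(rcRows) <- names(alnRows(aln))
    alnRC <- GroupedAlignment(rcRows, groupLabels(aln))
    v3 <- trackWindows(nucleotideDiversity(alnRC, window = 100))$value
    expect_equal(rev(v3), v1)
})

test_that("pi and window counts equal brute-force recounting", {
    set.seed(88)
    for (rep in 1:5) {
        nr <- sample(3:8, 1); nc <- sample(200:400, 1)
        base <- paste(sample(c("A", "C", "G", "T"), nc, replace = TRUE),
                      collapse = "")
        sim <- simulateGroupedAlignment(
            base, stats::setNames(c(nr %/% 2, nr - nr %/% 2),
                                  c("g1", "g2")),
            snpRate = 0.05, indelRate = 0.01, seed = 100 + rep)
        m <- alnMatrix(sim$alignment)
        w <- sample(c(50, 100), 1); s <- sample(c(25, 50), 1)
        expect_equal(
            trackWindows(nucleotideDiversity(sim$alignment, window = w,
                                             step = s))$value,
            brutePi(m, w, s))
        snps <- callSNPs(sim$alignment)$column
        expect_equal(
            trackWindows(windowCounts(snps, sim$alignment, window = w,
                                      step = s))$value,
            bruteWindowCounts(snps, nc, w, s))
    }
})

test_that("windows with no comparable sites are zero and flagged", {
    aln <- GroupedAlignment(c(a = "----ACGT", b = "NNNNACGT"),
                            c(a = "g", b = "g"))
    tr <- nucleotideDiversity(aln, window = 4)
    w <- trackWindows(tr)
    expect_equal(w$value, c(0, 0))
    expect_equal(w$flagged, c(TRUE, FALSE))
})

test_that("window counts place positions and project onto the reference", {
    aln <- GroupedAlignment(
        c(ref = strrep("A", 200), alt = strrep("C", 200)),
        c(ref = "g", alt = "h"))
    tr <- windowCounts(c(10L, 120L, 130L), aln, window = 100, step = 100)
    expect_equal(trackWindows(tr)$value, c(1, 2))
    expect_error(windowCounts(5L, aln, window = 100, step = 0), "step")
    # empty input: all-zero track
    expect_true(all(trackWindows(
        windowCounts(integer(), aln, window = 50))$value == 0))

    # projection: reference gap columns collapse onto the preceding
    # reference position
    aln2 <- GroupedAlignment(c(ref = "AC--GTAC", alt = "ACTTGTAC"),
                             c(ref = "g", alt = "h"))
    tr2 <- windowCounts(c(3L, 4L, 7L), aln2, window = 2, step = 2,
                        referenceId = "ref")
    # ref positions: cols 3,4 -> 2; col 7 -> 5; ref length 6
    expect_equal(trackWindows(tr2)$value, c(2, 0, 1))
    expect_equal(tr2@space, "reference")
})

test_that("region percentages rank planted hotspots first", {
    # 600 bp reference, two genes and the spacer between them
    set.seed(9)
    base <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                  collapse = "")
    baseChars <- strsplit(base, "")[[1]]
    cols <- 301:304          # 4 SNPs inside the spacer 251..450
    states <- vapply(cols, function(cc)
        sample(setdiff(c("A", "C", "G", "T"), baseChars[cc]), 1),
        character(1))
    sim <- simulateGroupedAlignment(base, c(gA = 1, gB = 1),
        planted = list(gB = data.frame(column = cols, state = states)),
        seed = 3)
    feats <- plastomeDiag:::.makeFeatures(
        seqname = "ref", feature_id = 1:2, name = c("geneA", "geneB"),
        type = "CDS", strand = "+", start = c(51L, 451L),
        end = c(250L, 570L))
    rp <- regionPercentages(sim$alignment, feats, referenceId = "gA_1")
    expect_equal(rp$region[1], "geneA--geneB")
    expect_equal(rp$snp_pct[1], 100 * 4 / 200)   # 4 SNPs in 200 bp
    expect_equal(rp$n_snp[rp$region == "geneA"], 0)
    # spacer class is noncoding
    expect_equal(rp$class[1], "noncoding")
})
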