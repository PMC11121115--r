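test_that("planted quadripartite partitions are recovered exactly", {
    for (seed in 1:5) {
        lsc <- sample(6000:9000, 1); ssc <- sample(1500:2500, 1)
        ir <- sample(1200:2500, 1)
        g <- simulatePlastome(lscLen = lsc, sscLen = ssc, irLen = ir,
                              seed = seed)
        p <- findInvertedRepeats(g, minLen = 1000)
        expect_equal(regionLengths(p),
                     c(LSC = lsc, IRB = ir, SSC = ssc, IRA = ir))
    }
})

test_that("detection is idempotent and rotation-invariant", {
    g <- simulatePlastome(lscLen = 7000, sscLen = 1800, irLen = 2000,
                          seed = 3)
    p <- findInvertedRepeats(g)
    canon <- partitionGenome(p)
    p2 <- findInvertedRepeats(canon)
    expect_equal(regionLengths(p2), regionLengths(p))
    expect_equal(as.character(genomeSeq(partitionGenome(p2))),
                 as.character(genomeSeq(canon)))

    # arbitrary rotation of the circular input yields the same partition
    s <- as.character(genomeSeq(g))
    rot <- paste0(substring(s, 4001), substring(s, 1, 4000))
    pRot <- findInvertedRepeats(PlastomeGenome("rot", rot))
    expect_equal(unname(regionLengths(pRot)), unname(regionLengths(p)))
    # reverse complement too (partition lengths are strand-free)
    rc <- as.character(Biostrings::reverseComplement(genomeSeq(g)))
    pRc <- findInvertedRepeats(PlastomeGenome("rc", rc))
    expect_equal(unname(regionLengths(pRc)), unname(regionLengths(p)))
})

test_that("IR detection equals the brute-force diagonal scan on small genomes", {
    for (seed in c(2, 8)) {
        g <- simulatePlastome(lscLen = 1500, sscLen = 500, irLen = 400,
                              nGenes = c(lsc = 2, ssc = 1, ir = 1),
                              geneLen = 120, seed = seed)
        s <- as.character(genomeSeq(g))
        oracle <- bruteMaxInvertedRepeat(s, 200)
        p <- findInvertedRepeats(g, minLen = 200)
        expect_equal(irLength(p), oracle$len)
        expect_equal(unname(regionLengths(p)[c("IRB", "IRA")]),
                     c(oracle$len, oracle$len))
    }
})

test_that("repeat-free sequences raise the no-IR error (brute-verified)", {
    set.seed(42)
    s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
    expect_null(bruteMaxInvertedRepeat(s, 200))
    expect_error(findInvertedRepeats(PlastomeGenome("r", s),
                                     minLen = 200), "no-IR")
})

test_that("two equal-length maximal IR pairs raise a tie error", {
    set.seed(7)
    mk <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                   replace = TRUE), collapse = "")
    rc <- function(x) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(x)))
    a <- mk(400); b <- mk(400)
    s <- paste0(mk(800), a, mk(600), rc(a), mk(700), b, mk(500), rc(b),
                mk(300))
    expect_error(findInvertedRepeats(PlastomeGenome("tie", s),
                                     minLen = 300), "tie")
})

test_that("gcContent excludes ambiguity characters from both terms", {
    expect_equal(gcContent("ATGC"), 0.5)
    expect_equal(gcContent("AANN"), 0)          # denominator 2
    expect_equal(gcContent("GGCC"), 1)
    expect_error(gcContent("NNRY"), "undefined")
})

test_that("junction context reports straddling genes with exact splits", {
    g <- simulatePlastome(lscLen = 8000, sscLen = 2000, irLen = 3000,
                          seed = 7)
    p <- findInvertedRepeats(g)
    jx <- junctionContext(p)
    expect_setequal(jx$junction, c("JLB", "JSB", "JSA", "JLA"))

    jlb <- jx[jx$junction == "JLB", ]
    # generator plants the JLB gene with 120 bp in LSC and 60 bp in IRB
    expect_equal(jlb$feature, "jlbGene")
    expect_equal(c(jlb$side_left, jlb$side_right), c(120L, 60L))
    expect_equal(jlb$distance, -60L)

    jsb <- jx[jx$junction == "JSB", ]
    expect_equal(jsb$feature, "jsbGene")
    expect_equal(c(jsb$side_left, jsb$side_right), c(60L, 200L))

    # split lengths always sum to the feature's total length
    fr <- features(partitionGenome(p))
    mc <- S4Vectors::mcols(fr)
    for (i in which(!is.na(jx$side_left))) {
        sel <- mc$name == jx$feature[i]
        expect_equal(jx$side_left[i] + jx$side_right[i],
                     sum(GenomicRanges::width(fr[sel])))
    }
    expect_error(junctionContext(p, types = "rRNA"), "no features")
})

test_that("non-straddling junction distances count separating bases", {
    # hand-built genome: IRs at known places, one gene ending 13 bp
    # before the LSC/IRB junction
    set.seed(30)
    mk <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                   replace = TRUE), collapse = "")
    rc <- function(x) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(x)))
    ir <- mk(1500)
    lsc <- strsplit(mk(5000), "")[[1]]
    ssc <- strsplit(mk(1200), "")[[1]]
    # pin boundary characters so the planted IR pair cannot extend
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    lsc[1] <- "A"; lsc[5000] <- "A"      # A != comp(A)
    ssc[1] <- "C"; ssc[1200] <- "C"
    s <- paste0(paste(lsc, collapse = ""), ir,
                paste(ssc, collapse = ""), rc(ir))
    fr <- plastomeDiag:::.makeFeatures(
        seqname = "hb", feature_id = 1L, name = "rps19like",
        type = "CDS", strand = "+", start = 4787L, end = 4987L)
    g <- PlastomeGenome("hb", s, features = fr)
    p <- findInvertedRepeats(g)
    expect_equal(unname(regionLengths(p)), c(5000L, 1500L, 1200L, 1500L))
    jx <- junctionContext(p)
    expect_equal(jx$distance[jx$junction == "JLB"], 13)
})

test_that("gene inventory counts per region and flags IR duplicates", {
    g <- simulatePlastome(lscLen = 8000, sscLen = 2000, irLen = 3000,
                          nGenes = c(lsc = 4, ssc = 2, ir = 3),
                          junctionGenes = FALSE, seed = 13)
    p <- findInvertedRepeats(g)
    inv <- geneInventory(p)
    # generator plants 4 LSC genes (every 4th a tRNA), 2 SSC, 3 per IR
    expect_equal(inv$counts$CDS[inv$counts$region == "LSC"], 3L)
    expect_equal(inv$counts$tRNA[inv$counts$region == "LSC"], 1L)
    expect_equal(inv$counts$CDS[inv$counts$region == "SSC"], 2L)
    expect_equal(sum(inv$counts[inv$counts$region %in% c("IRA", "IRB"),
                                c("CDS", "tRNA")]), 6L)
    # every IR gene is mirrored, so all are duplicated
    expect_setequal(inv$duplicated,
                    c("irbGene1", "irbGene2", "irbGene3"))
    # 4 LSC + 2 SSC + 3 IRB genes + 3 mirrored IRA copies
    expect_equal(unname(inv$totals["CDS"] + inv$totals["tRNA"]), 12L)
})

test_that("partition tables carry coordinates, lengths and GC", {
    g <- simulatePlastome(lscLen = 6000, sscLen = 1500, irLen = 1500,
                          seed = 2)
    p <- findInvertedRepeats(g)
    tab <- partitionTable(p)
    expect_equal(tab$region, c("LSC", "IRB", "SSC", "IRA"))
    expect_equal(tab$start, c(1, 6001, 7501, 9001))
    expect_equal(tab$end, c(6000, 7500, 9000, 10500))
    expect_equal(sum(tab$length), length(g))
    expect_equal(tab$gc[2], tab$gc[4])      # IRs are revcomp-identical
})
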