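test_that("pairwise p-distance excludes ambiguous sites", {
    expect_equal(pDistance("ACGTACGTAC", "ACGTACGTAA"),
                 list(distance = 0.10, comparable = 10L))
    ## N and gaps drop the site for this pair only
    expect_equal(pDistance("ACGN", "ACGA"),
                 list(distance = 0, comparable = 3L))
    expect_equal(pDistance("AC-T", "ACGT"),
                 list(distance = 0, comparable = 3L))
    ## no comparable site: undefined, never 0 or 1
    expect_identical(pDistance("NNNN", "ACGT")$distance, NA_real_)
    expect_identical(pDistance("NNNN", "ACGT")$comparable, 0L)
    expect_error(pDistance("ACGT", "ACGTA"), "alignment-shape")
})

test_that("distance matrix matches hand counts and has exact invariants", {
    aln <- BarcodeAlignment(
        c(a = "ACGT", b = "ACGA", c = "TCGA"),
        data.frame(specimen_id = c("a", "b", "c"),
                   nominal_species = c("s1", "s1", "s2")))
    dm <- distanceMatrix(aln)
    d <- distances(dm)
    expect_equal(d["a", "b"], 0.25)
    expect_equal(d["a", "c"], 0.50)
    expect_equal(d["b", "c"], 0.25)
    expect_equal(diag(d), c(a = 0, b = 0, c = 0))
    expect_equal(d, t(d))
    ## identical rows at distance zero
    same <- BarcodeAlignment(
        c(x = "ACGT", y = "ACGT", z = "ACGT"),
        data.frame(specimen_id = c("x", "y", "z"),
                   nominal_species = "s1"))
    expect_true(all(distances(distanceMatrix(same)) == 0))
})

test_that("matrix equals the per-site recount oracle on random data", {
    set.seed(21)
    for (rep in 1:60) {
        aln <- randomAlignment(sample(3:8, 1), sample(5:30, 1),
                               ambigProb = 0.25)
        dm <- distanceMatrix(aln)
        o <- oracleDistanceMatrix(aln)
        expect_identical(distances(dm), o$d)
        expect_identical(comparableSites(dm), o$L)
        ## the mismatch count is an integer
        def <- !is.na(distances(dm))
        prod <- distances(dm)[def] * comparableSites(dm)[def]
        expect_equal(prod, round(prod))
    }
})

test_that("distances agree with ape's raw pairwise-deletion distance", {
    set.seed(22)
    aln <- randomAlignment(8, 60, ambigProb = 0.1)
    dm <- distanceMatrix(aln)
    bin <- ape::as.DNAbin(tolower(alignmentMatrix(aln)))
    ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = TRUE))
    expect_equal(unname(distances(dm)), unname(ref), tolerance = 1e-12)
})

test_that("complete deletion drops every column with any ambiguity", {
    aln <- BarcodeAlignment(
        c(a = "ACGTA", b = "ACGNA", c = "ACTTA"),
        data.frame(specimen_id = c("a", "b", "c"),
                   nominal_species = "s1"))
    dm <- distanceMatrix(aln, deletion = "complete")
    ## column 4 is gone for all pairs, including a-c which could compare it
    expect_true(all(comparableSites(dm) == 4L))
    expect_equal(distances(dm)["a", "c"], 0.25)
})

test_that("nearest heterospecific picks minima with lexicographic ties", {
    d <- matrix(c(0,    0.01, 0.04, 0.06,
                  0.01, 0,    0.05, 0.06,
                  0.04, 0.05, 0,    0.02,
                  0.06, 0.06, 0.02, 0), 4, 4,
                dimnames = list(c("a1", "a2", "b1", "b2"),
                                c("a1", "a2", "b1", "b2")))
    dm <- dmFromMatrix(d)
    nh <- nearestHeterospecific(dm, c(a1 = "A", a2 = "A",
                                      b1 = "B", b2 = "B"))
    expect_equal(nh$groupPairMin["A", "B"], 0.04)
    ps <- nh$perSpecimen
    expect_equal(ps$nearest[ps$specimen == "a1"], "b1")
    ## tie: a2 is 0.06 from both b1 and b2 -> smallest id wins
    d2 <- d; d2["a2", "b1"] <- d2["b1", "a2"] <- 0.06
    nh2 <- nearestHeterospecific(dmFromMatrix(d2),
                                 c(a1 = "A", a2 = "A",
                                   b1 = "B", b2 = "B"))
    expect_equal(nh2$perSpecimen$nearest[2], "b1")
    ## single species: everything undefined, with a warning
    expect_warning(
        nh3 <- nearestHeterospecific(dm, c(a1 = "A", a2 = "A",
                                           b1 = "A", b2 = "A")),
        NA)
    expect_true(all(is.na(nh3$perSpecimen$distance)))
    expect_error(nearestHeterospecific(dm, c(a1 = "A")), "label error")
})

test_that("distance matrices round-trip through TSV and relaxed PHYLIP", {
    set.seed(23)
    aln <- randomAlignment(6, 40, ambigProb = 0.2)
    m <- alignmentMatrix(aln)
    m[2, ] <- "N"                     # force an undefined pair
    aln <- BarcodeAlignment(m, data.frame(
        specimen_id = rownames(m), nominal_species = "sp1"))
    dm <- distanceMatrix(aln)
    for (fmt in c("tsv", "phylip")) {
        path <- withr::local_tempfile()
        writeDistanceMatrix(dm, path, format = fmt)
        back <- readDistanceMatrix(path, format = fmt)
        expect_equal(back, round(distances(dm), 6), tolerance = 1e-9)
        expect_identical(dimnames(back), dimnames(distances(dm)))
    }
})

test_that("a silent genealogy yields exactly zero distances", {
    cfg <- simulationConfig(nSpecies = 3, specimensPerSpecies = 2,
                            mutationScale = 0, missingRate = c(0.1, 0.2),
                            seed = 7)
    ev <- evolveSequences(simulateSpeciesTree(cfg), cfg)
    d <- distances(distanceMatrix(ev$alignment))
    expect_true(all(d[!is.na(d)] == 0))
})
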