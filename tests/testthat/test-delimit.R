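test_that("threshold clustering forms single-linkage components", {
    d <- matrix(c(0, .01, .05, .01, 0, .05, .05, .05, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    part <- clusterMotus(dmFromMatrix(d), 0.03)
    expect_equal(unname(lengths(motuClusters(part))), c(2L, 1L))
    expect_equal(motuClusters(part)[[1]], c("a", "b"))

    ## chaining: a-b and b-c below threshold link a-c despite d(a,c) > t
    dch <- matrix(c(0, .02, .04, .02, 0, .02, .04, .02, 0), 3, 3,
                  dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    expect_length(motuClusters(clusterMotus(dmFromMatrix(dch), 0.03)), 1L)

    ## a permissive threshold collapses everything
    set.seed(41)
    dm <- randomDistanceMatrix(10)
    expect_length(motuClusters(clusterMotus(dm, 0.99)), 1L)

    expect_error(clusterMotus(dm, 0), "threshold")
})

test_that("clustering equals brute-force connected components", {
    set.seed(42)
    for (rep in 1:80) {
        n <- sample(3:20, 1)
        dm <- randomDistanceMatrix(n, naProb = 0.1)
        t <- runif(1, 0.01, 0.11)
        part <- suppressWarnings(clusterMotus(dm, t))
        adj <- !is.na(distances(dm)) & distances(dm) <= t
        diag(adj) <- FALSE
        want <- oracleComponents(adj)
        ## same partition up to relabelling
        got <- motuMembership(part)
        expect_equal(length(unique(got)), length(unique(want)))
        expect_true(all(tapply(got, want, function(x)
            length(unique(x))) == 1L))
    }
})

test_that("MOTU count never increases with the threshold", {
    set.seed(43)
    for (rep in 1:10) {
        dm <- randomDistanceMatrix(15)
        counts <- vapply(seq(0.01, 0.11, by = 0.01), function(t)
            length(motuClusters(clusterMotus(dm, t))), integer(1))
        expect_true(all(diff(counts) <= 0))
    }
})

test_that("split nominal species yield k-1 candidates beyond the anchor", {
    ## species A: MOTU of 3 + MOTU of 2; species B: one MOTU
    d <- matrix(0.1, 6, 6)
    ids <- c("A1", "A2", "A3", "A4", "A5", "B1")
    dimnames(d) <- list(ids, ids)
    d[1:3, 1:3] <- 0.01; d[4:5, 4:5] <- 0.01; diag(d) <- 0
    dm <- dmFromMatrix(d)
    labels <- setNames(c(rep("A", 5), "B"), ids)
    part <- clusterMotus(dm, 0.03)
    cs <- flagCandidates(part, dm, labels)
    r <- candidateRecords(cs)
    expect_equal(nrow(r), 1L)
    expect_equal(r$members, "A4,A5")        # the anchor is the larger MOTU
    expect_equal(r$trigger, "distance_threshold")
    ## nearest relative: closest specimen outside the lineage (here a tie
    ## at 0.1, broken to the smallest id, which is the anchor lineage)
    expect_equal(r$nearest_species, "A")
    expect_equal(r$nearest_distance, 0.1)
    expect_gt(r$nearest_distance, thresholdUsed(part))

    ## a marked reference specimen overrides the size rule
    cs2 <- flagCandidates(part, dm, labels, reference = "A4")
    expect_equal(candidateRecords(cs2)$members, "A1,A2,A3")

    ## every species in one MOTU, all monophyletic: nothing to flag
    dOne <- matrix(0.1, 4, 4,
                   dimnames = list(c("A1", "A2", "B1", "B2"),
                                   c("A1", "A2", "B1", "B2")))
    dOne[1:2, 1:2] <- 0.01; dOne[3:4, 3:4] <- 0.01; diag(dOne) <- 0
    dmOne <- dmFromMatrix(dOne)
    partOne <- clusterMotus(dmOne, 0.03)
    labs <- setNames(c("A", "A", "B", "B"), rownames(dOne))
    expect_equal(nrow(candidateRecords(flagCandidates(
        partOne, dmOne, labs,
        treeStatus = list(A = "monophyletic", B = "monophyletic")))), 0L)

    ## single-MOTU but polyphyletic: flagged on tree evidence alone
    cs3 <- flagCandidates(partOne, dmOne, labs,
                          treeStatus = list(A = "polyphyletic"))
    r3 <- candidateRecords(cs3)
    expect_equal(nrow(r3), 1L)
    expect_equal(r3$trigger, "non_monophyly")
    expect_equal(r3$monophyly_status, "polyphyletic")

    expect_error(flagCandidates(part, dm, labels[-1]), "label error")
})

test_that("a MOTU mixing nominal labels is reported, not merged", {
    d <- matrix(0.1, 4, 4,
                dimnames = list(c("A1", "A2", "B1", "B2"),
                                c("A1", "A2", "B1", "B2")))
    d[1:3, 1:3] <- 0.01; diag(d) <- 0   # B1 clusters with the A's
    dm <- dmFromMatrix(d)
    part <- clusterMotus(dm, 0.03)
    labs <- setNames(c("A", "A", "B", "B"), rownames(d))
    expect_warning(cs <- flagCandidates(part, dm, labs), "synonymy")
    expect_length(cs@mixedMotus, 1L)
})

test_that("morphological diagnosability follows the disjointness rules", {
    chars <- data.frame(
        row.names = c("c1", "c2", "o1", "o2"),
        branched_anal_rays = c(18L, 19L, 22L, 23L),
        body_depth_ratio = c(0.30, 0.35, 0.33, 0.40))
    ## disjoint meristic sets are diagnostic -> concordant
    res <- diagnosability(c("c1", "c2"), c("o1", "o2"), chars)
    expect_equal(res$verdict, "concordant")
    expect_true(res$perCharacter$diagnostic[
        res$perCharacter$character == "branched_anal_rays"])

    ## overlapping ranges on the only character, >= 2 per side -> discordant
    only <- chars["body_depth_ratio"]
    expect_equal(diagnosability(c("c1", "c2"), c("o1", "o2"),
                                only)$verdict, "discordant")

    ## one side singly scored and overlapping -> inconclusive
    expect_equal(diagnosability("c2", c("o1", "o2"), only)$verdict,
                 "inconclusive")

    ## no shared scored character -> inconclusive with a warning
    half <- data.frame(row.names = c("c1", "o1"), x = c(1L, NA))
    expect_warning(v <- diagnosability("c1", "o1", half)$verdict,
                   "inconclusive")
    expect_equal(v, "inconclusive")
})

test_that("verdicts map onto final classes and conserve counts", {
    mk <- function(n) {
        d <- matrix(0.1, 2 * n + 2, 2 * n + 2)
        ids <- c(paste0("X", seq_len(2 * n)), "Y1", "Y2")
        dimnames(d) <- list(ids, ids)
        for (k in seq_len(n))
            d[2 * k - 1, 2 * k] <- d[2 * k, 2 * k - 1] <- 0.01
        d[2 * n + 1, 2 * n + 2] <- d[2 * n + 2, 2 * n + 1] <- 0.01
        diag(d) <- 0
        dm <- dmFromMatrix(d)
        labs <- setNames(c(rep("X", 2 * n), "Y", "Y"), ids)
        suppressWarnings(
            flagCandidates(clusterMotus(dm, 0.03), dm, labs))
    }
    cs <- mk(9)                      # species X spans 9 MOTUs -> 8 records
    expect_equal(nrow(candidateRecords(cs)), 8L)
    cls <- classifyCandidates(cs, c(rep("concordant", 6),
                                    rep("inconclusive", 2)))
    tot <- candidateTotals(cls)
    expect_equal(unname(tot[c("confirmed", "unconfirmed",
                              "deep_conspecific_lineage")]), c(6L, 2L, 0L))
    expect_equal(unname(tot[["total"]]),
                 sum(tot[c("confirmed", "unconfirmed",
                           "deep_conspecific_lineage",
                           "not_classified")]))

    one <- mk(3)                     # 3 MOTUs -> 2 candidate records
    ids <- candidateRecords(one)$candidate_id
    r <- classifyCandidates(one, setNames(c("discordant", "unavailable"),
                                          ids))
    totalsOne <- candidateTotals(r)
    expect_equal(unname(totalsOne[["deep_conspecific_lineage"]]), 1L)
    expect_equal(unname(totalsOne[["unconfirmed"]]), 1L)

    ## empty candidate set classifies to all-zero totals
    empty <- mk(1)
    expect_equal(unname(candidateTotals(
        classifyCandidates(empty, character()))[["total"]]), 0L)

    expect_error(classifyCandidates(cs, rep("weird", 8)), "invalid verdict")
    expect_error(classifyCandidates(cs, rep("concordant", 3)),
                 "one verdict per")
})

test_that("the threshold sweep reports both counts per cutoff", {
    set.seed(44)
    cfg <- simulationConfig(nSpecies = 4, specimensPerSpecies = 3,
                            crypticPairs = 1, missingRate = c(0, 0),
                            seed = 99)
    ev <- evolveSequences(simulateSpeciesTree(cfg), cfg)
    dm <- distanceMatrix(ev$alignment)
    sw <- thresholdSweep(dm, nominalSpecies(ev$alignment),
                         seq(0.01, 0.11, by = 0.02))
    expect_equal(nrow(sw), 6L)
    expect_true(all(diff(sw$n_motus) <= 0))
})
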