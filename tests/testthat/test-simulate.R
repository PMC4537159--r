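test_that("config validation rejects degenerate studies", {
    expect_error(simulationConfig(nSpecies = 1, seed = 1), "nSpecies")
    expect_error(simulationConfig(nSpecies = 4, seed = 1,
                                  intraDivergence = 0.2,
                                  interDivergence = c(0.05, 0.11)),
                 "intraDivergence")
    expect_error(simulationConfig(nSpecies = 4, crypticPairs = 3,
                                  seed = 1), "crypticPairs")
    expect_error(simulationConfig(nSpecies = 4), "seed")
})

test_that("identical config and seed reproduce byte-identical outputs", {
    cfg <- simulationConfig(nSpecies = 5, specimensPerSpecies = 3,
                            crypticPairs = 1, seed = 123)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    generateDataset(cfg, d1)
    generateDataset(cfg, d2)
    expect_identical(readLines(file.path(d1, "alignment.fasta")),
                     readLines(file.path(d2, "alignment.fasta")))
    expect_identical(readLines(file.path(d1, "true_tree.nwk")),
                     readLines(file.path(d2, "true_tree.nwk")))
    expect_identical(readLines(file.path(d1, "morphology.tsv")),
                     readLines(file.path(d2, "morphology.tsv")))
    ## a different seed changes the sequences
    cfg2 <- simulationConfig(nSpecies = 5, specimensPerSpecies = 3,
                             crypticPairs = 1, seed = 124)
    d3 <- withr::local_tempdir()
    generateDataset(cfg2, d3)
    expect_false(identical(readLines(file.path(d1, "alignment.fasta")),
                           readLines(file.path(d3, "alignment.fasta"))))
})

test_that("sister-pair branch lengths are calibrated to the JC expectation", {
    ## two species, one specimen each, no within-species variation:
    ## the realised p-distance should average the 6% target
    reps <- 100
    got <- numeric(reps)
    for (s in seq_len(reps)) {
        cfg <- simulationConfig(nSpecies = 2, specimensPerSpecies = 1,
                                intraDivergence = 0,
                                interDivergence = c(0.06, 0.06),
                                missingRate = c(0, 0), seed = 5000 + s)
        ev <- evolveSequences(simulateSpeciesTree(cfg), cfg)
        d <- distances(distanceMatrix(ev$alignment))
        got[s] <- d["sp01_01", "sp02_01"]
    }
    expect_lt(abs(mean(got) - 0.06), 0.2 * 0.06)
})

test_that("realised within-species divergence tracks the configured value", {
    reps <- 100
    got <- numeric(reps)
    for (s in seq_len(reps)) {
        cfg <- simulationConfig(nSpecies = 2, specimensPerSpecies = 4,
                                intraDivergence = 0.005,
                                missingRate = c(0, 0), seed = 6000 + s)
        ev <- evolveSequences(simulateSpeciesTree(cfg), cfg)
        d <- distances(distanceMatrix(ev$alignment))
        sp1 <- paste0("sp01_0", 1:4)
        got[s] <- mean(d[sp1, sp1][upper.tri(diag(4))])
    }
    expect_lt(abs(mean(got) - 0.005), 0.2 * 0.005)
})

test_that("per-specimen missingness stays inside the configured range", {
    cfg <- simulationConfig(nSpecies = 6, specimensPerSpecies = 4,
                            missingRate = c(0.08, 0.34),
                            missingShape = c(1, 1), seed = 77)
    ev <- evolveSequences(simulateSpeciesTree(cfg), cfg)
    pct <- alignmentStats(ev$alignment)$missingBySpecimen
    expect_true(all(pct >= 7.9 & pct <= 34.1))
})

test_that("truth table and alignment describe the same specimens", {
    cfg <- simulationConfig(nSpecies = 4, specimensPerSpecies = c(2, 5),
                            crypticPairs = 1, seed = 9)
    ev <- evolveSequences(simulateSpeciesTree(cfg), cfg)
    expect_setequal(ev$truth$specimen_id, specimenIds(ev$alignment))
    ## nominal = true species except inside cryptic pairs
    tt <- ev$truth[ev$truth$specimen_id != "OUTGROUP", ]
    cryptic <- !is.na(tt$cryptic_pair)
    expect_true(all(tt$true_species[!cryptic] ==
                    tt$nominal_species[!cryptic]))
    expect_true(all(tt$true_species[cryptic] !=
                    tt$nominal_species[cryptic]))
    ## two true lineages share each lumped nominal name
    for (p in unique(tt$cryptic_pair[cryptic]))
        expect_length(unique(tt$true_species[cryptic &
                                             tt$cryptic_pair == p]), 2L)
})

test_that("the outgroup sits far outside the ingroup radiation", {
    cfg <- simulationConfig(nSpecies = 5, specimensPerSpecies = 2,
                            missingRate = c(0, 0), seed = 55)
    tr <- simulateSpeciesTree(cfg)
    expect_true("OUTGROUP" %in% tr$tip.label)
    dd <- ape::cophenetic.phylo(tr)
    ingroup <- setdiff(rownames(dd), "OUTGROUP")
    ## JC path length whose expected p-distance doubles the deepest
    ## configured sister divergence
    minOut <- min(dd["OUTGROUP", ingroup])
    expect_gte(0.75 * (1 - exp(-4 * minOut / 3)), 2 * 0.11)
})

test_that("clean, well-separated lineages are recovered exactly", {
    ## no missing data, 0.5% within / >= 5% between: every replicate
    ## recovers one MOTU per true species and one candidate per pair
    for (s in 1:25) {
        cfg <- simulationConfig(nSpecies = 6, specimensPerSpecies = 3,
                                crypticPairs = 1, intraDivergence = 0.005,
                                interDivergence = c(0.05, 0.11),
                                missingRate = c(0, 0), seed = 2000 + s)
        ev <- evolveSequences(simulateSpeciesTree(cfg), cfg)
        dm <- distanceMatrix(ev$alignment)
        part <- clusterMotus(dm, 0.03)
        ing <- setdiff(specimenIds(ev$alignment), "OUTGROUP")
        expect_equal(length(unique(motuMembership(part)[ing])),
                     cfg@nSpecies)
        cs <- flagCandidates(part, dm, nominalSpecies(ev$alignment))
        expect_equal(candidateRecords(cs)$nominal_species, "sp01")
    }
})

test_that("a study without cryptic pairs flags no candidates", {
    cfg <- simulationConfig(nSpecies = 5, specimensPerSpecies = 3,
                            crypticPairs = 0, missingRate = c(0, 0),
                            seed = 31)
    ev <- evolveSequences(simulateSpeciesTree(cfg), cfg)
    rep <- runDelimitation(ev$alignment)
    expect_equal(unname(rep$totals[["total"]]), 0L)
})
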