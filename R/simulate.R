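## Jukes-Cantor conversions between an expected p-distance and a branch
## length in expected substitutions per site: p = 3/4 (1 - exp(-4 d / 3)).
.jcDist <- function(p) -0.75 * log(1 - 4 * p / 3)
.jcP <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Build a simulation configuration
#'
#' Describes a simulated barcode study with known species structure.
#' True species are laid out as sister pairs ("cherries") whose expected
#' p-distance is drawn from \code{interDivergence}; the first
#' \code{crypticPairs} cherries are \emph{cryptic}: their two true
#' lineages share one nominal species name, so a correct delimitation
#' must flag exactly one candidate per cryptic pair.  Within-species
#' variation, per-specimen missing data (read-end truncation by default,
#' written as \code{N} or \code{-}) and a morphology table with a
#' configurable concordance scenario per cryptic pair complete the
#' data set.  An outgroup specimen named \code{OUTGROUP} is always
#' emitted, at more than twice the maximum ingroup divergence.
#'
#' @param nSpecies number of true species (>= 2), outgroup excluded.
#' @param specimensPerSpecies a single count, a range \code{c(lo, hi)}
#'   to draw per-species counts from, or a vector of length
#'   \code{nSpecies} (ordered as pair-1 lineage A, pair-1 lineage B,
#'   ..., then the non-cryptic species).
#' @param crypticPairs number of cryptic pairs (true species pairs lumped
#'   under one nominal name).
#' @param crypticDivergence optional expected p-distance per cryptic
#'   pair; \code{NA} entries are drawn from \code{interDivergence}.
#' @param seqLength alignment length in sites (default 657, a typical
#'   partial 16S fragment).
#' @param intraDivergence expected within-species p-distance (default
#'   0.005).
#' @param interDivergence range of expected sister-pair p-distances
#'   (default 0.05 to 0.11).
#' @param missingRate per-specimen missing-fraction range (default 0.08
#'   to 0.34).
#' @param missingShape Beta(a, b) shape of the missing-fraction draw
#'   within its range; the default (1, 4.2) skews draws toward the low
#'   end so the mean fraction is about 0.13 while the full range stays
#'   reachable; use c(1, 1) for uniform.
#' @param missingMode \code{"terminal"} (contiguous truncation at the
#'   sequence ends, the dominant pattern in real barcode reads) or
#'   \code{"random"}.
#' @param ambiguityRate fraction of masked characters written as \code{N}
#'   rather than \code{-} (default 0.5).
#' @param morphScenario per-cryptic-pair scenario: \code{"diagnosable"}
#'   (a meristic character separates the pair: confirmed candidate),
#'   \code{"identical"} (morphology overlaps: deep conspecific lineage)
#'   or \code{"unscored"} (no morphology: unconfirmed candidate).
#'   Default: all \code{"diagnosable"}.
#' @param mutationScale multiplier on every branch length (default 1;
#'   0 switches substitution off).
#' @param seed mandatory RNG seed (integer below 2^31 - 48).
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSpecies, specimensPerSpecies = 4L,
                             crypticPairs = 0L,
                             crypticDivergence = NULL,
                             seqLength = 657L,
                             intraDivergence = 0.005,
                             interDivergence = c(0.05, 0.11),
                             missingRate = c(0.08, 0.34),
                             missingShape = c(1, 4.2),
                             missingMode = c("terminal", "random"),
                             ambiguityRate = 0.5,
                             morphScenario = NULL,
                             mutationScale = 1,
                             seed) {
    if (missing(seed)) stop("seed is mandatory for reproducibility")
    nSpecies <- as.integer(nSpecies)
    crypticPairs <- as.integer(crypticPairs)
    if (is.null(crypticDivergence))
        crypticDivergence <- rep(NA_real_, crypticPairs)
    if (is.null(morphScenario))
        morphScenario <- rep("diagnosable", crypticPairs)
    missingMode <- match.arg(missingMode)
    sps <- as.integer(specimensPerSpecies)
    if (length(sps) == 1L) {
        sps <- rep(sps, nSpecies)
    } else if (length(sps) == 2L && nSpecies != 2L) {
        ## a (lo, hi) range: draw per-species counts, seeded
        set.seed(as.integer(seed) %% 2147483000L + 7L)
        sps <- sample(sps[1L]:sps[2L], nSpecies, replace = TRUE)
    }
    new("SimulationConfig",
        nSpecies = nSpecies, specimensPerSpecies = sps,
        crypticPairs = crypticPairs,
        crypticDivergence = as.numeric(crypticDivergence),
        seqLength = as.integer(seqLength),
        intraDivergence = intraDivergence,
        interDivergence = as.numeric(interDivergence),
        missingRate = as.numeric(missingRate),
        missingShape = as.numeric(missingShape),
        missingMode = missingMode,
        ambiguityRate = ambiguityRate,
        morphScenario = morphScenario,
        mutationScale = mutationScale,
        seed = as.integer(seed))
}

#' The survey-scale preset configuration
#'
#' A study at the scale of a full 16S barcode survey of Amazonian
#' characins: 232 specimens (231 ingroup plus outgroup) in a 657-site
#' alignment, 33 nominal species, and 8 planted cryptic pairs, of which
#' 6 carry a diagnosable meristic difference (confirmed candidates) and
#' 2 are morphologically unscored (unconfirmed candidates).  Cryptic
#' divergences are a fixed ladder from 5.5\% to 11\%, spanning the
#' shallow-to-deep range reported for 16S candidate species while
#' staying clearly above the 3\% delimitation threshold.
#'
#' @param seed mandatory RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
surveyPresetConfig <- function(seed) {
    ## per-true-species specimen counts: cryptic anchors get 6, cryptic
    ## candidate lineages 3, the 25 ordinary species 7 or 6 specimens,
    ## totalling 231 ingroup specimens (+ OUTGROUP = 232 terminals)
    sps <- c(rep(c(6L, 3L), 8L), rep(7L, 9L), rep(6L, 16L))
    simulationConfig(
        nSpecies = 41L, specimensPerSpecies = sps, crypticPairs = 8L,
        crypticDivergence = c(0.055, 0.065, 0.075, 0.080,
                              0.085, 0.090, 0.100, 0.110),
        seqLength = 657L,
        morphScenario = c(rep("diagnosable", 6L), rep("unscored", 2L)),
        seed = seed)
}

## ---------------------------------------------------------------------
## Internal seeded layout of the study: lineage names, nominal labels,
## specimen allocation, cherry pairing and ultrametric node depths (in
## expected substitutions per site).  All downstream randomness flows
## from this one structure, so a config + seed fixes the whole data set.
.simStructure <- function(cfg) {
    set.seed(cfg@seed)
    c0 <- cfg@crypticPairs
    nNominal <- cfg@nSpecies - c0
    spName <- sprintf("sp%02d", seq_len(nNominal))
    lineage <- character(cfg@nSpecies)
    nominal <- character(cfg@nSpecies)
    pairIdx <- rep(NA_integer_, cfg@nSpecies)
    if (c0 > 0L) {
        lineage[seq_len(2L * c0)] <-
            paste0(rep(spName[seq_len(c0)], each = 2L), c("A", "B"))
        nominal[seq_len(2L * c0)] <- rep(spName[seq_len(c0)], each = 2L)
        pairIdx[seq_len(2L * c0)] <- rep(seq_len(c0), each = 2L)
    }
    if (nNominal > c0) {
        rest <- (2L * c0 + 1L):cfg@nSpecies
        lineage[rest] <- nominal[rest] <- spName[(c0 + 1L):nNominal]
    }

    ## sister-pair ("cherry") layout: cryptic pairs are cherries by
    ## construction; the remaining species are paired at random
    lo <- cfg@interDivergence[1L]; hi <- cfg@interDivergence[2L]
    crypticP <- cfg@crypticDivergence
    crypticP[is.na(crypticP)] <- stats::runif(sum(is.na(crypticP)), lo, hi)
    cherries <- list()
    for (i in seq_len(c0))
        cherries[[length(cherries) + 1L]] <- list(
            members = lineage[pairIdx %in% i], p = crypticP[i])
    others <- lineage[is.na(pairIdx)]
    if (length(others)) {
        perm <- sample(others)
        while (length(perm) >= 2L) {
            cherries[[length(cherries) + 1L]] <- list(
                members = perm[1:2], p = stats::runif(1, lo, hi))
            perm <- perm[-(1:2)]
        }
        if (length(perm) == 1L)
            cherries[[length(cherries) + 1L]] <- list(members = perm, p = NA)
    }
    cherries <- cherries[sample(length(cherries))]

    ## pectinate ladder above the cherries; depths in JC units, spaced so
    ## between-cherry expected p-distances start around 14% and grow
    hCherry <- vapply(cherries, function(ch)
        if (length(ch$members) == 2L) .jcDist(ch$p) / 2 else 0, numeric(1))
    base <- max(.jcDist(0.14) / 2, max(hCherry) + 0.01)
    depths <- base + 0.006 * (seq_along(cherries) - 1L)
    depths <- depths[-1L]                      # m cherries need m-1 joins
    hOut <- max(.jcDist(0.25) / 2,
                if (length(depths)) max(depths) + 0.02 else base + 0.02)

    nspec <- stats::setNames(cfg@specimensPerSpecies, lineage)
    list(lineage = lineage, nominal = stats::setNames(nominal, lineage),
         pairIdx = stats::setNames(pairIdx, lineage),
         cherries = cherries, hCherry = hCherry, depths = depths,
         hOut = hOut, nspec = nspec)
}

## Newick assembly of the ultrametric layout.  At the specimen level each
## lineage leaf is replaced by a star of specimens attached at depth b =
## jcDist(intra)/2, so conspecific paths have expected p-distance equal
## to intraDivergence and between-lineage paths keep their target.
.buildNewick <- function(struct, cfg, specimenLevel) {
    scale <- cfg@mutationScale
    b <- .jcDist(cfg@intraDivergence) / 2
    leafStr <- function(lin) {
        if (!specimenLevel) return(list(txt = lin, h = 0))
        k <- struct$nspec[[lin]]
        ids <- sprintf("%s_%02d", lin, seq_len(k))
        if (k == 1L) return(list(txt = ids, h = 0))
        list(txt = paste0("(", paste0(ids, ":", b * scale,
                                      collapse = ","), ")"),
             h = b)
    }
    node <- function(ch) {
        if (length(ch$members) == 1L) return(leafStr(ch$members))
        h <- .jcDist(ch$p) / 2
        kids <- lapply(ch$members, leafStr)
        txt <- paste0("(",
                      paste(vapply(kids, function(k)
                          paste0(k$txt, ":", (h - k$h) * scale),
                          character(1)), collapse = ","),
                      ")")
        list(txt = txt, h = h)
    }
    cur <- node(struct$cherries[[1L]])
    for (j in seq_along(struct$depths)) {
        nxt <- node(struct$cherries[[j + 1L]])
        H <- struct$depths[j]
        cur <- list(txt = paste0("(", cur$txt, ":", (H - cur$h) * scale,
                                 ",", nxt$txt, ":", (H - nxt$h) * scale,
                                 ")"),
                    h = H)
    }
    paste0("(", cur$txt, ":", (struct$hOut - cur$h) * scale, ",",
           "OUTGROUP:", struct$hOut * scale, ");")
}

#' Simulate the species tree of a configured study
#'
#' Returns the rooted ultrametric lineage-level tree (one leaf per true
#' species plus \code{OUTGROUP}) whose branch lengths, in expected
#' substitutions per site, are calibrated so that sister-pair path
#' lengths reproduce the configured expected p-distances under the
#' Jukes-Cantor model.  Deterministic given the config seed.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return a rooted \code{phylo}.
#' @export
simulateSpeciesTree <- function(cfg) {
    stopifnot(is(cfg, "SimulationConfig"))
    struct <- .simStructure(cfg)
    ape::read.tree(text = .buildNewick(struct, cfg, specimenLevel = FALSE))
}

#' Evolve sequences along the configured genealogy
#'
#' Expands the species tree to the specimen level (within-species
#' branchlets sized for the configured intra-species divergence), draws a
#' uniform A/C/G/T root sequence and evolves it by site-independent
#' Jukes-Cantor substitution, then applies the per-specimen missing-data
#' mask (contiguous read-end truncation or random positions, written as
#' \code{N} or \code{-}).  Deterministic given the config seed.
#'
#' @param tree the lineage-level tree from
#'   \code{\link{simulateSpeciesTree}} (checked for consistency with the
#'   config).
#' @param cfg the same \linkS4class{SimulationConfig}.
#' @return list with \code{alignment} (a
#'   \linkS4class{BarcodeAlignment} whose specimen table carries
#'   \code{nominal_species} and a logical \code{reference} column) and
#'   \code{truth} (DataFrame: \code{specimen_id}, \code{true_species},
#'   \code{nominal_species}, \code{cryptic_pair}, \code{morph_truth}).
#' @export
evolveSequences <- function(tree, cfg) {
    stopifnot(is(cfg, "SimulationConfig"))
    struct <- .simStructure(cfg)
    if (!setequal(tree$tip.label, c(struct$lineage, "OUTGROUP")))
        stop("tree does not match the configuration ",
             "(expected the tree from simulateSpeciesTree on this config)")
    set.seed(cfg@seed + 1L)
    specTree <- ape::read.tree(
        text = .buildNewick(struct, cfg, specimenLevel = TRUE))
    sim <- phangorn::simSeq(specTree, l = cfg@seqLength, type = "DNA")
    m <- toupper(as.character(sim))
    m <- m[sort(rownames(m)), , drop = FALSE]

    ## per-specimen missing-data mask
    L <- ncol(m)
    a <- cfg@missingShape[1L]; bsh <- cfg@missingShape[2L]
    for (i in seq_len(nrow(m))) {
        f <- cfg@missingRate[1L] +
            diff(cfg@missingRate) * stats::rbeta(1, a, bsh)
        k <- round(f * L)
        if (k == 0L) next
        pos <- if (cfg@missingMode == "terminal") {
            s <- sample.int(k + 1L, 1L) - 1L
            c(seq_len(s), if (k - s > 0L) (L - (k - s) + 1L):L)
        } else sample.int(L, k)
        m[i, pos] <- ifelse(stats::runif(length(pos)) < cfg@ambiguityRate,
                            "N", "-")
    }

    ids <- rownames(m)
    lin <- ifelse(ids == "OUTGROUP", "OUTGROUP",
                  sub("_[0-9]+$", "", ids))
    nominal <- ifelse(lin == "OUTGROUP", "OUTGROUP",
                      struct$nominal[lin])
    pairIdx <- ifelse(lin == "OUTGROUP", NA_integer_,
                      struct$pairIdx[lin])
    morphTruth <- ifelse(is.na(pairIdx), "none",
                         cfg@morphScenario[pairIdx])
    ## the anchor lineage of each cryptic pair gets a reference specimen,
    ## fixing which MOTU counts as the already-described species
    reference <- ids %in% paste0(struct$lineage[grepl("A$", struct$lineage) &
                                                !is.na(struct$pairIdx)], "_01")
    truth <- DataFrame(specimen_id = ids, true_species = lin,
                       nominal_species = nominal,
                       cryptic_pair = as.integer(pairIdx),
                       morph_truth = morphTruth)
    aln <- BarcodeAlignment(
        m, data.frame(specimen_id = ids, nominal_species = nominal,
                      reference = reference,
                      stringsAsFactors = FALSE))
    list(alignment = aln, truth = truth)
}

## Seeded morphology table: meristic counts, a morphometric ratio and a
## categorical character per specimen, with the cryptic-pair scenario
## controlling whether the candidate lineage is diagnosable, identical
## or unscored.
.simulateMorphology <- function(cfg, truth) {
    set.seed(cfg@seed + 2L)
    lineages <- unique(truth$true_species)
    base <- list()
    for (lin in lineages) {
        base[[lin]] <- list(
            rays = sample(16:28, 1L),
            scales = sample(30:44, 1L),
            teeth = sample(2:8, 1L),
            depth = stats::runif(1, 0.25, 0.36),
            spot = sample(c("round", "bar", "absent"), 1L))
    }
    ## candidate (B) lineages inherit or diverge from their anchor (A)
    for (i in seq_len(cfg@crypticPairs)) {
        pair <- unique(truth$true_species[
            !is.na(truth$cryptic_pair) & truth$cryptic_pair == i])
        anchor <- pair[grepl("A$", pair)]
        cand <- pair[grepl("B$", pair)]
        base[[cand]] <- base[[anchor]]
        if (cfg@morphScenario[i] == "diagnosable")
            base[[cand]]$rays <- base[[anchor]]$rays + 4L
    }
    n <- nrow(truth)
    tab <- data.frame(
        specimen_id = truth$specimen_id,
        branched_anal_rays = integer(n),
        lateral_line_scales = integer(n),
        maxilla_teeth = integer(n),
        body_depth_ratio = numeric(n),
        caudal_spot = character(n),
        stringsAsFactors = FALSE)
    for (r in seq_len(n)) {
        bs <- base[[truth$true_species[r]]]
        tab$branched_anal_rays[r] <- bs$rays + sample(-1:1, 1L)
        tab$lateral_line_scales[r] <- bs$scales + sample(-2:2, 1L)
        tab$maxilla_teeth[r] <- max(0L, bs$teeth + sample(-1:1, 1L))
        tab$body_depth_ratio[r] <- round(bs$depth +
                                         stats::runif(1, -0.015, 0.015), 3)
        tab$caudal_spot[r] <- bs$spot
    }
    unscored <- truth$morph_truth == "unscored" &
        grepl("B$", truth$true_species)
    tab[unscored, -1L] <- NA
    tab
}

#' Generate a complete simulated data set on disk
#'
#' Writes everything needed to run the whole pipeline from files: the
#' aligned FASTA, the specimen table (with nominal species and reference
#' flags), the ground-truth table, the true lineage-level tree in newick,
#' the morphology table, and a JSON echo of the configuration.  Byte
#' identical for a given config + seed.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param dir output directory (created if absent).
#' @return invisibly, a list with the written \code{paths} and the
#'   in-memory \code{alignment}, \code{truth}, \code{tree} and
#'   \code{morphology} objects.
#' @export
generateDataset <- function(cfg, dir) {
    stopifnot(is(cfg, "SimulationConfig"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tree <- simulateSpeciesTree(cfg)
    ev <- evolveSequences(tree, cfg)
    morph <- .simulateMorphology(cfg, ev$truth)

    paths <- list(
        fasta = file.path(dir, "alignment.fasta"),
        specimens = file.path(dir, "specimens.tsv"),
        truth = file.path(dir, "truth.tsv"),
        tree = file.path(dir, "true_tree.nwk"),
        morphology = file.path(dir, "morphology.tsv"),
        config = file.path(dir, "config.json"))

    m <- alignmentMatrix(ev$alignment)
    writeLines(as.vector(rbind(paste0(">", rownames(m)),
                               apply(m, 1L, paste, collapse = ""))),
               paths$fasta)
    sd <- as.data.frame(specimenData(ev$alignment))
    utils::write.table(
        data.frame(specimen_id = rownames(sd), sd, row.names = NULL),
        paths$specimens, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(ev$truth), paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ape::write.tree(tree, file = paths$tree)
    utils::write.table(morph, paths$morphology, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(nSpecies = cfg@nSpecies,
             specimensPerSpecies = cfg@specimensPerSpecies,
             crypticPairs = cfg@crypticPairs,
             crypticDivergence = cfg@crypticDivergence,
             seqLength = cfg@seqLength,
             intraDivergence = cfg@intraDivergence,
             interDivergence = cfg@interDivergence,
             missingRate = cfg@missingRate,
             missingShape = cfg@missingShape,
             missingMode = cfg@missingMode,
             ambiguityRate = cfg@ambiguityRate,
             morphScenario = cfg@morphScenario,
             mutationScale = cfg@mutationScale,
             seed = cfg@seed),
        paths$config, auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(paths = paths, alignment = ev$alignment,
                   truth = ev$truth, tree = tree, morphology = morph))
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d true species (%d cryptic pair(s)), %d specimens + outgroup, %d sites, seed %d\n",
        object@nSpecies, object@crypticPairs,
        sum(object@specimensPerSpecies), object@seqLength, object@seed))
})
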