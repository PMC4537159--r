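#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## IUPAC nucleotide alphabet accepted in aligned matrices.  `U` is
## normalised to `T` on input, so it never appears in a stored alignment.
.IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-", "?")

## Characters treated as missing/ambiguous everywhere in the package:
## gaps, `?`, `N` and all partial ambiguity codes.  Only A/C/G/T are
## "unambiguous" states; the same definition backs the missing-data
## percentages and the pairwise-deletion distance.
.MISSING_CHARS <- setdiff(.IUPAC_CHARS, c("A", "C", "G", "T"))

#' BarcodeAlignment: an aligned single-locus nucleotide matrix
#'
#' Holds an aligned matrix of IUPAC nucleotide characters (one row per
#' specimen) together with a per-specimen annotation table.  The
#' annotation table must at minimum carry a \code{nominal_species} column
#' assigning every specimen its Linnaean (pre-delimitation) name; an
#' optional logical \code{reference} column marks reference specimens
#' used as anchors when a nominal species splits into several MOTUs.
#'
#' @slot seqs character matrix, rows = specimens (rownames are specimen
#'   ids), columns = alignment sites; entries are single upper-case IUPAC
#'   characters with \code{U} already normalised to \code{T}.
#' @slot specimenData \link[S4Vectors]{DataFrame} with one row per
#'   specimen, rownames matching \code{rownames(seqs)}.
#' @export
setClass("BarcodeAlignment",
         representation(seqs = "matrix", specimenData = "DataFrame"))

setValidity("BarcodeAlignment", function(object) {
    m <- object@seqs
    msg <- character()
    if (!is.character(m) || is.null(rownames(m)))
        return("seqs must be a character matrix with specimen rownames")
    if (nrow(m) < 2L)
        msg <- c(msg, "an alignment needs at least 2 specimens")
    if (ncol(m) < 1L)
        msg <- c(msg, "an alignment needs at least 1 site")
    if (anyDuplicated(rownames(m)))
        msg <- c(msg, "duplicate specimen ids")
    bad <- matrix(!(m %in% .IUPAC_CHARS), nrow = nrow(m))
    if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf(
            "non-IUPAC character '%s' in specimen '%s' at site %d",
            m[w[1L], w[2L]], rownames(m)[w[1L]], w[2L]))
    }
    if (!identical(rownames(object@specimenData), rownames(m)))
        msg <- c(msg, "specimenData rownames must match alignment rows")
    if (!"nominal_species" %in% colnames(object@specimenData))
        msg <- c(msg, "specimenData must have a 'nominal_species' column")
    if (length(msg)) msg else TRUE
})

#' PDistanceMatrix: uncorrected pairwise distances with comparable-site counts
#'
#' Symmetric matrix of uncorrected p-distances between specimens, computed
#' under pairwise deletion: for every pair only the sites where both
#' sequences carry an unambiguous base (A/C/G/T) are compared.  A pair with
#' no comparable site has an undefined distance, stored as \code{NA}.
#'
#' @slot d numeric matrix of proportions in [0,1]; \code{NA} marks an
#'   undefined distance; zero diagonal.
#' @slot comparableSites integer matrix of per-pair comparable-site counts;
#'   the diagonal holds each specimen's number of unambiguous sites.
#' @slot deletion either \code{"pairwise"} or \code{"complete"}.
#' @export
setClass("PDistanceMatrix",
         representation(d = "matrix", comparableSites = "matrix",
                        deletion = "character"))

setValidity("PDistanceMatrix", function(object) {
    d <- object@d; L <- object@comparableSites
    msg <- character()
    if (!identical(dim(d), dim(L)) || nrow(d) != ncol(d))
        msg <- c(msg, "d and comparableSites must be square and congruent")
    if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
        msg <- c(msg, "d must carry matching specimen id dimnames")
    if (!isTRUE(all.equal(d, t(d))) || !identical(L, t(L)))
        msg <- c(msg, "matrices must be symmetric")
    if (any(diag(d) != 0, na.rm = TRUE))
        msg <- c(msg, "diagonal distances must be 0")
    off <- upper.tri(d) | lower.tri(d)
    if (any(is.na(d[off]) != (L[off] == 0L)))
        msg <- c(msg, "a distance is NA exactly when no site is comparable")
    dd <- d[!is.na(d)]
    if (length(dd) && (any(dd < 0) || any(dd > 1)))
        msg <- c(msg, "distances must lie in [0, 1]")
    if (!object@deletion %in% c("pairwise", "complete"))
        msg <- c(msg, "deletion must be 'pairwise' or 'complete'")
    if (length(msg)) msg else TRUE
})

#' MotuPartition: single-linkage threshold clustering of specimens
#'
#' Partition of the specimen set into molecular operational taxonomic
#' units (MOTUs): the connected components of the graph joining every
#' specimen pair whose defined p-distance is at most the threshold.
#'
#' @slot membership named integer vector mapping each specimen id to its
#'   MOTU index (1-based, numbered by first appearance in specimen order).
#' @slot threshold the clustering threshold as a proportion (default 0.03).
#' @slot linkage clustering linkage; only \code{"single"} is defined.
#' @export
setClass("MotuPartition",
         representation(membership = "integer", threshold = "numeric",
                        linkage = "character"))

setValidity("MotuPartition", function(object) {
    msg <- character()
    if (is.null(names(object@membership)) ||
        anyDuplicated(names(object@membership)))
        msg <- c(msg, "membership must be named by unique specimen ids")
    k <- length(unique(object@membership))
    if (length(object@membership) &&
        !identical(sort(unique(object@membership)), seq_len(k)))
        msg <- c(msg, "MOTU indices must be 1..k")
    if (length(object@threshold) != 1L || object@threshold <= 0 ||
        object@threshold >= 1)
        msg <- c(msg, "threshold must be a single proportion in (0, 1)")
    if (!identical(object@linkage, "single"))
        msg <- c(msg, "only single linkage is defined")
    if (length(msg)) msg else TRUE
})

#' CandidateSet: flagged candidate-species records
#'
#' One row per flagged lineage: its member specimens, the nominal species
#' it was flagged within, the nearest heterospecific lineage and distance,
#' the monophyly status of the nominal species on the supplied tree (if
#' any), what triggered the flag, the morphology verdict, and the final
#' class (confirmed candidate, unconfirmed candidate, deep conspecific
#' lineage).
#'
#' @slot records \link[S4Vectors]{DataFrame} with columns
#'   \code{candidate_id}, \code{nominal_species}, \code{members}
#'   (comma-separated specimen ids), \code{n_members},
#'   \code{nearest_species}, \code{nearest_distance},
#'   \code{monophyly_status}, \code{trigger}, \code{morphology_verdict},
#'   \code{final_class}.
#' @slot threshold the clustering threshold the flags were derived under.
#' @slot mixedMotus list of character vectors: MOTUs that mix nominal
#'   labels (potential synonymy), reported but never merged.
#' @export
setClass("CandidateSet",
         representation(records = "DataFrame", threshold = "numeric",
                        mixedMotus = "list"))

.CANDIDATE_COLS <- c("candidate_id", "nominal_species", "members",
                     "n_members", "nearest_species", "nearest_distance",
                     "monophyly_status", "trigger", "morphology_verdict",
                     "final_class")

setValidity("CandidateSet", function(object) {
    msg <- character()
    if (!all(.CANDIDATE_COLS %in% colnames(object@records)))
        msg <- c(msg, "records is missing required columns")
    r <- object@records
    ok_class <- c("confirmed_candidate", "unconfirmed_candidate",
                  "deep_conspecific_lineage", "not_classified")
    if (nrow(r) && !all(r$final_class %in% ok_class))
        msg <- c(msg, "invalid final_class value")
    if (nrow(r) && !all(r$trigger %in%
                        c("distance_threshold", "non_monophyly", "both")))
        msg <- c(msg, "invalid trigger value")
    if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the barcode data simulator
#'
#' Describes a simulated study: how many true species, how specimens are
#' allocated, which true species pairs are lumped under one nominal name
#' (cryptic pairs), the Jukes-Cantor divergence targets, and the
#' missing-data process.  See \code{\link{simulationConfig}}.
#'
#' @slot nSpecies number of true species (lineages), outgroup excluded.
#' @slot specimensPerSpecies integer vector of length nSpecies.
#' @slot crypticPairs number of true species pairs sharing a nominal name.
#' @slot crypticDivergence expected p-distance between the two lineages of
#'   each cryptic pair (length crypticPairs), or NA to draw from
#'   \code{interDivergence}.
#' @slot seqLength alignment length in sites.
#' @slot intraDivergence expected within-species p-distance.
#' @slot interDivergence range (lo, hi) of expected between-sister
#'   p-distances.
#' @slot missingRate range (lo, hi) of the per-specimen missing fraction.
#' @slot missingShape Beta(a, b) shape of the missing-fraction draw within
#'   its range; (1, 1) is uniform.
#' @slot missingMode "terminal" (read-end truncation) or "random".
#' @slot ambiguityRate fraction of masked characters written as N (the
#'   rest are written as gaps).
#' @slot morphScenario per-cryptic-pair morphology scenario:
#'   "diagnosable", "identical" or "unscored".
#' @slot mutationScale multiplier applied to every branch length; 0 turns
#'   substitution off entirely (all sequences identical).
#' @slot seed RNG seed (mandatory).
#' @export
setClass("SimulationConfig",
         representation(nSpecies = "integer",
                        specimensPerSpecies = "integer",
                        crypticPairs = "integer",
                        crypticDivergence = "numeric",
                        seqLength = "integer",
                        intraDivergence = "numeric",
                        interDivergence = "numeric",
                        missingRate = "numeric",
                        missingShape = "numeric",
                        missingMode = "character",
                        ambiguityRate = "numeric",
                        morphScenario = "character",
                        mutationScale = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nSpecies < 2L)
        msg <- c(msg, "nSpecies must be at least 2")
    if (length(object@specimensPerSpecies) != object@nSpecies ||
        any(object@specimensPerSpecies < 1L))
        msg <- c(msg, "specimensPerSpecies must give a positive count per species")
    if (object@crypticPairs < 0L ||
        2L * object@crypticPairs > object@nSpecies)
        msg <- c(msg, "crypticPairs must satisfy 0 <= 2*crypticPairs <= nSpecies")
    if (length(object@crypticDivergence) != object@crypticPairs)
        msg <- c(msg, "crypticDivergence must have one value per cryptic pair")
    if (object@seqLength < 1L)
        msg <- c(msg, "seqLength must be positive")
    if (object@intraDivergence < 0 || object@intraDivergence >= 0.75)
        msg <- c(msg, "intraDivergence must be in [0, 0.75)")
    if (length(object@interDivergence) != 2L ||
        any(object@interDivergence <= 0) ||
        diff(object@interDivergence) < 0 ||
        max(object@interDivergence) >= 0.75)
        msg <- c(msg, "interDivergence must be an increasing pair in (0, 0.75)")
    if (object@intraDivergence >= min(object@interDivergence))
        msg <- c(msg, "intraDivergence must be below interDivergence")
    if (length(object@missingRate) != 2L || any(object@missingRate < 0) ||
        any(object@missingRate > 1) || diff(object@missingRate) < 0)
        msg <- c(msg, "missingRate must be an ordered pair in [0, 1]")
    if (length(object@missingShape) != 2L || any(object@missingShape <= 0))
        msg <- c(msg, "missingShape must be two positive Beta parameters")
    if (!object@missingMode %in% c("terminal", "random"))
        msg <- c(msg, "missingMode must be 'terminal' or 'random'")
    if (object@ambiguityRate < 0 || object@ambiguityRate > 1)
        msg <- c(msg, "ambiguityRate must be in [0, 1]")
    if (length(object@morphScenario) != object@crypticPairs ||
        (object@crypticPairs > 0L &&
         !all(object@morphScenario %in%
              c("diagnosable", "identical", "unscored"))))
        msg <- c(msg, "morphScenario must give a valid scenario per cryptic pair")
    if (length(object@mutationScale) != 1L || object@mutationScale < 0)
        msg <- c(msg, "mutationScale must be a single non-negative number")
    if (length(object@seed) != 1L || is.na(object@seed) ||
        object@seed < 0L || object@seed > 2147483600L)
        msg <- c(msg, "seed must be a single integer in [0, 2^31 - 48]")
    if (length(msg)) msg else TRUE
})
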