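#' Cluster specimens into MOTUs by single-linkage threshold clustering
#'
#' Builds the graph joining every specimen pair whose defined p-distance
#' is at most \code{threshold} and returns its connected components as
#' molecular operational taxonomic units (MOTUs).  Lineages are flagged
#' downstream as candidates when their separation from every other
#' cluster exceeds the threshold; comparison uses unrounded distances.
#' Specimens whose distances are all undefined become singletons with a
#' warning.
#'
#' @param dm a \linkS4class{PDistanceMatrix}.
#' @param threshold proportion in (0, 1); default 0.03, the conservative
#'   16S divergence cutoff.
#' @return a \linkS4class{MotuPartition}.
#' @examples
#' aln <- BarcodeAlignment(
#'     c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "AAAAACCCCC"),
#'     data.frame(specimen_id = c("a", "b", "c"),
#'                nominal_species = c("sp1", "sp1", "sp2")))
#' motuClusters(clusterMotus(distanceMatrix(aln), 0.03))
#' @export
clusterMotus <- function(dm, threshold = 0.03) {
    stopifnot(is(dm, "PDistanceMatrix"))
    if (length(threshold) != 1L || threshold <= 0 || threshold >= 1)
        stop("threshold must be a single proportion in (0, 1)")
    d <- dm@d
    ids <- rownames(d)
    adj <- !is.na(d) & d <= threshold
    diag(adj) <- FALSE
    isolated <- ids[rowSums(!is.na(d)) <= 1L]   # only the diagonal defined
    if (length(isolated))
        warning("specimen(s) with no defined distance form singletons: ",
                paste(isolated, collapse = ", "))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    membership <- as.integer(match(comp, unique(comp)))  # number by appearance
    names(membership) <- ids
    new("MotuPartition", membership = membership,
        threshold = threshold, linkage = "single")
}

#' @rdname MotuPartition-class
#' @aliases motuMembership motuClusters thresholdUsed
#' @param object,x a \code{MotuPartition}
#' @export
setMethod("motuMembership", "MotuPartition", function(x) x@membership)

#' @rdname MotuPartition-class
#' @export
setMethod("motuClusters", "MotuPartition", function(x)
    split(names(x@membership), x@membership))

#' @rdname MotuPartition-class
#' @export
setMethod("thresholdUsed", "MotuPartition", function(x) x@threshold)

#' @rdname MotuPartition-class
#' @export
setMethod("specimenIds", "MotuPartition",
          function(x) names(x@membership))

setMethod("show", "MotuPartition", function(object) {
    cat(sprintf("MotuPartition: %d specimens in %d MOTUs at threshold %g (%s linkage)\n",
                length(object@membership),
                length(unique(object@membership)),
                object@threshold, object@linkage))
})

#' Flag candidate species against nominal labels and tree monophyly
#'
#' A nominal species occupying k > 1 MOTUs keeps one \emph{anchor} MOTU
#' (holding its reference specimen if the specimen table marks one via a
#' logical \code{reference} label, else its largest MOTU, ties broken by
#' the lexicographically smallest member id) and its other k - 1 MOTUs
#' are flagged as candidate species with trigger
#' \code{distance_threshold}.  A nominal species that is single-MOTU but
#' paraphyletic or polyphyletic on the supplied tree is flagged once with
#' trigger \code{non_monophyly} (members: all its specimens).  A species
#' satisfying both conditions gets trigger \code{both} on its
#' distance-flagged records.  MOTUs mixing nominal labels (potential
#' synonymy) are reported in the result but never merged.
#'
#' @param partition a \linkS4class{MotuPartition}.
#' @param dm the \linkS4class{PDistanceMatrix} the partition came from;
#'   each record's nearest relative is the closest specimen outside the
#'   flagged lineage (for a split nominal species, typically its own
#'   anchor lineage).
#' @param labels named character vector: specimen id to nominal species.
#' @param treeStatus optional result of assessing each nominal species on
#'   a rooted tree: a named list (per species) as returned by
#'   \code{\link{assessMonophyly}}, or a named character vector of
#'   statuses.  Species absent from it are recorded as
#'   \code{not_assessed}.
#' @param reference optional character vector of reference specimen ids
#'   (anchors for their nominal species).
#' @return a \linkS4class{CandidateSet} with morphology verdicts unset.
#' @export
flagCandidates <- function(partition, dm, labels, treeStatus = NULL,
                           reference = NULL) {
    stopifnot(is(partition, "MotuPartition"), is(dm, "PDistanceMatrix"))
    ids <- specimenIds(partition)
    unlabeled <- setdiff(ids, names(labels))
    if (length(unlabeled))
        stop("label error: unlabeled specimens: ",
             paste(unlabeled, collapse = ", "))
    lab <- stats::setNames(as.character(labels[ids]), ids)
    mem <- motuMembership(partition)
    status <- .treeStatusVector(treeStatus)

    ## mixed-label MOTUs: reported, never merged
    mixed <- Filter(function(s) length(unique(lab[s])) > 1L,
                    motuClusters(partition))
    if (length(mixed))
        warning(length(mixed), " MOTU(s) mix nominal labels ",
                "(potential synonymy); recorded in the candidate set")

    rows <- list()
    for (sp in sort(unique(lab))) {
        spIds <- ids[lab == sp]
        motus <- split(spIds, mem[spIds])
        spStatus <- if (sp %in% names(status)) status[[sp]] else "not_assessed"
        if (length(motus) > 1L) {
            anchor <- .anchorMotu(motus, reference)
            trig <- if (spStatus %in% c("paraphyletic", "polyphyletic"))
                "both" else "distance_threshold"
            for (k in setdiff(names(motus), anchor))
                rows[[length(rows) + 1L]] <-
                    .candidateRow(motus[[k]], sp, dm, lab, spStatus, trig)
        } else if (spStatus %in% c("paraphyletic", "polyphyletic")) {
            rows[[length(rows) + 1L]] <-
                .candidateRow(spIds, sp, dm, lab, spStatus,
                              "non_monophyly")
        }
    }
    records <- .bindCandidateRows(rows)
    new("CandidateSet", records = records,
        threshold = thresholdUsed(partition), mixedMotus = unname(mixed))
}

.treeStatusVector <- function(treeStatus) {
    if (is.null(treeStatus)) return(character())
    if (is.list(treeStatus))
        vapply(treeStatus, function(x)
            if (is.list(x)) x$status else as.character(x), character(1))
    else
        vapply(treeStatus, as.character, character(1))
}

.anchorMotu <- function(motus, reference) {
    if (length(reference)) {
        hasRef <- vapply(motus, function(m) any(m %in% reference),
                         logical(1))
        if (any(hasRef)) return(names(motus)[which(hasRef)[1L]])
    }
    sizes <- lengths(motus)
    best <- names(motus)[sizes == max(sizes)]
    if (length(best) == 1L) return(best)
    firstIds <- vapply(motus[best], function(m) sort(m)[1L], character(1))
    best[order(firstIds)][1L]
}

## Nearest relative of a flagged lineage: the closest specimen outside
## the lineage itself, which for a split nominal species is usually its
## own anchor lineage - exactly the candidate-to-closest-relative
## divergence a barcode survey reports.  Ties go to the
## lexicographically smallest specimen id.
.candidateRow <- function(members, sp, dm, lab, monoStatus, trigger) {
    d <- distances(dm)
    outside <- setdiff(rownames(d), members)
    sub <- d[members, outside, drop = FALSE]
    if (any(!is.na(sub))) {
        nearestD <- min(sub, na.rm = TRUE)
        hits <- which(sub == nearestD, arr.ind = TRUE)
        nearestId <- sort(outside[hits[, "col"]])[1L]
        nearestSp <- unname(lab[nearestId])
    } else {
        nearestSp <- NA_character_; nearestD <- NA_real_
    }
    members <- sort(members)
    DataFrame(candidate_id = NA_character_,
              nominal_species = sp,
              members = paste(members, collapse = ","),
              n_members = length(members),
              nearest_species = nearestSp,
              nearest_distance = nearestD,
              monophyly_status = monoStatus,
              trigger = trigger,
              morphology_verdict = "unset",
              final_class = "not_classified")
}

.bindCandidateRows <- function(rows) {
    if (!length(rows)) {
        records <- DataFrame(candidate_id = character(),
                             nominal_species = character(),
                             members = character(),
                             n_members = integer(),
                             nearest_species = character(),
                             nearest_distance = numeric(),
                             monophyly_status = character(),
                             trigger = character(),
                             morphology_verdict = character(),
                             final_class = character())
        return(records)
    }
    records <- do.call(rbind, rows)
    ## deterministic, diffable ordering: nominal species then smallest id
    ord <- order(records$nominal_species,
                 vapply(strsplit(records$members, ",", fixed = TRUE),
                        `[`, character(1), 1L))
    records <- records[ord, , drop = FALSE]
    records$candidate_id <- sprintf("cand_%02d", seq_len(nrow(records)))
    rownames(records) <- records$candidate_id
    records
}

#' @rdname CandidateSet-class
#' @aliases candidateRecords
#' @param object,x a \code{CandidateSet}
#' @export
setMethod("candidateRecords", "CandidateSet", function(x) x@records)

#' @rdname CandidateSet-class
#' @export
setMethod("length", "CandidateSet", function(x) nrow(x@records))

setMethod("show", "CandidateSet", function(object) {
    tot <- candidateTotals(object)
    cat(sprintf(
        "CandidateSet: %d candidate(s) at threshold %g (%d confirmed, %d unconfirmed, %d DCL, %d unclassified)\n",
        nrow(object@records), object@threshold, tot[["confirmed"]],
        tot[["unconfirmed"]], tot[["deep_conspecific_lineage"]],
        tot[["not_classified"]]))
    if (length(object@mixedMotus))
        cat(sprintf("  %d mixed-label MOTU(s) recorded (potential synonymy)\n",
                    length(object@mixedMotus)))
})

#' Read a morphology character table
#'
#' TSV with a header row: a \code{specimen_id} column plus one column per
#' character.  Column types determine the character kind: integer-valued
#' columns are meristic counts, fractional numeric columns are
#' morphometric ratios (to standard length), text columns are categorical
#' (e.g. a caudal-spot pattern).  Empty cells are unscored.
#'
#' @param path TSV file path.
#' @return data.frame with specimen ids as rownames.
#' @export
readMorphTable <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, encoding = "UTF-8",
                             check.names = FALSE)
    if (!"specimen_id" %in% colnames(tab))
        stop("morphology table needs a 'specimen_id' column")
    if (anyDuplicated(tab$specimen_id))
        stop("duplicate-id error: repeated specimen ids in morphology table")
    rownames(tab) <- tab$specimen_id
    tab$specimen_id <- NULL
    tab
}

.characterKind <- function(v) {
    if (is.numeric(v)) {
        w <- v[!is.na(v)]
        if (length(w) && all(w == round(w))) "meristic" else "morphometric"
    } else "categorical"
}

#' Morphological diagnosability between a candidate and its comparison set
#'
#' A meristic or categorical character is diagnostic when the observed
#' value sets of the two specimen sets are disjoint; a morphometric
#' character is diagnostic when the observed ranges are disjoint.  The
#' overall verdict is \code{concordant} when at least one shared
#' character is diagnostic; \code{discordant} when every shared character
#' overlaps \emph{and} every shared character was scored for at least two
#' specimens on each side; otherwise \code{inconclusive} (insufficient
#' scoring).  No shared scored character yields \code{inconclusive} with
#' a warning.
#'
#' @param candidate,comparison character vectors of specimen ids.
#' @param chars morphology table as returned by
#'   \code{\link{readMorphTable}} (specimen ids as rownames).
#' @return list with \code{verdict} and \code{perCharacter} (DataFrame:
#'   \code{character}, \code{kind}, \code{diagnostic},
#'   \code{n_scored_candidate}, \code{n_scored_comparison}).
#' @export
diagnosability <- function(candidate, comparison, chars) {
    if (!length(candidate) || !length(comparison))
        stop("both specimen sets must be non-empty")
    a <- chars[rownames(chars) %in% candidate, , drop = FALSE]
    b <- chars[rownames(chars) %in% comparison, , drop = FALSE]
    out <- list()
    for (ch in colnames(chars)) {
        va <- a[[ch]][!is.na(a[[ch]]) & a[[ch]] != ""]
        vb <- b[[ch]][!is.na(b[[ch]]) & b[[ch]] != ""]
        if (!length(va) || !length(vb)) next
        kind <- .characterKind(chars[[ch]])
        diagnostic <- if (kind == "morphometric")
            (max(va) < min(vb)) || (max(vb) < min(va))
        else
            !any(va %in% vb)
        out[[length(out) + 1L]] <- DataFrame(
            character = ch, kind = kind, diagnostic = diagnostic,
            n_scored_candidate = length(va),
            n_scored_comparison = length(vb))
    }
    if (!length(out)) {
        warning("no character scored in both specimen sets; ",
                "verdict is inconclusive")
        return(list(verdict = "inconclusive",
                    perCharacter = DataFrame(character = character(),
                                             kind = character(),
                                             diagnostic = logical(),
                                             n_scored_candidate = integer(),
                                             n_scored_comparison = integer())))
    }
    per <- do.call(rbind, out)
    verdict <- if (any(per$diagnostic)) "concordant"
    else if (all(per$n_scored_candidate >= 2L &
                 per$n_scored_comparison >= 2L)) "discordant"
    else "inconclusive"
    list(verdict = verdict, perCharacter = per)
}

#' Classify candidate records from morphology verdicts
#'
#' Applies the fixed mapping: \code{concordant} morphology confirms the
#' candidate (confirmed candidate species), \code{discordant} morphology
#' demotes it to a deep conspecific lineage, and \code{inconclusive} or
#' \code{unavailable} morphology leaves it unconfirmed.
#'
#' @param cs a \linkS4class{CandidateSet}.
#' @param verdicts character vector of per-record verdicts in
#'   \{\code{concordant}, \code{discordant}, \code{inconclusive},
#'   \code{unavailable}\}; either named by \code{candidate_id} or
#'   positional (one per record).
#' @return the \linkS4class{CandidateSet} with \code{morphology_verdict}
#'   and \code{final_class} filled in.
#' @export
classifyCandidates <- function(cs, verdicts) {
    stopifnot(is(cs, "CandidateSet"))
    r <- cs@records
    if (nrow(r) == 0L) return(cs)
    ok <- c("concordant", "discordant", "inconclusive", "unavailable")
    if (!is.null(names(verdicts))) {
        missing <- setdiff(r$candidate_id, names(verdicts))
        if (length(missing))
            stop("missing verdict for: ", paste(missing, collapse = ", "))
        v <- as.character(verdicts[r$candidate_id])
    } else {
        if (length(verdicts) != nrow(r))
            stop("need exactly one verdict per candidate record")
        v <- as.character(verdicts)
    }
    if (!all(v %in% ok))
        stop("invalid verdict(s): ",
             paste(unique(v[!v %in% ok]), collapse = ", "))
    r$morphology_verdict <- v
    r$final_class <- ifelse(v == "concordant", "confirmed_candidate",
                     ifelse(v == "discordant", "deep_conspecific_lineage",
                            "unconfirmed_candidate"))
    new("CandidateSet", records = r, threshold = cs@threshold,
        mixedMotus = cs@mixedMotus)
}

#' Totals of a candidate set by final class
#'
#' @param cs a \linkS4class{CandidateSet}.
#' @return named integer vector: \code{confirmed}, \code{unconfirmed},
#'   \code{deep_conspecific_lineage}, \code{not_classified}, \code{total}.
#' @export
candidateTotals <- function(cs) {
    stopifnot(is(cs, "CandidateSet"))
    fc <- cs@records$final_class
    c(confirmed = sum(fc == "confirmed_candidate"),
      unconfirmed = sum(fc == "unconfirmed_candidate"),
      deep_conspecific_lineage = sum(fc == "deep_conspecific_lineage"),
      not_classified = sum(fc == "not_classified"),
      total = length(fc))
}

#' MOTU and candidate counts across a threshold sweep
#'
#' Re-clusters the same distance matrix at each threshold and reports the
#' MOTU count and the number of distance-flagged candidates, to show how
#' sensitive the delimitation is to the cutoff choice.
#'
#' @param dm a \linkS4class{PDistanceMatrix}.
#' @param labels named specimen-to-species vector.
#' @param thresholds numeric vector of proportions (default 0.01 to 0.11
#'   by 0.01).
#' @return DataFrame with columns \code{threshold}, \code{n_motus},
#'   \code{n_candidates}.
#' @export
thresholdSweep <- function(dm, labels,
                           thresholds = seq(0.01, 0.11, by = 0.01)) {
    rows <- lapply(thresholds, function(t) {
        part <- suppressWarnings(clusterMotus(dm, t))
        cs <- suppressWarnings(flagCandidates(part, dm, labels))
        DataFrame(threshold = t,
                  n_motus = length(unique(motuMembership(part))),
                  n_candidates = nrow(candidateRecords(cs)))
    })
    do.call(rbind, rows)
}
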