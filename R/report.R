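#' Species-richness increase from candidate counts
#'
#' Two explicit conventions are provided because both appear in
#' cross-study comparisons of cryptic diversity: the increase over the
#' described species (\code{over_described}: 100 U / D, as in rows like
#' "200\% (1D/2U)") and the increase over the sampled species pool
#' (\code{over_sampled}: 100 U / (D + U), as in a headline "8 candidates
#' among 33 sampled = 24\%").  The two agree only when U = 0; reports
#' print both, labelled, so the convention is never implicit.
#'
#' @param D described species count.
#' @param U undescribed (candidate) species count.
#' @param mode \code{"over_described"} or \code{"over_sampled"}.
#' @return list with the unrounded \code{percent} and the
#'   nearest-integer \code{display} value.
#' @examples
#' richnessIncrease(25, 8, "over_sampled")$display   # 24
#' richnessIncrease(1, 2, "over_described")$display  # 200
#' @export
richnessIncrease <- function(D, U, mode = c("over_described",
                                            "over_sampled")) {
    mode <- match.arg(mode)
    if (D < 0 || U < 0) stop("counts must be non-negative")
    denom <- if (mode == "over_described") D else D + U
    if (denom < 1) stop("config error: division by zero (", mode,
                        " needs ", if (mode == "over_described")
                            "D >= 1" else "D + U >= 1", ")")
    pct <- 100 * U / denom
    list(percent = pct, display = round(pct))
}

#' Projected basin-wide richness from an increase-rate range
#'
#' Applies a low and a high relative increase to a baseline described
#' richness.  Display values follow the reporting convention of rounding
#' the low endpoint to the nearest 10 and the high endpoint to the
#' nearest 100; the unrounded products are retained.
#'
#' @param B baseline described species richness.
#' @param rLo,rHi low and high increase rates (proportions, rLo <= rHi).
#' @return list with \code{low}, \code{high} (unrounded) and
#'   \code{lowDisplay}, \code{highDisplay}.
#' @examples
#' richnessProjection(2173, 0.24, 2.0)[c("lowDisplay", "highDisplay")]
#' @export
richnessProjection <- function(B, rLo, rHi) {
    if (B < 0 || rLo < 0 || rHi < rLo)
        stop("need B >= 0 and 0 <= rLo <= rHi")
    low <- B * rLo; high <- B * rHi
    list(low = low, high = high,
         lowDisplay = round(low / 10) * 10,
         highDisplay = round(high / 100) * 100)
}

.REPORT_SCHEMA <- "barcode-delim-report/1"

#' Run the full delimitation pipeline
#'
#' Chains every stage: alignment statistics, the p-distance matrix,
#' single-linkage MOTU clustering at the threshold, optional monophyly
#' assessment of every nominal species on a supplied tree (rooted on
#' \code{outgroup} if given), candidate flagging, morphology verdicts
#' (computed by \code{\link{diagnosability}} against the anchor MOTU of
#' the same nominal species when a morphology table is supplied;
#' user-supplied verdicts override computed ones, with both retained),
#' final classification, richness statistics in both conventions, and an
#' optional threshold sweep.
#'
#' @param aln a \linkS4class{BarcodeAlignment}.
#' @param tree optional \code{phylo} on (a subset of) the specimens.
#' @param outgroup optional outgroup label(s) used to root \code{tree};
#'   specimens named in it are excluded from the nominal species pool.
#' @param threshold clustering threshold (default 0.03).
#' @param deletion \code{"pairwise"} or \code{"complete"}.
#' @param morph optional morphology table
#'   (\code{\link{readMorphTable}}).
#' @param verdicts optional named character vector of user-supplied
#'   morphology verdicts per candidate id (overrides computed ones).
#' @param sweep optional numeric vector of thresholds for a sensitivity
#'   sweep.
#' @param excludeFromRichness specimen labels (nominal species names)
#'   never counted as sampled species; defaults to \code{"OUTGROUP"}.
#' @return a \code{DelimitationReport}: a list with elements
#'   \code{schema}, \code{provenance}, \code{alignmentStats},
#'   \code{motus}, \code{monophyly}, \code{candidates} (a
#'   \linkS4class{CandidateSet}), \code{totals}, \code{richness} and
#'   optionally \code{sweep}.
#' @export
runDelimitation <- function(aln, tree = NULL, outgroup = NULL,
                            threshold = 0.03,
                            deletion = c("pairwise", "complete"),
                            morph = NULL, verdicts = NULL, sweep = NULL,
                            excludeFromRichness = "OUTGROUP") {
    stopifnot(is(aln, "BarcodeAlignment"))
    deletion <- match.arg(deletion)
    stats <- alignmentStats(aln)
    dm <- distanceMatrix(aln, deletion = deletion)
    part <- suppressWarnings(clusterMotus(dm, threshold))
    labels <- nominalSpecies(aln)

    monophyly <- NULL
    if (!is.null(tree)) {
        if (!is.null(outgroup)) tree <- rootWithOutgroup(tree, outgroup)
        if (!ape::is.rooted(tree))
            stop("supply a rooted tree or an outgroup to root it with")
        monophyly <- .assessAllSpecies(tree, labels, outgroup)
    }

    sd <- specimenData(aln)
    reference <- if ("reference" %in% colnames(sd))
        rownames(sd)[as.logical(sd$reference)] else NULL
    cs <- suppressWarnings(
        flagCandidates(part, dm, labels, treeStatus = monophyly,
                       reference = reference))
    v <- .resolveVerdicts(cs, part, labels, morph, verdicts, reference)
    cs <- classifyCandidates(cs, v$applied)
    tot <- candidateTotals(cs)

    sampled <- setdiff(unique(labels), excludeFromRichness)
    U <- unname(tot[["total"]])
    S <- length(sampled)
    richness <- list(
        sampled_species = S,
        candidates = U,
        over_sampled = if (S >= 1 && U <= S)
            richnessIncrease(S - U, U, "over_sampled") else NULL,
        over_described = if (S - U >= 1)
            richnessIncrease(S - U, U, "over_described") else NULL)

    sweepTab <- if (!is.null(sweep))
        thresholdSweep(dm, labels, sweep) else NULL

    report <- list(
        schema = .REPORT_SCHEMA,
        provenance = list(
            tool = "BarcodeDelim",
            version = as.character(utils::packageVersion("BarcodeDelim")),
            threshold = threshold, deletion = deletion,
            n_specimens = nSpecimens(aln), n_sites = nSites(aln),
            tree_supplied = !is.null(tree),
            morphology_supplied = !is.null(morph),
            user_verdicts = v$user,
            anchor_rule = paste(
                "reference specimen if marked; else largest MOTU;",
                "ties to the MOTU with the lexicographically smallest id"),
            paraphyly_rule = paste(
                "intruder set forming exactly one clade = paraphyletic;",
                "more than one = polyphyletic")),
        alignmentStats = stats,
        motus = part,
        monophyly = monophyly,
        candidates = cs,
        totals = tot,
        richness = richness,
        sweep = sweepTab)
    class(report) <- "DelimitationReport"
    report
}

.assessAllSpecies <- function(tree, labels, outgroup) {
    species <- setdiff(unique(labels), c("OUTGROUP", outgroup))
    out <- list()
    for (sp in sort(species)) {
        grp <- intersect(names(labels)[labels == sp], tree$tip.label)
        out[[sp]] <- if (length(grp))
            assessMonophyly(tree, grp)
        else list(status = "not_assessed", intruders = character())
    }
    out
}

## Verdict per candidate record: user-supplied wins; else morphology
## table diagnosability of candidate members against the anchor-MOTU
## members of the same nominal species; else "unavailable".
.resolveVerdicts <- function(cs, part, labels, morph, verdicts,
                             reference) {
    r <- candidateRecords(cs)
    if (nrow(r) == 0L)
        return(list(applied = character(), user = list()))
    applied <- stats::setNames(rep("unavailable", nrow(r)),
                               r$candidate_id)
    user <- list()
    mem <- motuMembership(part)
    for (i in seq_len(nrow(r))) {
        id <- r$candidate_id[i]
        members <- strsplit(r$members[i], ",", fixed = TRUE)[[1L]]
        if (!is.null(verdicts) && id %in% names(verdicts)) {
            applied[id] <- verdicts[[id]]
            user[[id]] <- verdicts[[id]]
            next
        }
        if (is.null(morph)) next
        spIds <- names(labels)[labels == r$nominal_species[i]]
        comparison <- setdiff(spIds, members)
        if (r$trigger[i] != "non_monophyly" && length(comparison)) {
            ## compare against the anchor MOTU only
            anchorIds <- comparison[mem[comparison] ==
                                    .majorityMotu(mem, comparison,
                                                  reference)]
            if (length(anchorIds)) comparison <- anchorIds
        }
        scored <- function(idset) {
            rows <- morph[rownames(morph) %in% idset, , drop = FALSE]
            nrow(rows) > 0L && any(!is.na(rows) & rows != "")
        }
        if (!length(comparison) || !scored(members) || !scored(comparison))
            next                                  # stays "unavailable"
        applied[id] <- suppressWarnings(
            diagnosability(members, comparison, morph)$verdict)
    }
    list(applied = applied, user = user)
}

.majorityMotu <- function(mem, ids, reference) {
    if (length(reference)) {
        ref <- intersect(ids, reference)
        if (length(ref)) return(mem[[ref[1L]]])
    }
    tab <- table(mem[ids])
    as.integer(names(tab)[which.max(tab)])
}

#' @export
print.DelimitationReport <- function(x, ...) {
    cat("== Species delimitation report ==\n")
    print(x$alignmentStats)
    show(x$motus)
    show(x$candidates)
    tot <- x$totals
    if (tot[["total"]] == 0L) cat("No candidate species flagged.\n")
    rich <- x$richness
    if (!is.null(rich$over_sampled))
        cat(sprintf("Richness increase over sampled pool: %d%% (%d among %d)\n",
                    rich$over_sampled$display, rich$candidates,
                    rich$sampled_species))
    if (!is.null(rich$over_described))
        cat(sprintf("Richness increase over described species: %d%%\n",
                    rich$over_described$display))
    invisible(x)
}

#' Serialise / read a delimitation report
#'
#' The JSON form carries a schema tag and every machine-readable field at
#' full precision; \code{readReportJSON} validates the schema and the
#' presence of the required blocks on read, so a round trip preserves all
#' totals.
#'
#' @param report a \code{DelimitationReport}.
#' @param path file path.
#' @return \code{writeReportJSON}: \code{path}, invisibly.
#'   \code{readReportJSON}: the parsed report list.
#' @export
writeReportJSON <- function(report, path) {
    stopifnot(inherits(report, "DelimitationReport"))
    st <- report$alignmentStats
    out <- list(
        schema = report$schema,
        provenance = report$provenance,
        alignment = list(
            n_terminals = st$nTerminals, n_sites = st$nSites,
            n_invariable = st$nInvariable, n_variable = st$nVariable,
            n_parsimony_informative = st$nParsimonyInformative,
            pct_invariable = st$pctInvariable,
            missing_mean = st$missingMean, missing_min = st$missingMin,
            missing_max = st$missingMax),
        motus = list(
            threshold = thresholdUsed(report$motus),
            n_motus = length(unique(motuMembership(report$motus))),
            membership = as.list(motuMembership(report$motus))),
        monophyly = lapply(report$monophyly, function(x)
            list(status = x$status, intruders = x$intruders)),
        candidates = as.data.frame(candidateRecords(report$candidates)),
        totals = as.list(report$totals),
        richness = report$richness,
        sweep = if (!is.null(report$sweep))
            as.data.frame(report$sweep) else NULL)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname writeReportJSON
#' @export
readReportJSON <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(x$schema, .REPORT_SCHEMA))
        stop("unsupported report schema: ",
             if (is.null(x$schema)) "<missing>" else x$schema)
    required <- c("provenance", "alignment", "motus", "candidates",
                  "totals", "richness")
    absent <- setdiff(required, names(x))
    if (length(absent))
        stop("dependency error: report is missing stage(s): ",
             paste(absent, collapse = ", "))
    x
}

#' Plain-text rendering of a delimitation report
#'
#' @param report a \code{DelimitationReport}.
#' @return character vector of report lines.
#' @export
formatReportText <- function(report) {
    stopifnot(inherits(report, "DelimitationReport"))
    con <- textConnection("lines", "w", local = TRUE)
    sink(con); on.exit({ sink(); close(con) })
    print(report)
    r <- as.data.frame(candidateRecords(report$candidates))
    if (nrow(r)) {
        cat("\nCandidates (ordered by nominal species, then first member):\n")
        for (i in seq_len(nrow(r)))
            cat(sprintf(
                "  %s  %s  n=%d  nearest=%s d=%s  tree=%s  trigger=%s  morphology=%s  class=%s\n",
                r$candidate_id[i], r$nominal_species[i], r$n_members[i],
                r$nearest_species[i],
                ifelse(is.na(r$nearest_distance[i]), "NA",
                       sprintf("%.1f%%", 100 * r$nearest_distance[i])),
                r$monophyly_status[i], r$trigger[i],
                r$morphology_verdict[i], r$final_class[i]))
    }
    sink(); close(con); on.exit()
    lines
}
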