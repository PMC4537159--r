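#' Uncorrected p-distance between two aligned sequences
#'
#' Compares only the sites where both sequences carry an unambiguous base
#' (A/C/G/T); gaps, \code{N}, \code{?} and partial ambiguity codes are
#' excluded (pairwise deletion), never counted as a fifth state.  The
#' distance is the proportion of differing bases among the comparable
#' sites, \code{NA} if no site is comparable.
#'
#' @param x,y aligned sequences of equal length: single strings or
#'   character vectors of single characters.
#' @return list with \code{distance} (proportion or \code{NA}) and
#'   \code{comparable} (site count).
#' @examples
#' pDistance("ACGTACGTAC", "ACGTACGTAA")  # 1 mismatch over 10 sites
#' @export
pDistance <- function(x, y) {
    x <- .asChars(x); y <- .asChars(y)
    if (length(x) != length(y))
        stop("alignment-shape error: sequences have unequal lengths (",
             length(x), " vs ", length(y), ")")
    bases <- c("A", "C", "G", "T")
    ok <- x %in% bases & y %in% bases
    comparable <- sum(ok)
    d <- if (comparable == 0L) NA_real_ else
        sum(x[ok] != y[ok]) / comparable
    list(distance = d, comparable = comparable)
}

.asChars <- function(s) {
    if (length(s) == 1L && nchar(s) > 1L)
        s <- strsplit(s, "", fixed = TRUE)[[1L]]
    toupper(s)
}

#' Pairwise p-distance matrix for an alignment
#'
#' Applies \code{\link{pDistance}} to every specimen pair.  Under
#' \code{deletion = "pairwise"} each pair excludes only its own ambiguous
#' sites; under \code{deletion = "complete"} every column containing any
#' ambiguous character in any specimen is dropped before comparison, so
#' all pairs share one site set.
#'
#' Internally the mismatch counts are obtained from base-indicator
#' cross-products, so the full matrix for a few hundred specimens takes a
#' fraction of a second; the result is exact (counts are integers).
#'
#' @param aln a \linkS4class{BarcodeAlignment}.
#' @param deletion \code{"pairwise"} (default) or \code{"complete"}.
#' @return a \linkS4class{PDistanceMatrix}.
#' @export
distanceMatrix <- function(aln, deletion = c("pairwise", "complete")) {
    stopifnot(is(aln, "BarcodeAlignment"))
    deletion <- match.arg(deletion)
    m <- aln@seqs
    if (deletion == "complete") {
        keep <- colSums(matrix(m %in% c("A", "C", "G", "T"),
                               nrow = nrow(m))) == nrow(m)
        m <- m[, keep, drop = FALSE]
    }
    bases <- c("A", "C", "G", "T")
    ind <- lapply(bases, function(b) (m == b) * 1)
    anyBase <- Reduce(`+`, ind)
    L <- tcrossprod(anyBase)                       # comparable sites
    matches <- Reduce(`+`, lapply(ind, tcrossprod))
    mismatch <- L - matches
    d <- ifelse(L > 0, mismatch / L, NA_real_)
    diag(d)[diag(L) == 0] <- 0                     # self-distance is 0
    storage.mode(L) <- "integer"
    dimnames(d) <- dimnames(L) <- list(rownames(m), rownames(m))
    new("PDistanceMatrix", d = d, comparableSites = L,
        deletion = deletion)
}

#' @rdname PDistanceMatrix-class
#' @aliases distances comparableSites
#' @param object,x a \code{PDistanceMatrix}
#' @export
setMethod("distances", "PDistanceMatrix", function(x) x@d)

#' @rdname PDistanceMatrix-class
#' @export
setMethod("comparableSites", "PDistanceMatrix",
          function(x) x@comparableSites)

#' @rdname PDistanceMatrix-class
#' @export
setMethod("specimenIds", "PDistanceMatrix", function(x) rownames(x@d))

setMethod("show", "PDistanceMatrix", function(object) {
    n <- nrow(object@d)
    undef <- sum(is.na(object@d[upper.tri(object@d)]))
    cat(sprintf(
        "PDistanceMatrix: %d specimens, %s deletion, %d undefined pair(s)\n",
        n, object@deletion, undef))
})

#' Nearest heterospecific specimen and minimum between-species linkage
#'
#' For every specimen, finds the closest specimen carrying a different
#' nominal label (undefined distances are skipped; exact ties go to the
#' lexicographically smallest specimen id).  Also returns, for every pair
#' of nominal species, the minimum defined distance across all
#' between-species specimen pairs.
#'
#' @param dm a \linkS4class{PDistanceMatrix}.
#' @param labels named character vector: specimen id to nominal species.
#'   Every specimen in \code{dm} must be labelled.
#' @return list with \code{perSpecimen} (DataFrame: \code{specimen},
#'   \code{species}, \code{nearest}, \code{nearest_species},
#'   \code{distance}) and \code{groupPairMin} (species x species numeric
#'   matrix, \code{NA} where no pair is comparable).
#' @export
nearestHeterospecific <- function(dm, labels) {
    stopifnot(is(dm, "PDistanceMatrix"))
    ids <- specimenIds(dm)
    unlabeled <- setdiff(ids, names(labels))
    if (length(unlabeled))
        stop("label error: unlabeled specimens: ",
             paste(unlabeled, collapse = ", "))
    lab <- as.character(labels[ids])
    d <- dm@d
    nearest <- character(length(ids))
    nearestSp <- character(length(ids))
    dist <- rep(NA_real_, length(ids))
    anyUndef <- FALSE
    for (i in seq_along(ids)) {
        other <- which(lab != lab[i] & !is.na(d[i, ]))
        if (!length(other)) {
            nearest[i] <- NA_character_; nearestSp[i] <- NA_character_
            if (any(lab != lab[i])) anyUndef <- TRUE
            next
        }
        dmin <- min(d[i, other])
        cand <- ids[other[d[i, other] == dmin]]
        nearest[i] <- sort(cand)[1L]
        nearestSp[i] <- lab[match(nearest[i], ids)]
        dist[i] <- dmin
    }
    if (anyUndef)
        warning("some specimens have no defined heterospecific distance")
    species <- sort(unique(lab))
    gp <- matrix(NA_real_, length(species), length(species),
                 dimnames = list(species, species))
    for (a in seq_along(species)) for (b in seq_along(species)) {
        if (a >= b) next
        dd <- d[lab == species[a], lab == species[b], drop = FALSE]
        if (any(!is.na(dd)))
            gp[a, b] <- gp[b, a] <- min(dd, na.rm = TRUE)
    }
    diag(gp) <- 0
    list(perSpecimen = DataFrame(specimen = ids, species = lab,
                                 nearest = nearest,
                                 nearest_species = nearestSp,
                                 distance = dist),
         groupPairMin = gp)
}

#' Write / read a distance matrix
#'
#' Two on-disk forms are supported: a square TSV (specimen ids as header
#' and first column) and a relaxed PHYLIP matrix (taxon count on the
#' first line, then one row per specimen: id followed by whitespace-
#' separated values).  Undefined distances are written as \code{NA}.
#' Values are written with six decimals; a write/read round trip is
#' lossless at that precision.
#'
#' @param dm a \linkS4class{PDistanceMatrix}.
#' @param path output/input file path.
#' @param format \code{"tsv"} or \code{"phylip"}.
#' @return \code{writeDistanceMatrix} returns \code{path} invisibly;
#'   \code{readDistanceMatrix} returns a numeric matrix with specimen id
#'   dimnames (comparable-site counts are not serialised).
#' @export
writeDistanceMatrix <- function(dm, path, format = c("tsv", "phylip")) {
    stopifnot(is(dm, "PDistanceMatrix"))
    format <- match.arg(format)
    d <- dm@d
    fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
    if (format == "tsv") {
        lines <- c(paste(c("specimen_id", rownames(d)), collapse = "\t"),
                   vapply(seq_len(nrow(d)), function(i)
                       paste(c(rownames(d)[i], fmt(d[i, ])),
                             collapse = "\t"), character(1)))
    } else {
        lines <- c(as.character(nrow(d)),
                   vapply(seq_len(nrow(d)), function(i)
                       paste(c(rownames(d)[i], fmt(d[i, ])),
                             collapse = " "), character(1)))
    }
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path, format = c("tsv", "phylip")) {
    format <- match.arg(format)
    lines <- readLines(path)
    if (format == "tsv") {
        ids <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
        body <- lines[-1L]
        sep <- "\t"
    } else {
        n <- as.integer(lines[1L])
        body <- lines[1L + seq_len(n)]
        sep <- "\\s+"
        ids <- vapply(strsplit(body, sep), `[`, character(1), 1L)
    }
    rows <- strsplit(body, sep)
    d <- t(vapply(rows, function(r)
        suppressWarnings(as.numeric(r[-1L])), numeric(length(ids))))
    dimnames(d) <- list(vapply(rows, `[`, character(1), 1L), ids)
    d
}
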