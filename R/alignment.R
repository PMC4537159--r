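#' Construct a BarcodeAlignment from sequences and specimen annotations
#'
#' @param seqs named character vector of equal-length aligned sequences,
#'   or a character matrix of single characters with specimen rownames.
#' @param specimenData data.frame or \link[S4Vectors]{DataFrame} with a
#'   \code{specimen_id} column (or rownames) and a \code{nominal_species}
#'   column; every sequence id must appear exactly once.
#' @return a validated \linkS4class{BarcodeAlignment}.  Sequences are
#'   case-folded to upper case and \code{U} is normalised to \code{T}.
#' @examples
#' aln <- BarcodeAlignment(
#'     c(s1 = "ACGT", s2 = "ACGA"),
#'     data.frame(specimen_id = c("s1", "s2"),
#'                nominal_species = c("spA", "spA")))
#' nSites(aln)
#' @export
BarcodeAlignment <- function(seqs, specimenData) {
    if (is.matrix(seqs)) {
        m <- seqs
    } else {
        if (is.null(names(seqs)))
            stop("sequences must be named by specimen id")
        lens <- nchar(seqs)
        if (length(unique(lens)) != 1L)
            stop("alignment-shape error: rows have unequal lengths (",
                 paste(unique(lens), collapse = ", "), ")")
        m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
        rownames(m) <- names(seqs)
    }
    m[] <- toupper(m)
    m[m == "U"] <- "T"
    sd <- .asSpecimenData(specimenData, rownames(m))
    new("BarcodeAlignment", seqs = m, specimenData = sd)
}

.asSpecimenData <- function(specimenData, ids) {
    sd <- as(as.data.frame(specimenData), "DataFrame")
    if ("specimen_id" %in% colnames(sd)) {
        rownames(sd) <- as.character(sd$specimen_id)
        sd$specimen_id <- NULL
    }
    if (anyDuplicated(rownames(sd)))
        stop("duplicate-id error: repeated specimen ids in specimen table")
    missing <- setdiff(ids, rownames(sd))
    if (length(missing))
        stop("label error: specimen table lacks entries for: ",
             paste(missing, collapse = ", "))
    sd[ids, , drop = FALSE]
}

#' Read an aligned FASTA plus a specimen table
#'
#' The FASTA may be line-wrapped; the record id is the header token up to
#' the first whitespace.  The specimen table is a UTF-8 TSV with a header
#' row and at least the columns \code{specimen_id} and
#' \code{nominal_species}; an optional logical \code{reference} column
#' marks anchor specimens.  Every FASTA id must appear in the table.
#' Rows of unequal length, duplicate ids and non-IUPAC characters are
#' errors, never silently repaired.
#'
#' @param fasta path to the aligned FASTA file.
#' @param specimens path to the specimen TSV.
#' @return a \linkS4class{BarcodeAlignment}.
#' @export
readAlignment <- function(fasta, specimens) {
    if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
    if (!file.exists(specimens))
        stop("specimen table not found: ", specimens)
    seqs <- Biostrings::readBStringSet(fasta)
    ids <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(ids))
        stop("duplicate-id error: repeated FASTA ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    v <- as.character(seqs)
    names(v) <- ids
    tab <- utils::read.delim(specimens, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, encoding = "UTF-8",
                             check.names = FALSE)
    if (!all(c("specimen_id", "nominal_species") %in% colnames(tab)))
        stop("specimen table needs 'specimen_id' and 'nominal_species' columns")
    aln <- BarcodeAlignment(v, tab)
    validObject(aln)
    aln
}

#' @rdname BarcodeAlignment-class
#' @aliases specimenIds nominalSpecies nSpecimens nSites alignmentMatrix
#'   specimenData
#' @param object,x a \code{BarcodeAlignment}
#' @export
setMethod("specimenIds", "BarcodeAlignment",
          function(x) rownames(x@seqs))

#' @rdname BarcodeAlignment-class
#' @export
setMethod("nominalSpecies", "BarcodeAlignment", function(x) {
    stats::setNames(as.character(x@specimenData$nominal_species),
                    rownames(x@seqs))
})

#' @rdname BarcodeAlignment-class
#' @export
setMethod("nSpecimens", "BarcodeAlignment", function(x) nrow(x@seqs))

#' @rdname BarcodeAlignment-class
#' @export
setMethod("nSites", "BarcodeAlignment", function(x) ncol(x@seqs))

#' @rdname BarcodeAlignment-class
#' @export
setMethod("alignmentMatrix", "BarcodeAlignment", function(x) x@seqs)

#' @rdname BarcodeAlignment-class
#' @export
setMethod("specimenData", "BarcodeAlignment", function(x) x@specimenData)

setMethod("show", "BarcodeAlignment", function(object) {
    cat(sprintf("BarcodeAlignment: %d specimens x %d sites, %d nominal species\n",
                nSpecimens(object), nSites(object),
                length(unique(nominalSpecies(object)))))
})

#' Classify alignment sites
#'
#' Censuses the unambiguous states (A/C/G/T) in every column; gaps, N, ?
#' and partial ambiguity codes are ignored rather than expanded.  A site
#' is \emph{variable} if at least two distinct unambiguous states occur,
#' \emph{invariable} if exactly one occurs, and
#' \emph{uninformative_other} if none does.  A site is
#' parsimony-informative if at least two distinct unambiguous states each
#' occur in at least two rows.
#'
#' @param aln a \linkS4class{BarcodeAlignment}.
#' @return \link[S4Vectors]{DataFrame} with one row per site: columns
#'   \code{site}, \code{category} and \code{parsimony_informative}.
#' @export
classifySites <- function(aln) {
    stopifnot(is(aln, "BarcodeAlignment"))
    m <- aln@seqs
    bases <- c("A", "C", "G", "T")
    counts <- vapply(bases, function(b) colSums(m == b),
                     numeric(ncol(m)))
    if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
    nStates <- rowSums(counts > 0)
    category <- ifelse(nStates >= 2L, "variable",
                       ifelse(nStates == 1L, "invariable",
                              "uninformative_other"))
    DataFrame(site = seq_len(ncol(m)),
              category = category,
              parsimony_informative = rowSums(counts >= 2L) >= 2L)
}

#' Alignment summary statistics
#'
#' Computes the matrix-level summaries used to describe a barcode
#' alignment: terminal and site counts, the site-classification tallies
#' of \code{\link{classifySites}}, and per-specimen missing-data
#' percentages, where "missing" covers gaps, \code{?}, \code{N} and all
#' partial ambiguity codes.  Percentages are computed on unrounded values
#' and displayed to one decimal.
#'
#' @param aln a \linkS4class{BarcodeAlignment}.
#' @return an object of class \code{AlignmentStats}: a list with elements
#'   \code{nTerminals}, \code{nSites}, \code{nInvariable},
#'   \code{nVariable}, \code{nUninformativeOther},
#'   \code{nParsimonyInformative}, \code{pctInvariable},
#'   \code{missingMean}, \code{missingMin}, \code{missingMax} and the
#'   per-specimen vector \code{missingBySpecimen}.
#' @export
alignmentStats <- function(aln) {
    stopifnot(is(aln, "BarcodeAlignment"))
    sites <- classifySites(aln)
    m <- aln@seqs
    missing <- rowSums(matrix(m %in% .MISSING_CHARS, nrow = nrow(m)))
    pctMissing <- 100 * missing / ncol(m)
    names(pctMissing) <- rownames(m)
    out <- list(
        nTerminals = nrow(m),
        nSites = ncol(m),
        nInvariable = sum(sites$category == "invariable"),
        nVariable = sum(sites$category == "variable"),
        nUninformativeOther = sum(sites$category == "uninformative_other"),
        nParsimonyInformative = sum(sites$parsimony_informative),
        pctInvariable = 100 * sum(sites$category == "invariable") / ncol(m),
        missingMean = mean(pctMissing),
        missingMin = min(pctMissing),
        missingMax = max(pctMissing),
        missingBySpecimen = pctMissing)
    class(out) <- "AlignmentStats"
    out
}

#' @export
print.AlignmentStats <- function(x, ...) {
    cat(sprintf("Alignment: %d terminals, %d sites\n",
                x$nTerminals, x$nSites))
    cat(sprintf("  invariable sites:           %d (%.1f%%)\n",
                x$nInvariable, x$pctInvariable))
    cat(sprintf("  variable sites:             %d\n", x$nVariable))
    cat(sprintf("  parsimony-informative:      %d\n",
                x$nParsimonyInformative))
    cat(sprintf("  no unambiguous state:       %d\n",
                x$nUninformativeOther))
    cat(sprintf("  missing data: mean %.1f%% (range %.1f to %.1f)\n",
                x$missingMean, x$missingMin, x$missingMax))
    invisible(x)
}
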