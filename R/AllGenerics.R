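#' @rdname BarcodeAlignment-class
#' @param x an object
#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("nominalSpecies", function(x) standardGeneric("nominalSpecies"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("nSpecimens", function(x) standardGeneric("nSpecimens"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("specimenData", function(x) standardGeneric("specimenData"))

#' @rdname PDistanceMatrix-class
#' @param x an object
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname PDistanceMatrix-class
#' @export
setGeneric("comparableSites",
           function(x) standardGeneric("comparableSites"))

#' @rdname MotuPartition-class
#' @param x an object
#' @export
setGeneric("motuMembership", function(x) standardGeneric("motuMembership"))

#' @rdname MotuPartition-class
#' @export
setGeneric("motuClusters", function(x) standardGeneric("motuClusters"))

#' @rdname MotuPartition-class
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))

#' @rdname CandidateSet-class
#' @param x an object
#' @export
setGeneric("candidateRecords",
           function(x) standardGeneric("candidateRecords"))
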