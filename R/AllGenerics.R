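#' @rdname EDNADataset-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname EDNADataset-accessors
#' @export
setGeneric("nDualSites", function(x) standardGeneric("nDualSites"))

#' @rdname EDNADataset-accessors
#' @export
setGeneric("siteIDs", function(x) standardGeneric("siteIDs"))

#' @rdname EDNADataset-accessors
#' @export
setGeneric("dualSiteIDs", function(x) standardGeneric("dualSiteIDs"))

#' @rdname EDNADataset-accessors
#' @export
setGeneric("ednaOnlyIDs", function(x) standardGeneric("ednaOnlyIDs"))

#' @rdname EDNADataset-accessors
#' @export
setGeneric("replicateCounts", function(x) standardGeneric("replicateCounts"))

#' @rdname EDNADataset-accessors
#' @export
setGeneric("siteDensities", function(x) standardGeneric("siteDensities"))

#' @rdname EDNADataset-accessors
#' @export
setGeneric("edna", function(x) standardGeneric("edna"))

#' @rdname EDNADataset-accessors
#' @export
setGeneric("ednaUnit", function(x) standardGeneric("ednaUnit"))

#' @rdname modelFamily
#' @export
setGeneric("modelFamily", function(x) standardGeneric("modelFamily"))

#' @rdname predictDensities
#' @export
setGeneric("predictDensities", function(object, ...)
  standardGeneric("predictDensities"))

#' @rdname EDNACV-accessors
#' @export
setGeneric("cvRecords", function(x) standardGeneric("cvRecords"))

#' @rdname EDNACV-accessors
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))
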