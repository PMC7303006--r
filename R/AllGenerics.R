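#' @import methods
NULL

#' Accessor generics
#'
#' S4 generics implemented by the package's data classes; see the class
#' pages ([Parcellation-class], [RegionTimeSeries-class],
#' [Connectome-class], [ConnectomeCohort-class], [NBSResult-class],
#' [SignatureSummary-class]) for the method semantics.
#'
#' @param x an object of one of the classes above.
#' @param value replacement value (replacement generics).
#' @param alpha significance level for [significantComponents()]; `NULL`
#'   uses the level stored in the result's configuration.
#' @return see the individual class pages.
#' @name accessors
#' @aliases nNodes networkLabels parcellation zMatrix tsValues censorMask
#'   censorMask<- trSeconds groundTruth nbsComponents nullDistribution
#'   significantComponents overallMeanZ pairMeans
NULL

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' @rdname accessors
#' @export
setGeneric("parcellation", function(x) standardGeneric("parcellation"))

#' @rdname accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname accessors
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))

#' @rdname accessors
#' @export
setGeneric("censorMask", function(x) standardGeneric("censorMask"))

#' @rdname accessors
#' @export
setGeneric("censorMask<-", function(x, value) standardGeneric("censorMask<-"))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("nbsComponents", function(x) standardGeneric("nbsComponents"))

#' @rdname accessors
#' @export
setGeneric("nullDistribution", function(x) standardGeneric("nullDistribution"))

#' @rdname accessors
#' @export
setGeneric("significantComponents",
           function(x, alpha = NULL) standardGeneric("significantComponents"))

#' @rdname accessors
#' @export
setGeneric("overallMeanZ", function(x) standardGeneric("overallMeanZ"))

#' @rdname accessors
#' @export
setGeneric("pairMeans", function(x) standardGeneric("pairMeans"))
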