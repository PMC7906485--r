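#' @rdname LoadingMatrix-class
#' @param object,x a LoadingMatrix or BiclusterSet
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))

#' @rdname LoadingMatrix-class
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname LoadingMatrix-class
#' @export
setGeneric("featureLabels", function(object) standardGeneric("featureLabels"))

#' @rdname LoadingMatrix-class
#' @export
setGeneric("featureKind", function(object) standardGeneric("featureKind"))

#' @rdname Bicluster-class
#' @param object a Bicluster
#' @export
setGeneric("subjects", function(object) standardGeneric("subjects"))

#' @rdname Bicluster-class
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' Rediscovery frequency of a bicluster
#'
#' Promotes \code{stats::frequency} to an S4 generic so that biclusters can
#' report their stability count through the same verb.
#' @param x a [Bicluster-class]
#' @param ... unused
#' @export
setGeneric("frequency")

#' @rdname Bicluster-class
#' @export
setGeneric("bicSize", function(object) standardGeneric("bicSize"))
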