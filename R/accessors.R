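#' @rdname LoadingMatrix-class
#' @export
setMethod("loadings", "LoadingMatrix", function(object) object@values)

#' @rdname LoadingMatrix-class
#' @export
setMethod("subjectIds", "LoadingMatrix", function(object) rownames(object@values))

#' @rdname LoadingMatrix-class
#' @export
setMethod("featureLabels", "LoadingMatrix", function(object) colnames(object@values))

#' @rdname LoadingMatrix-class
#' @export
setMethod("featureKind", "LoadingMatrix", function(object) object@featureKind)

#' @rdname LoadingMatrix-class
#' @export
setMethod("dim", "LoadingMatrix", function(x) dim(x@values))

setMethod("show", "LoadingMatrix", function(object) {
  k <- table(factor(object@featureKind, levels = c("imaging", "symptom")))
  cat(sprintf("LoadingMatrix: %d subjects x %d features (%d imaging, %d symptom)\n",
              nrow(object@values), ncol(object@values), k[["imaging"]],
              k[["symptom"]]))
  cat("features:", paste(utils::head(colnames(object@values), 8L),
                         collapse = ", "),
      if (ncol(object@values) > 8L) "..." else "", "\n")
})

#' @rdname Bicluster-class
#' @export
setMethod("subjects", "Bicluster", function(object) object@subjects)

#' @rdname Bicluster-class
#' @export
setMethod("features", "Bicluster", function(object) object@features)

#' @rdname Bicluster-class
#' @param x a Bicluster
#' @param ... unused
#' @export
setMethod("frequency", "Bicluster", function(x, ...) x@frequency)

#' @describeIn Bicluster-class size |subjects| x |features|, the number of
#'   matrix cells the bicluster covers.
#' @export
setMethod("bicSize", "Bicluster", function(object)
  length(object@subjects) * length(object@features))

setMethod("show", "Bicluster", function(object) {
  cat(sprintf("Bicluster: %d subjects x %d features (size %d, frequency %d)\n",
              length(object@subjects), length(object@features),
              bicSize(object), object@frequency))
  cat("features:", paste(object@features, collapse = ", "), "\n")
})

#' @rdname BiclusterSet-class
#' @param x a BiclusterSet
#' @export
setMethod("length", "BiclusterSet", function(x) length(x@elements))

#' @rdname BiclusterSet-class
#' @param i index
#' @export
setMethod("[[", "BiclusterSet", function(x, i) x@elements[[i]])

#' @rdname BiclusterSet-class
#' @param j,drop,... ignored
#' @export
setMethod("[", "BiclusterSet", function(x, i, j, ..., drop = FALSE)
  new("BiclusterSet", elements = x@elements[i]))

setMethod("show", "BiclusterSet", function(object) {
  cat(sprintf("BiclusterSet of %d biclusters\n", length(object)))
  if (length(object))
    print(as(object, "data.frame"), row.names = FALSE)
})

#' Summarise a BiclusterSet as a data.frame
#'
#' One row per bicluster: id, feature labels (comma-joined), subject and
#' feature counts, size and frequency. Subject membership is not flattened;
#' use \code{subjects()} on the elements or [writeBiclusterReport()].
#' @name as.data.frame
#' @rdname BiclusterSet-class
setAs("BiclusterSet", "data.frame", function(from) {
  if (!length(from))
    return(data.frame(id = integer(), features = character(),
                      nSubjects = integer(), nFeatures = integer(),
                      size = integer(), frequency = integer()))
  data.frame(
    id = seq_along(from@elements),
    features = vapply(from@elements,
                      function(b) paste(b@features, collapse = ","), ""),
    nSubjects = vapply(from@elements, function(b) length(b@subjects), 0L),
    nFeatures = vapply(from@elements, function(b) length(b@features), 0L),
    size = vapply(from@elements, bicSize, 0L),
    frequency = vapply(from@elements, function(b) b@frequency, 0L))
})

#' @rdname BiclusterSet-class
#' @param row.names,optional passed through
#' @export
as.data.frame.BiclusterSet <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  as(x, "data.frame")
}
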