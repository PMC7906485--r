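#' @import methods
NULL

#' LoadingMatrix: a labelled subject-by-feature matrix
#'
#' Container for the matrix being biclustered: one row per subject, one
#' column per feature. Features are typically ICA loading parameters from a
#' source-based morphometry decomposition, optionally concatenated with
#' symptom-scale scores; the \code{featureKind} vector records which columns
#' are which. Values must be finite and both identifier sets must be unique.
#'
#' @slot values numeric matrix (subjects x features) with rownames (subject
#'   identifiers) and colnames (feature labels).
#' @slot featureKind character vector, one of \code{"imaging"} or
#'   \code{"symptom"} per column.
#'
#' @seealso [LoadingMatrix()] for construction, [readLoadingMatrix()] for
#'   file input, [runNBiC()] for the search.
#' @name LoadingMatrix-class
#' @rdname LoadingMatrix-class
#' @exportClass LoadingMatrix
setClass("LoadingMatrix",
         slots = c(values = "matrix", featureKind = "character"))

setValidity("LoadingMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v))
    msgs <- c(msgs, "values must be a numeric matrix")
  else if (any(!is.finite(v)))
    msgs <- c(msgs, "values must be finite (no NA/NaN/Inf)")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must carry subject ids (rownames) and feature labels (colnames)")
  else {
    if (anyDuplicated(rownames(v)))
      msgs <- c(msgs, "duplicate subject ids")
    if (anyDuplicated(colnames(v)))
      msgs <- c(msgs, "duplicate feature labels")
  }
  if (length(object@featureKind) != ncol(v))
    msgs <- c(msgs, "featureKind must have one entry per feature")
  if (!all(object@featureKind %in% c("imaging", "symptom")))
    msgs <- c(msgs, "featureKind entries must be 'imaging' or 'symptom'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LoadingMatrix
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#' @param subjectIds optional character vector of subject identifiers
#'   (defaults to existing rownames, else \code{"1"..."n"}).
#' @param featureLabels optional character vector of feature labels (defaults
#'   to existing colnames, else \code{"C1"..."Cm"}).
#' @param featureKind \code{"imaging"} or \code{"symptom"}, recycled across
#'   columns if scalar.
#' @return a validated [LoadingMatrix-class] object.
#' @examples
#' m <- LoadingMatrix(matrix(rnorm(12), 4, 3))
#' dim(m)
#' @export
LoadingMatrix <- function(values, subjectIds = NULL, featureLabels = NULL,
                          featureKind = "imaging") {
  values <- as.matrix(values)
  if (!is.null(subjectIds)) rownames(values) <- as.character(subjectIds)
  if (is.null(rownames(values))) rownames(values) <- as.character(seq_len(nrow(values)))
  if (!is.null(featureLabels)) colnames(values) <- as.character(featureLabels)
  if (is.null(colnames(values))) colnames(values) <- paste0("C", seq_len(ncol(values)))
  if (length(featureKind) == 1L)
    featureKind <- rep(featureKind, ncol(values))
  new("LoadingMatrix", values = values, featureKind = unname(featureKind))
}

#' Bicluster: a subject subset paired with a feature subset
#'
#' A bicluster is a submatrix of the loading matrix — a set of subjects
#' homogeneously expressed across a set of features — together with a
#' stability frequency: the number of feature-order permutations in which the
#' search rediscovered it (or an equivalent one under the cross-permutation
#' overlap threshold).
#'
#' @slot subjects character vector of subject identifiers (nonempty, unique).
#' @slot features character vector of feature labels (nonempty, unique).
#' @slot frequency positive integer rediscovery count.
#' @name Bicluster-class
#' @rdname Bicluster-class
#' @exportClass Bicluster
setClass("Bicluster",
         slots = c(subjects = "character", features = "character",
                   frequency = "integer"))

setValidity("Bicluster", function(object) {
  msgs <- character()
  if (length(object@subjects) == 0L) msgs <- c(msgs, "subjects must be nonempty")
  if (length(object@features) == 0L) msgs <- c(msgs, "features must be nonempty")
  if (anyDuplicated(object@subjects)) msgs <- c(msgs, "duplicate subjects")
  if (anyDuplicated(object@features)) msgs <- c(msgs, "duplicate features")
  if (length(object@frequency) != 1L || is.na(object@frequency) ||
      object@frequency < 1L)
    msgs <- c(msgs, "frequency must be a single integer >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Bicluster
#'
#' @param subjects subject identifiers (coerced to character).
#' @param features feature labels (coerced to character).
#' @param frequency rediscovery count, default 1.
#' @return a validated [Bicluster-class] object.
#' @examples
#' Bicluster(c(1, 2, 5), c("C1", "C3"))
#' @export
Bicluster <- function(subjects, features, frequency = 1L) {
  new("Bicluster", subjects = as.character(subjects),
      features = as.character(features), frequency = as.integer(frequency))
}

#' BiclusterSet: an ordered collection of biclusters
#'
#' Holds the final (or ground-truth) list of biclusters. Supports
#' \code{length}, \code{[}, \code{[[} and coercion to a data.frame summary.
#'
#' @slot elements list of [Bicluster-class] objects.
#' @name BiclusterSet-class
#' @rdname BiclusterSet-class
#' @exportClass BiclusterSet
setClass("BiclusterSet", slots = c(elements = "list"))

setValidity("BiclusterSet", function(object) {
  ok <- vapply(object@elements, function(e) is(e, "Bicluster"), logical(1))
  if (all(ok)) TRUE else "all elements must be Bicluster objects"
})

#' Construct a BiclusterSet
#'
#' @param ... [Bicluster-class] objects, or a single list of them.
#' @return a [BiclusterSet-class].
#' @examples
#' BiclusterSet(Bicluster(1:3, "C1"), Bicluster(4:6, c("C2", "C3")))
#' @export
BiclusterSet <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !is(args[[1L]], "Bicluster"))
    args <- args[[1L]]
  new("BiclusterSet", elements = args)
}

#' NBicParam: search parameters
#'
#' Bundles the tunable parameters of the biclustering search: the minimum
#' bicluster size (N subjects, K features), the allowed overlap percentages
#' within (O) and across (OE) feature-order permutations, the column sorting
#' rule M, the permutation budget, the RNG seed, the minimum rediscovery
#' frequency for the final report, and whether columns are z-scored before
#' sorting (NA = automatic: on when symptom columns are present).
#'
#' @slot N integer, minimum subjects per bicluster (>= 1).
#' @slot K integer, minimum features per bicluster (>= 2).
#' @slot O numeric, allowed overlap percent within a permutation, in [0, 100].
#' @slot OE numeric, allowed overlap percent across permutations, in
#'   [0, 100]; NA means "use O".
#' @slot M integer sorting method selector in 1..4.
#' @slot permutations integer, maximum number of feature-order permutations.
#' @slot seed integer RNG seed.
#' @slot minFrequency integer, minimum frequency kept by the final filter.
#' @slot zscore logical, z-score columns before sorting (NA = auto).
#' @name NBicParam-class
#' @rdname NBicParam-class
#' @exportClass NBicParam
setClass("NBicParam",
         slots = c(N = "integer", K = "integer", O = "numeric", OE = "numeric",
                   M = "integer", permutations = "integer", seed = "integer",
                   minFrequency = "integer", zscore = "logical"))

setValidity("NBicParam", function(object) {
  msgs <- character()
  if (object@N < 1L) msgs <- c(msgs, "N must be >= 1")
  if (object@K < 2L) msgs <- c(msgs, "K must be >= 2")
  if (object@O < 0 || object@O > 100) msgs <- c(msgs, "O must be in [0, 100]")
  if (!is.na(object@OE) && (object@OE < 0 || object@OE > 100))
    msgs <- c(msgs, "OE must be in [0, 100]")
  if (!object@M %in% 1:4) msgs <- c(msgs, "M must be in 1..4")
  if (object@permutations < 1L) msgs <- c(msgs, "permutations must be >= 1")
  if (object@minFrequency < 1L) msgs <- c(msgs, "minFrequency must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct search parameters
#'
#' Defaults follow the configuration found to behave well on source-based
#' morphometry loadings: biclusters of at least 35 subjects and 3 features,
#' 35 percent allowed overlap, the positive-or-negative sorting rule
#' (method 4), a budget of 720 feature-order permutations, and a stability
#' filter keeping biclusters rediscovered in at least 2 permutations.
#'
#' @param N minimum subjects per bicluster.
#' @param K minimum features per bicluster.
#' @param O allowed overlap percentage within a permutation.
#' @param OE allowed overlap percentage across permutations (default: O).
#' @param M sorting method, 1-4 (see [sortComponent()]).
#' @param permutations cap on the number of feature-order permutations.
#' @param seed RNG seed controlling permutation sampling.
#' @param minFrequency minimum rediscovery frequency retained.
#' @param zscore z-score columns before sorting; NA = on iff symptom
#'   columns are present.
#' @return an [NBicParam-class] object.
#' @examples
#' NBicParam(N = 11, K = 3, O = 35)
#' @export
NBicParam <- function(N = 35, K = 3, O = 35, OE = NA_real_, M = 4,
                      permutations = 720, seed = 1, minFrequency = 2,
                      zscore = NA) {
  new("NBicParam", N = as.integer(N), K = as.integer(K), O = as.numeric(O),
      OE = as.numeric(OE), M = as.integer(M),
      permutations = as.integer(permutations), seed = as.integer(seed),
      minFrequency = as.integer(minFrequency), zscore = as.logical(zscore))
}
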