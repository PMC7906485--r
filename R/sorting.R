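#' Sort a feature column into its strongly-expressing subject subset
#'
#' Reduces one feature column to the subset of subjects whose loading on that
#' feature is extreme — the sorted component (SCOMP) that the search engine
#' intersects. Four mean-based rules are available:
#'
#' \describe{
#'   \item{Method 1 (positive and negative):}{compute the mean of the strictly
#'     positive loadings and the mean of the strictly negative loadings
#'     separately; keep subjects with loading >= the positive mean or
#'     <= the negative mean.}
#'   \item{Method 2 (positive and negative quartiles):}{keep the upper
#'     quartile of the positive loadings (>= their 75th percentile) and the
#'     lower quartile of the negative loadings (<= their 25th percentile).}
#'   \item{Method 3 (absolute value):}{keep subjects with |loading| >=
#'     |mean loading| of the column.}
#'   \item{Method 4 (positive or negative):}{if the column mean is >= 0 keep
#'     subjects with loading >= mean; otherwise keep subjects with
#'     loading < mean.}
#' }
#'
#' Zero loadings belong to neither the positive nor the negative subsample in
#' methods 1-2. An all-zero column selects every subject under methods 3-4
#' (|mean| = 0) and none under methods 1-2. Quartiles use the
#' linear-interpolation definition (\code{stats::quantile} type 7).
#'
#' @param column numeric vector of loadings for one feature (finite, nonempty).
#' @param method integer 1-4; default 4, the rule that recovers planted
#'   biclusters best in simulation.
#' @return sorted integer vector of selected subject indices (possibly empty).
#' @examples
#' sortComponent(c(0.9, 0.8, 0.7, 0.1), method = 4)  # 1 2 3
#' @export
sortComponent <- function(column, method = 4) {
  if (length(column) == 0L) stop("empty column")
  if (any(!is.finite(column))) stop("column contains non-finite values")
  method <- as.integer(method)
  if (!method %in% 1:4) stop("method must be 1, 2, 3 or 4")
  pos <- column > 0
  neg <- column < 0
  sel <- switch(method,
    { # 1: tails beyond the positive / negative means
      keep <- rep(FALSE, length(column))
      if (any(pos)) keep <- keep | column >= mean(column[pos])
      if (any(neg)) keep <- keep | column <= mean(column[neg])
      keep
    },
    { # 2: upper quartile of positives, lower quartile of negatives
      keep <- rep(FALSE, length(column))
      if (any(pos))
        keep <- keep | column >= stats::quantile(column[pos], 0.75,
                                                 names = FALSE)
      if (any(neg))
        keep <- keep | column <= stats::quantile(column[neg], 0.25,
                                                 names = FALSE)
      keep
    },
    abs(column) >= abs(mean(column)),                     # 3
    if (mean(column) >= 0) column >= mean(column) else column < mean(column) # 4
  )
  which(sel)
}

#' Sort every feature column of a loading matrix
#'
#' Applies [sortComponent()] to each column, yielding one sorted component
#' per feature in column order; the component's numeric ID is its column
#' position.
#'
#' @param mat a [LoadingMatrix-class].
#' @param method sorting rule 1-4 (see [sortComponent()]).
#' @param zscore center and scale each column first; puts symptom scales and
#'   ICA loadings on comparable footing when mixed. Constant columns are
#'   centered only.
#' @return named list (feature label -> integer vector of subject indices).
#' @examples
#' m <- LoadingMatrix(matrix(rnorm(40), 10, 4))
#' lengths(sortComponents(m, method = 4))
#' @export
sortComponents <- function(mat, method = 4, zscore = FALSE) {
  stopifnot(is(mat, "LoadingMatrix"))
  v <- mat@values
  if (zscore) v <- .zscoreColumns(v)
  out <- lapply(seq_len(ncol(v)), function(j) {
    tryCatch(sortComponent(v[, j], method),
             error = function(e)
               stop(sprintf("feature '%s': %s", colnames(v)[j],
                            conditionMessage(e)), call. = FALSE))
  })
  names(out) <- colnames(v)
  out
}

.zscoreColumns <- function(v) {
  ctr <- sweep(v, 2L, colMeans(v))
  sds <- apply(v, 2L, stats::sd)
  sds[sds == 0] <- 1  # constant column: center only
  sweep(ctr, 2L, sds, "/")
}
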