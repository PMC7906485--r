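#' Mean square residue of a submatrix
#'
#' The coherence measure of a bicluster: the mean over cells of the squared
#' additive residual \code{a_ij - rowmean_i - colmean_j + grandmean}. Zero
#' for constant and additive (row effect + column effect) submatrices; lower
#' values mean stronger coherence. Invariant under adding a constant to any
#' row or column.
#'
#' @param x numeric matrix (at least 1 x 1), e.g. from [biclusterValues()].
#' @return nonnegative scalar.
#' @examples
#' msr(matrix(c(1, 0, 0, 1), 2, 2))  # 0.25
#' msr(outer(1:3, 1:4, "+"))         # 0 (additive)
#' @export
msr <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0L) stop("empty submatrix")
  if (!is.numeric(x)) stop("submatrix must be numeric")
  res <- sweep(x, 1L, rowMeans(x))
  res <- sweep(res, 2L, colMeans(x))
  mean((res + mean(x))^2)
}

#' Extract the submatrix covered by a bicluster
#'
#' @param mat a [LoadingMatrix-class].
#' @param bic a [Bicluster-class] whose subjects/features are present in
#'   \code{mat}.
#' @return numeric matrix (bicluster subjects x bicluster features).
#' @export
biclusterValues <- function(mat, bic) {
  stopifnot(is(mat, "LoadingMatrix"), is(bic, "Bicluster"))
  miss <- setdiff(bic@subjects, rownames(mat@values))
  if (length(miss)) stop("unknown subjects: ", paste(miss, collapse = ", "))
  miss <- setdiff(bic@features, colnames(mat@values))
  if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "))
  mat@values[bic@subjects, bic@features, drop = FALSE]
}

# pairwise F1 matrix between two bicluster sets (rows: A, cols: B)
.f1matrix <- function(setA, setB) {
  outer(seq_along(setA@elements), seq_along(setB@elements),
        Vectorize(function(i, j) f1Index(setA[[i]], setB[[j]])))
}

#' Consensus score between two bicluster sets
#'
#' Builds the pairwise F1 matrix between the two sets, finds the one-to-one
#' assignment maximizing the total F1 (maximum-weight bipartite matching),
#' and divides the optimum by the size of the larger set. 1 exactly when the
#' sets are identical up to order; 0 when every pair has zero overlap.
#' Symmetric in its arguments.
#'
#' An optional variant first condenses \code{setA}: members whose
#' cell-level sensitivity (shared cells / own cells) to the same \code{setB}
#' bicluster reaches \code{mergeSensitivity} are unioned into one combined
#' bicluster before scoring, shrinking the normalizing set size. The merge
#' rule has no canonical threshold, so the variant is off by default.
#'
#' @param setA,setB nonempty [BiclusterSet-class] objects (e.g. estimated
#'   vs ground truth; \code{setB} is the reference for the merge variant).
#' @param mergeSensitivity NULL (default, no merging) or a threshold in
#'   (0, 1] enabling the combined-set variant.
#' @return score in [0, 1].
#' @examples
#' tr <- sim1Truth()
#' consensusScore(tr, tr)  # 1
#' @export
consensusScore <- function(setA, setB, mergeSensitivity = NULL) {
  stopifnot(is(setA, "BiclusterSet"), is(setB, "BiclusterSet"))
  if (!is.null(mergeSensitivity)) {
    stopifnot(mergeSensitivity > 0, mergeSensitivity <= 1)
    setA <- .mergeBySensitivity(setA, setB, mergeSensitivity)
  }
  a <- length(setA); b <- length(setB)
  if (a == 0L || b == 0L) stop("consensusScore requires nonempty sets")
  f1 <- .f1matrix(setA, setB)
  pos <- which(f1 > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(0)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, a), rep(TRUE, b)),
    edges = as.vector(rbind(pos[, 1L], a + pos[, 2L])))
  match <- igraph::max_bipartite_match(g, weights = f1[pos])
  match$matching_weight / max(a, b)
}

# combined-set condensation: group setA members by the reference bicluster
# they are most cell-sensitive to (shared cells / own cells >= threshold);
# each group is unioned into one bicluster, the rest stay singletons
.mergeBySensitivity <- function(setA, ref, threshold) {
  groups <- rep(NA_integer_, length(setA))
  for (i in seq_len(length(setA))) {
    a <- setA[[i]]
    sens <- vapply(ref@elements, function(r) {
      shared <- length(intersect(a@subjects, r@subjects)) *
        length(intersect(a@features, r@features))
      shared / bicSize(a)
    }, numeric(1))
    if (length(sens) && max(sens) >= threshold)
      groups[i] <- which.max(sens)
  }
  merged <- lapply(stats::na.omit(unique(groups)), function(g) {
    members <- setA@elements[which(groups == g)]
    Bicluster(unique(unlist(lapply(members, subjects))),
              unique(unlist(lapply(members, features))))
  })
  singles <- setA@elements[is.na(groups)]
  BiclusterSet(c(merged, singles))
}

#' Best-match recovery report against a ground truth
#'
#' For every ground-truth bicluster, reports the highest F1 achieved by any
#' estimated bicluster and which estimate achieved it. An empty estimated
#' set yields best F1 = 0 throughout.
#'
#' @param estimated [BiclusterSet-class] produced by the search (may be
#'   empty).
#' @param truth nonempty [BiclusterSet-class] of planted biclusters.
#' @return data.frame with columns \code{truth}, \code{bestF1},
#'   \code{match} (index into \code{estimated}, NA when empty).
#' @export
recoveryReport <- function(estimated, truth) {
  stopifnot(is(estimated, "BiclusterSet"), is(truth, "BiclusterSet"),
            length(truth) >= 1L)
  if (!length(estimated))
    return(data.frame(truth = seq_len(length(truth)), bestF1 = 0,
                      match = NA_integer_))
  f1 <- .f1matrix(truth, estimated)
  data.frame(truth = seq_len(length(truth)),
             bestF1 = apply(f1, 1L, max),
             match = apply(f1, 1L, which.max))
}

#' Compare the four sorting rules on a fixture with known truth
#'
#' Runs the full search once per sorting method and summarises each run by
#' the mean and SD of the biclusters' mean square residues, the consensus
#' score against the truth, and the per-truth best-match F1 values.
#' Deterministic given the seed in \code{param}.
#'
#' @param mat a [LoadingMatrix-class] fixture.
#' @param truth the planted [BiclusterSet-class].
#' @param param an [NBicParam-class]; its \code{M} slot is overridden per
#'   method.
#' @return list with \code{$summary} (data.frame: method, nBiclusters,
#'   meanMSR, sdMSR, cScore) and \code{$recovery} (list of per-method
#'   [recoveryReport()] tables).
#' @export
compareSortingMethods <- function(mat, truth, param = NBicParam()) {
  rows <- vector("list", 4L)
  recov <- vector("list", 4L)
  for (m in 1:4) {
    pm <- param; pm@M <- m
    res <- runNBiC(mat, pm)
    msrs <- if (length(res))
      vapply(res@elements, function(b) msr(biclusterValues(mat, b)),
             numeric(1))
    else numeric(0)
    rows[[m]] <- data.frame(
      method = m, nBiclusters = length(res),
      meanMSR = if (length(msrs)) mean(msrs) else NA_real_,
      sdMSR = if (length(msrs) > 1L) stats::sd(msrs) else NA_real_,
      cScore = if (length(res)) consensusScore(res, truth) else 0)
    recov[[m]] <- recoveryReport(res, truth)
  }
  list(summary = do.call(rbind, rows), recovery = recov)
}
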