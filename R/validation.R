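#' Derive the F1 overlap thresholds from the overlap percentages
#'
#' The search blocks a new bicluster when its dice (F1) similarity to an
#' already-kept one reaches a threshold. Substituting the minimum bicluster
#' size into the dice formula reduces the within-permutation threshold to
#' O/100, and the cross-permutation threshold to OE/100 (OE defaulting to O).
#' These are the minimum thresholds implied by the size parameters; users can
#' calibrate upward for stricter de-duplication.
#'
#' @param N,K minimum subjects / features per bicluster (unused after the
#'   simplification; kept for the full form of the derivation).
#' @param O allowed overlap percent within a permutation, in [0, 100].
#' @param OE allowed overlap percent across permutations; NA means "use O".
#' @return named numeric vector \code{c(fTH1 =, fTH2 =)}, both in [0, 1].
#' @examples
#' computeThresholds(35, 3, 35)       # 0.35 0.35
#' computeThresholds(35, 3, 20, 35)   # 0.20 0.35
#' @export
computeThresholds <- function(N, K, O, OE = NA_real_) {
  stopifnot(O >= 0, O <= 100, is.na(OE) || (OE >= 0 && OE <= 100))
  c(fTH1 = O / 100, fTH2 = (if (is.na(OE)) O else OE) / 100)
}

# dice similarity on matrix cells for label/index sets; the shared cell count
# factorises as (shared subjects) x (shared features)
.f1cells <- function(sA, fA, sB, fB) {
  inter <- length(intersect(sA, sB)) * length(intersect(fA, fB))
  2 * inter / (length(sA) * length(fA) + length(sB) * length(fB))
}

#' F1 (dice) similarity between two biclusters
#'
#' Treats each bicluster as its set of matrix cells (subjects x features) and
#' returns \code{2|A n B| / (|A| + |B|)}, where the shared cell count is the
#' product of shared subjects and shared features. Symmetric; 1 iff the two
#' biclusters have identical subject and feature sets; 0 when either the
#' subject sets or the feature sets are disjoint.
#'
#' @param A,B [Bicluster-class] objects.
#' @return similarity in [0, 1].
#' @examples
#' a <- Bicluster(1:10, c("C1", "C2", "C3"))
#' b <- Bicluster(6:15, c("C2", "C3", "C4"))
#' f1Index(a, b)  # 2*(5*2)/(30+30) = 1/3
#' @export
f1Index <- function(A, B) {
  stopifnot(is(A, "Bicluster"), is(B, "Bicluster"))
  .f1cells(A@subjects, A@features, B@subjects, B@features)
}

# rec versions used by the search hot path: rec = list(s=, f=, freq=)
.f1rec <- function(a, b) .f1cells(a$s, a$f, b$s, b$f)

.localValidateRec <- function(cand, accepted, fTH1) {
  for (b in accepted)
    if (.f1rec(cand, b) >= fTH1) return(FALSE)
  TRUE
}

#' Within-permutation local validator
#'
#' A size-qualified candidate is kept only if its F1 similarity to every
#' bicluster already accepted in the same permutation stays below the
#' within-permutation threshold fTH1 (first come, first kept).
#'
#' @param candidate a [Bicluster-class].
#' @param accepted a [BiclusterSet-class] or list of biclusters accepted so
#'   far in this permutation.
#' @param fTH1 within-permutation threshold in [0, 1].
#' @return TRUE to accept, FALSE to reject.
#' @export
localValidate <- function(candidate, accepted, fTH1) {
  if (is(accepted, "BiclusterSet")) accepted <- accepted@elements
  for (b in accepted)
    if (f1Index(candidate, b) >= fTH1) return(FALSE)
  TRUE
}

.globalUpdateRec <- function(finalRecs, tempRecs, fTH2) {
  for (t in tempRecs) {
    if (length(finalRecs)) {
      sims <- vapply(finalRecs, .f1rec, numeric(1), b = t)
      best <- which.max(sims)  # earliest index wins ties
      if (sims[best] >= fTH2) {
        finalRecs[[best]]$freq <- finalRecs[[best]]$freq + 1L
        next
      }
    }
    t$freq <- 1L
    finalRecs[[length(finalRecs) + 1L]] <- t
  }
  finalRecs
}

#' Cross-permutation global stability update
#'
#' Folds one permutation's temporary bicluster list into the accumulating
#' final list: each temporary bicluster either increments the frequency of
#' the most similar final bicluster (when that maximum F1 reaches fTH2; the
#' incumbent's membership is kept, earliest entry wins ties) or is appended
#' with frequency 1. With an empty final list (the first permutation) every
#' temporary bicluster is appended.
#'
#' @param finalList [BiclusterSet-class] accumulated so far.
#' @param tempList [BiclusterSet-class] from the current permutation.
#' @param fTH2 cross-permutation threshold in [0, 1].
#' @return updated [BiclusterSet-class].
#' @export
globalUpdate <- function(finalList, tempList, fTH2) {
  stopifnot(is(finalList, "BiclusterSet"), is(tempList, "BiclusterSet"))
  recs <- .globalUpdateRec(lapply(finalList@elements, .bicToRec),
                           lapply(tempList@elements, .bicToRec), fTH2)
  .recsToSet(recs)
}

.bicToRec <- function(b) list(s = b@subjects, f = b@features, freq = b@frequency)
.recsToSet <- function(recs) {
  BiclusterSet(lapply(recs, function(r)
    Bicluster(r$s, r$f, frequency = r$freq)))
}

#' Final stability filter
#'
#' Keeps biclusters rediscovered in at least \code{minFrequency}
#' permutations, ordered by frequency (descending), then size (descending),
#' then original position.
#'
#' @param bics a [BiclusterSet-class] with frequencies accumulated.
#' @param minFrequency minimum frequency retained.
#' @return the filtered, re-ordered [BiclusterSet-class].
#' @export
stabilityFilter <- function(bics, minFrequency = 2) {
  stopifnot(is(bics, "BiclusterSet"))
  if (!length(bics)) return(bics)
  freqs <- vapply(bics@elements, function(b) b@frequency, 0L)
  sizes <- vapply(bics@elements, bicSize, 0L)
  keep <- which(freqs >= minFrequency)
  keep <- keep[order(-freqs[keep], -sizes[keep], keep)]
  new("BiclusterSet", elements = bics@elements[keep])
}
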