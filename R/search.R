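#' Enumerate feature-ID subsets in depth-first order
#'
#' Generates every subset of the given ID sequence with at least \code{K}
#' elements, exactly once, in depth-first prefix-extension order: prefixes
#' are extended left-to-right along the sequence, and a prefix is emitted
#' before any of its extensions. For a sequence of length m the count is
#' sum over j = K..m of choose(m, j).
#'
#' @param ids ordered vector of feature IDs (a permutation of the features).
#' @param K minimum subset size; \code{K > length(ids)} yields an empty list.
#' @return list of integer vectors, each in the order induced by \code{ids}.
#' @examples
#' enumerateSubsets(1:3, K = 2)  # {1,2} {1,2,3} {1,3} {2,3}
#' @export
enumerateSubsets <- function(ids, K = 2) {
  stopifnot(length(ids) >= 1L, K >= 1)
  m <- length(ids)
  out <- vector("list", if (m <= 20) 2^m else 2^20)
  cnt <- 0L
  rec <- function(prefix, start) {
    for (i in start:m) {
      cur <- c(prefix, ids[i])
      if (length(cur) >= K) {
        cnt <<- cnt + 1L
        out[[cnt]] <<- cur
      }
      if (i < m) rec(cur, i + 1L)
    }
  }
  if (K <= m) rec(ids[0], 1L)
  out[seq_len(cnt)]
}

#' Intersect the sorted components of a feature subset
#'
#' Returns the exact intersection of the subject sets of the named sorted
#' components; the candidate subject set of that feature subset.
#'
#' @param scomps named or unnamed list of subject index/ID vectors, indexed
#'   by feature ID.
#' @param featureSubset vector of feature IDs (positions in \code{scomps}).
#' @return vector of subjects present in every selected component.
#' @export
intersectScomps <- function(scomps, featureSubset) {
  idx <- as.integer(featureSubset)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(scomps)))
    stop("unknown feature ID in subset")
  Reduce(intersect, scomps[idx])
}

# Enumerate all size-qualified candidates once, independent of permutation
# order: DFS over column order with pruning (a prefix whose intersection
# already has fewer than N subjects cannot produce a qualifying superset).
# Returns list of rec = list(f = sorted int feature ids, s = int subjects).
.enumCandidates <- function(scomps, N, K) {
  m <- length(scomps)
  out <- list()
  cnt <- 0L
  rec <- function(feats, subj, start) {
    for (i in start:m) {
      s2 <- if (is.null(subj)) scomps[[i]] else intersect(subj, scomps[[i]])
      if (length(s2) < N) next
      f2 <- c(feats, i)
      if (length(f2) >= K) {
        cnt <<- cnt + 1L
        out[[cnt]] <<- list(f = f2, s = s2)
      }
      if (i < m) rec(f2, s2, i + 1L)
    }
  }
  if (K <= m) rec(integer(0), NULL, 1L)
  out
}

# Precompute, for Q candidates over n subjects and m features: the feature
# membership matrix and the full Q x Q pairwise F1 matrix. Valid because a
# final-list bicluster is always one of the candidates (merging keeps the
# incumbent's membership), so every similarity the search ever needs is a
# lookup here.
.candidateIndex <- function(cands, nSubjects, m) {
  Q <- length(cands)
  S <- matrix(0L, Q, nSubjects)
  Fm <- matrix(0L, Q, m)
  for (q in seq_len(Q)) {
    S[q, cands[[q]]$s] <- 1L
    Fm[q, cands[[q]]$f] <- 1L
  }
  inter <- tcrossprod(S) * tcrossprod(Fm)  # shared subjects x shared features
  sizes <- rowSums(S) * rowSums(Fm)
  list(featMat = Fm, f1 = 2 * inter / outer(sizes, sizes, "+"))
}

# DFS emission order of the candidates under a permutation. The order is
# lexicographic on each candidate's sorted permutation-position sequence
# (a prefix precedes its extensions); encoded as a base-(m+2) fraction so a
# single numeric sort suffices. Falls back to string keys when m is large
# enough for the fraction to lose precision.
.dfsOrder <- function(featMat, perm) {
  m <- length(perm)
  if (m <= 14) {
    key <- numeric(nrow(featMat))
    rank <- integer(nrow(featMat))
    base <- m + 2
    for (p in seq_len(m)) {
      sel <- featMat[, perm[p]] == 1L
      rank[sel] <- rank[sel] + 1L
      key[sel] <- key[sel] + p * base^(-rank[sel])
    }
    order(key)
  } else {
    pos <- integer(m)
    pos[perm] <- seq_len(m)
    keys <- apply(featMat, 1L, function(f)
      paste(sprintf("%03d", sort(pos[f == 1L])), collapse = ""))
    order(keys)
  }
}

# within-permutation local validation over candidate indices in DFS order
.localPass <- function(ord, f1, fTH1) {
  acc <- integer(0)
  for (i in ord)
    if (!length(acc) || all(f1[i, acc] < fTH1))
      acc <- c(acc, i)
  acc
}

# fold one permutation's accepted candidate indices into the final list
.globalFold <- function(finalIdx, freqs, tempIdx, f1, fTH2) {
  for (t in tempIdx) {
    if (length(finalIdx)) {
      sims <- f1[t, finalIdx]
      b <- which.max(sims)  # earliest entry wins ties
      if (sims[b] >= fTH2) {
        freqs[b] <- freqs[b] + 1L
        next
      }
    }
    finalIdx <- c(finalIdx, t)
    freqs <- c(freqs, 1L)
  }
  list(idx = finalIdx, freq = freqs)
}

#' Search one feature-order permutation for biclusters
#'
#' Enumerates the feature subsets of the permutation in depth-first order,
#' intersects the corresponding sorted components, keeps subsets meeting the
#' size constraints (at least N subjects, K features), and passes each
#' candidate through the within-permutation local validator (threshold
#' fTH1). Returns the permutation's temporary bicluster list, each with
#' frequency 1, in discovery order.
#'
#' @param perm integer permutation of the feature IDs \code{1..m}.
#' @param scomps list of sorted components (subject index vectors) in
#'   feature order, as produced by [sortComponents()].
#' @param param an [NBicParam-class] (N, K, O used).
#' @return a [BiclusterSet-class]; subjects/features are reported as the
#'   names of \code{scomps} entries when available, else as IDs.
#' @export
searchBic <- function(perm, scomps, param = NBicParam()) {
  perm <- as.integer(perm)
  stopifnot(length(perm) == length(scomps),
            all(sort(perm) == seq_along(scomps)))
  th <- computeThresholds(param@N, param@K, param@O, param@OE)
  scompIdx <- lapply(scomps, as.integer)
  cands <- .enumCandidates(scompIdx, param@N, param@K)
  featNames <- names(scomps)
  if (is.null(featNames)) featNames <- as.character(seq_along(scomps))
  if (!length(cands)) return(BiclusterSet(list()))
  idx <- .candidateIndex(cands, max(unlist(scompIdx)), length(scomps))
  acc <- .localPass(.dfsOrder(idx$featMat, perm), idx$f1, th[["fTH1"]])
  .recsToSet(lapply(cands[acc], function(r)
    list(s = as.character(r$s), f = featNames[r$f], freq = 1L)))
}

# permutation set: all m! orders when that fits the budget, else the identity
# plus a seeded uniform sample of distinct orders (rows of a matrix)
.permutationSet <- function(m, budget) {
  nAll <- if (m <= 12) factorial(m) else Inf
  if (nAll <= budget)
    return(do.call(rbind, .allPermutations(m)))
  seen <- new.env(hash = TRUE)
  out <- matrix(0L, nrow = budget, ncol = m)
  out[1L, ] <- seq_len(m)
  assign(paste(seq_len(m), collapse = ","), TRUE, envir = seen)
  k <- 1L
  while (k < budget) {
    p <- sample.int(m)
    key <- paste(p, collapse = ",")
    if (!exists(key, envir = seen, inherits = FALSE)) {
      k <- k + 1L
      out[k, ] <- p
      assign(key, TRUE, envir = seen)
    }
  }
  out
}

.allPermutations <- function(m) {
  if (m == 1L) return(list(1L))
  sub <- .allPermutations(m - 1L)
  out <- vector("list", m * length(sub))
  k <- 0L
  for (p in sub)
    for (pos in seq_len(m)) {
      k <- k + 1L
      out[[k]] <- append(p, m, after = pos - 1L)
    }
  # identity first, deterministic order
  keys <- vapply(out, function(p) paste(sprintf("%02d", p), collapse = ""), "")
  out[order(keys)]
}

#' Run the full N-way biclustering search
#'
#' The pipeline: sort each feature column into its strongly-expressing
#' subject subset (rule \code{M}); enumerate, once, every feature subset
#' whose subject intersection meets the size constraints (N subjects, K
#' features) — intersections do not depend on feature order, so candidates
#' are shared across permutations; then iterate over feature-order
#' permutations (all \code{m!} when within the budget, otherwise a seeded
#' uniform sample headed by the identity order), replaying the candidates in
#' each permutation's depth-first discovery order through the local
#' validator (fTH1) and folding each temporary list into the final list
#' through the global stability update (fTH2), which accumulates rediscovery
#' frequencies. Finally the stability filter keeps biclusters with frequency
#' at least \code{minFrequency}. Deterministic given the seed.
#'
#' @param mat a [LoadingMatrix-class].
#' @param param an [NBicParam-class].
#' @return a [BiclusterSet-class] of stable biclusters, ordered by frequency
#'   then size.
#' @examples
#' fx <- sim2Fixture(seed = 1)
#' res <- runNBiC(fx$matrix, NBicParam(N = 11, K = 3, O = 35,
#'                                     permutations = 50, seed = 1))
#' length(res)
#' @export
runNBiC <- function(mat, param = NBicParam()) {
  stopifnot(is(mat, "LoadingMatrix"), is(param, "NBicParam"))
  validObject(mat); validObject(param)
  m <- ncol(mat@values)
  if (m < param@K) stop("fewer features than K")
  zs <- if (is.na(param@zscore)) any(mat@featureKind == "symptom") else param@zscore
  scomps <- sortComponents(mat, method = param@M, zscore = zs)
  scompIdx <- lapply(scomps, as.integer)
  th <- computeThresholds(param@N, param@K, param@O, param@OE)
  cands <- .enumCandidates(scompIdx, param@N, param@K)
  if (!length(cands)) return(BiclusterSet(list()))
  idx <- .candidateIndex(cands, nrow(mat@values), m)
  finalIdx <- integer(0)
  freqs <- integer(0)
  .withSeed(param@seed, {
    perms <- .permutationSet(m, param@permutations)
    for (p in seq_len(nrow(perms))) {
      temp <- .localPass(.dfsOrder(idx$featMat, perms[p, ]), idx$f1,
                         th[["fTH1"]])
      upd <- .globalFold(finalIdx, freqs, temp, idx$f1, th[["fTH2"]])
      finalIdx <- upd$idx
      freqs <- upd$freq
    }
  })
  subjIds <- rownames(mat@values)
  featIds <- colnames(mat@values)
  res <- .recsToSet(lapply(seq_along(finalIdx), function(k) {
    r <- cands[[finalIdx[k]]]
    list(s = subjIds[r$s], f = featIds[r$f], freq = freqs[k])
  }))
  stabilityFilter(res, param@minFrequency)
}
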