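#' Generate a background loading matrix
#'
#' Each column is drawn from a normal distribution with its own mean sampled
#' uniformly in \code{meanRange} and common SD \code{sd}, then clipped to
#' [-1, 1] — emulating ICA loading parameters, which are bounded and
#' column-wise shifted. The default mean range is nonnegative so that a
#' planted column keeps a nonnegative overall mean, which [embedBiclusters()]
#' needs to guarantee that planted cells pass the mean-based sorting rules
#' (under a negative column mean the positive-or-negative rule selects
#' extreme negatives and no raised cell can qualify). Individual loadings
#' still take both signs. Deterministic per seed.
#'
#' @param nSubjects,nFeatures matrix dimensions.
#' @param seed RNG seed.
#' @param meanRange range the per-column means are sampled from.
#' @param sd common column SD before clipping.
#' @return a [LoadingMatrix-class] with subjects \code{"1"..."n"} and
#'   features \code{"C1"..."Cm"}.
#' @export
generateBaseMatrix <- function(nSubjects, nFeatures, seed = 1,
                               meanRange = c(0, 0.3), sd = 0.3) {
  stopifnot(nSubjects >= 1, nFeatures >= 1)
  v <- .withSeed(seed, {
    mu <- stats::runif(nFeatures, meanRange[1], meanRange[2])
    vapply(seq_len(nFeatures),
           function(j) stats::rnorm(nSubjects, mu[j], sd),
           numeric(nSubjects))
  })
  v <- matrix(pmin(1, pmax(-1, v)), nrow = nSubjects)
  LoadingMatrix(v, subjectIds = as.character(seq_len(nSubjects)),
                featureLabels = paste0("C", seq_len(nFeatures)))
}

#' Plant biclusters into a loading matrix
#'
#' Raises every cell belonging to a planted bicluster so that it exceeds the
#' positive-entry mean of its column, guaranteeing the planted subjects pass
#' the mean-based sorting rules for the planted features. Cells are first
#' redrawn uniformly in \code{[lo, hi]} (defaults [0.8, 1]); cells still
#' below the post-embedding positive column mean plus a \code{delta} margin
#' are redrawn once in \code{[mean + delta, 1]}. Errors if the guarantee is
#' infeasible (a required level above 1).
#'
#' @param mat a [LoadingMatrix-class].
#' @param truth a [BiclusterSet-class]; subjects/features must exist in
#'   \code{mat}.
#' @param seed RNG seed.
#' @param lo,hi planting range.
#' @param delta safety margin above the positive column mean.
#' @return the modified [LoadingMatrix-class].
#' @export
embedBiclusters <- function(mat, truth, seed = 1, lo = 0.8, hi = 1.0,
                            delta = 0.05) {
  stopifnot(is(mat, "LoadingMatrix"), is(truth, "BiclusterSet"))
  if (!length(truth)) return(mat)
  v <- mat@values
  cells <- unique(do.call(rbind, lapply(truth@elements, function(b) {
    ri <- match(b@subjects, rownames(v))
    ci <- match(b@features, colnames(v))
    if (any(is.na(ri)) || any(is.na(ci)))
      stop("planted bicluster outside matrix bounds")
    expand.grid(r = ri, c = ci)
  })))
  v <- .withSeed(seed, {
    v[as.matrix(cells)] <- stats::runif(nrow(cells), lo, hi)
    # one repair pass against the post-embedding positive column mean
    for (j in unique(cells$c)) {
      rows <- cells$r[cells$c == j]
      posMean <- mean(v[v[, j] > 0, j])
      if (posMean + delta > 1)
        stop(sprintf("embedding infeasible in column %s", colnames(v)[j]))
      low <- rows[v[rows, j] < posMean + delta]
      if (length(low))
        v[cbind(low, j)] <- stats::runif(length(low), posMean + delta, 1)
    }
    v
  })
  # verify the guarantee actually holds after the repair pass
  for (j in unique(cells$c)) {
    rows <- cells$r[cells$c == j]
    if (any(v[rows, j] < mean(v[v[, j] > 0, j])))
      stop(sprintf("embedding failed to dominate positive mean in column %s",
                   colnames(v)[j]))
  }
  LoadingMatrix(v, featureKind = mat@featureKind)
}

#' The 400-subject x 10-feature simulation fixture
#'
#' Background matrix from [generateBaseMatrix()] with the four [sim1Truth()]
#' blocks planted. This is the fixture used to compare the four sorting
#' rules.
#'
#' @param seed RNG seed (background and planting derive distinct streams
#'   from it).
#' @return list with \code{$matrix} ([LoadingMatrix-class], 400 x 10) and
#'   \code{$truth} ([BiclusterSet-class] of 4).
#' @export
sim1Fixture <- function(seed = 1) {
  base <- generateBaseMatrix(400, 10, seed = seed)
  truth <- sim1Truth()
  list(matrix = embedBiclusters(base, truth, seed = seed + 1L), truth = truth)
}

#' The 40-subject x 10-feature simulation fixture
#'
#' Background matrix with the three disjoint [sim2Truth()] blocks planted;
#' the small end-to-end demonstration fixture for the full search.
#'
#' @param seed RNG seed.
#' @return list with \code{$matrix} ([LoadingMatrix-class], 40 x 10) and
#'   \code{$truth} ([BiclusterSet-class] of 3).
#' @export
sim2Fixture <- function(seed = 1) {
  base <- generateBaseMatrix(40, 10, seed = seed)
  truth <- sim2Truth()
  list(matrix = embedBiclusters(base, truth, seed = seed + 1L), truth = truth)
}

#' Generate a fixture with symptom columns coupled to planted blocks
#'
#' Builds an imaging loading matrix with planted biclusters, then appends
#' symptom-score columns: each score is \code{coupling} times the
#' standardized membership indicator of one planted block (cycling over
#' blocks) plus independent Gaussian noise scaled so the population
#' correlation between block membership and score is approximately
#' \code{coupling}; scores are mapped to a questionnaire-like range and
#' clipped to [7, 49]. With \code{coupling = 0} the scores are pure noise —
#' the null fixture for the association stage.
#'
#' @param nSubjects,nImaging imaging matrix dimensions.
#' @param nSymptoms number of symptom columns (3 gives labels
#'   positive/negative/general).
#' @param coupling correlation strength in [0, 1].
#' @param truth planted [BiclusterSet-class]; defaults to [sim1Truth()] when
#'   dimensions allow, else [sim2Truth()].
#' @param seed RNG seed.
#' @return list with \code{$matrix} (a [LoadingMatrix-class] whose last
#'   \code{nSymptoms} columns have \code{featureKind == "symptom"}),
#'   \code{$symptoms} (numeric matrix subjects x scores, same values), and
#'   \code{$truth}.
#' @export
generateSymptomCoupled <- function(nSubjects = 400, nImaging = 10,
                                   nSymptoms = 3, coupling = 0.8,
                                   truth = NULL, seed = 1) {
  stopifnot(coupling >= 0, coupling <= 1, nSymptoms >= 1)
  if (is.null(truth))
    truth <- if (nSubjects >= 400 && nImaging >= 10) sim1Truth() else sim2Truth()
  base <- generateBaseMatrix(nSubjects, nImaging, seed = seed)
  mat <- embedBiclusters(base, truth, seed = seed + 1L)
  labels <- if (nSymptoms == 3) c("positive", "negative", "general")
            else paste0("S", seq_len(nSymptoms))
  sc <- .withSeed(seed + 2L, {
    vapply(seq_len(nSymptoms), function(k) {
      block <- truth[[((k - 1L) %% length(truth)) + 1L]]
      ind <- as.numeric(rownames(mat@values) %in% block@subjects)
      z <- if (stats::sd(ind) > 0) (ind - mean(ind)) / stats::sd(ind)
           else rep(0, nSubjects)
      raw <- coupling * z + sqrt(1 - coupling^2) * stats::rnorm(nSubjects)
      pmin(49, pmax(7, 28 + 7 * raw))
    }, numeric(nSubjects))
  })
  colnames(sc) <- labels
  rownames(sc) <- rownames(mat@values)
  full <- LoadingMatrix(cbind(mat@values, sc),
                        featureKind = c(mat@featureKind,
                                        rep("symptom", nSymptoms)))
  list(matrix = full, symptoms = sc, truth = truth)
}
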