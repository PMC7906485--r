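#' Correlate one bicluster with symptom scores
#'
#' For each symptom score, computes the Pearson correlation between the
#' subject's mean loading over the bicluster's imaging features and the
#' subject's score, with a two-sided p-value from the t distribution. By
#' default the correlation runs across the bicluster's own subjects
#' (within-subgroup association); \code{allSubjects = TRUE} instead runs it
#' across every subject shared by the matrix and the score table, which
#' measures whether expressing the bicluster's feature profile tracks the
#' symptom in the whole cohort. Requires at least 3 usable subjects and
#' nonzero variance on both sides; otherwise the row is flagged
#' not-computable (r and p are NA, never silent NaN).
#'
#' @param mat a [LoadingMatrix-class] containing the bicluster's imaging
#'   features.
#' @param symptoms numeric matrix, subjects (rownames) x scores (colnames).
#' @param bic a [Bicluster-class].
#' @param allSubjects correlate over the whole cohort instead of the
#'   bicluster's subjects.
#' @return data.frame with columns \code{symptom}, \code{n}, \code{r},
#'   \code{p}, \code{computable}.
#' @export
bicSymptomCorrelation <- function(mat, symptoms, bic, allSubjects = FALSE) {
  stopifnot(is(mat, "LoadingMatrix"), is(bic, "Bicluster"),
            is.matrix(symptoms), !is.null(rownames(symptoms)),
            !is.null(colnames(symptoms)))
  imaging <- intersect(bic@features,
                       colnames(mat@values)[mat@featureKind == "imaging"])
  pool <- if (allSubjects) rownames(mat@values) else bic@subjects
  subj <- intersect(pool, intersect(rownames(mat@values), rownames(symptoms)))
  out <- lapply(colnames(symptoms), function(lab) {
    score <- symptoms[subj, lab]
    use <- is.finite(score)
    n <- sum(use)
    if (length(imaging) == 0L || n < 3L)
      return(data.frame(symptom = lab, n = n, r = NA_real_, p = NA_real_,
                        computable = FALSE))
    meanLoad <- rowMeans(mat@values[subj[use], imaging, drop = FALSE])
    if (stats::sd(score[use]) == 0 || stats::sd(meanLoad) == 0)
      return(data.frame(symptom = lab, n = n, r = NA_real_, p = NA_real_,
                        computable = FALSE))
    ct <- stats::cor.test(meanLoad, score[use], method = "pearson")
    data.frame(symptom = lab, n = n, r = unname(ct$estimate),
               p = ct$p.value, computable = TRUE)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone in the input ordering, never below
#' the raw p-values, capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1] (may be empty).
#' @return adjusted p-values, same length and order.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
fdrAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

#' Bicluster-symptom association table
#'
#' Runs [bicSymptomCorrelation()] for every bicluster, applies FDR
#' adjustment (by default within each symptom's family of tests, optionally
#' globally), and flags significance: a row is significant when computable,
#' \code{|r| >= rMin} and \code{p_adj <= alpha}. A bicluster whose feature
#' set contains every symptom column of \code{mat} is labelled a SYMBiC.
#'
#' @param mat a [LoadingMatrix-class].
#' @param bics a [BiclusterSet-class].
#' @param symptoms numeric score matrix (subjects x scores); default: the
#'   symptom columns of \code{mat}.
#' @param rMin minimum absolute correlation, default 0.4.
#' @param alpha significance level on adjusted p-values, default 0.05.
#' @param fdrFamily \code{"per-symptom"} (adjust each symptom's column of
#'   tests separately) or \code{"global"}.
#' @param allSubjects correlate over the whole cohort instead of each
#'   bicluster's subjects (see [bicSymptomCorrelation()]).
#' @return data.frame with one row per (bicluster, symptom): \code{bic},
#'   \code{symptom}, \code{n}, \code{r}, \code{p}, \code{p_adj},
#'   \code{significant}, \code{symbic}.
#' @export
associate <- function(mat, bics, symptoms = NULL, rMin = 0.4, alpha = 0.05,
                      fdrFamily = c("per-symptom", "global"),
                      allSubjects = FALSE) {
  stopifnot(is(mat, "LoadingMatrix"), is(bics, "BiclusterSet"))
  fdrFamily <- match.arg(fdrFamily)
  if (is.null(symptoms)) {
    sCols <- colnames(mat@values)[mat@featureKind == "symptom"]
    if (length(sCols) == 0L)
      stop("no symptom columns in the matrix and none supplied")
    symptoms <- mat@values[, sCols, drop = FALSE]
  }
  if (!length(bics))
    return(data.frame(bic = integer(), symptom = character(), n = integer(),
                      r = numeric(), p = numeric(), p_adj = numeric(),
                      significant = logical(), symbic = logical()))
  symLabels <- colnames(mat@values)[mat@featureKind == "symptom"]
  rows <- lapply(seq_len(length(bics)), function(i) {
    df <- bicSymptomCorrelation(mat, symptoms, bics[[i]],
                                allSubjects = allSubjects)
    df$bic <- i
    df$symbic <- length(symLabels) > 0L &&
      all(symLabels %in% bics[[i]]@features)
    df
  })
  res <- do.call(rbind, rows)
  res$p_adj <- NA_real_
  if (fdrFamily == "per-symptom") {
    for (lab in unique(res$symptom)) {
      sel <- res$symptom == lab & res$computable
      res$p_adj[sel] <- fdrAdjust(res$p[sel])
    }
  } else {
    sel <- res$computable
    res$p_adj[sel] <- fdrAdjust(res$p[sel])
  }
  res$significant <- res$computable & !is.na(res$p_adj) &
    abs(res$r) >= rMin & res$p_adj <= alpha
  res[, c("bic", "symptom", "n", "r", "p", "p_adj", "significant", "symbic")]
}

#' Select significantly associated biclusters
#'
#' A bicluster is flagged when at least one symptom row is significant
#' (\code{|r| >= rMin} and adjusted p \code{<= alpha}). Returns the per-bic
#' summary of flagged biclusters, preserving the SYMBiC label.
#'
#' @param results an [associate()] table (the \code{significant} column is
#'   recomputed from \code{rMin}/\code{alpha} given here).
#' @param rMin minimum absolute correlation.
#' @param alpha level on adjusted p-values.
#' @return data.frame with columns \code{bic}, \code{symbic},
#'   \code{symptoms} (comma-joined significant symptom labels), one row per
#'   flagged bicluster.
#' @export
selectSignificant <- function(results, rMin = 0.4, alpha = 0.05) {
  stopifnot(all(c("bic", "symptom", "r", "p_adj", "symbic") %in%
                names(results)))
  sig <- !is.na(results$r) & !is.na(results$p_adj) &
    abs(results$r) >= rMin & results$p_adj <= alpha
  flagged <- unique(results$bic[sig])
  out <- lapply(sort(flagged), function(i) {
    sel <- results$bic == i
    data.frame(bic = i, symbic = results$symbic[sel][1L],
               symptoms = paste(results$symptom[sel & sig], collapse = ","))
  })
  if (!length(out))
    return(data.frame(bic = integer(), symbic = logical(),
                      symptoms = character()))
  do.call(rbind, out)
}

#' Per-bicluster symptom score summary
#'
#' Arithmetic mean and sample SD of each symptom score over the bicluster's
#' subjects; invariant to subject ordering.
#'
#' @param symptoms numeric score matrix (subjects x scores).
#' @param bic a [Bicluster-class] whose subjects appear in \code{symptoms}.
#' @return data.frame with columns \code{symptom}, \code{n}, \code{mean},
#'   \code{sd}.
#' @export
symptomSummary <- function(symptoms, bic) {
  stopifnot(is(bic, "Bicluster"), is.matrix(symptoms),
            !is.null(rownames(symptoms)))
  miss <- setdiff(bic@subjects, rownames(symptoms))
  if (length(miss)) stop("subjects missing from symptom table: ",
                         paste(miss, collapse = ", "))
  sub <- symptoms[bic@subjects, , drop = FALSE]
  data.frame(symptom = colnames(sub),
             n = nrow(sub),
             mean = colMeans(sub),
             sd = apply(sub, 2L, stats::sd),
             row.names = NULL)
}
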