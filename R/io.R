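.dialectSep <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv"
               else "csv"
  if (dialect == "csv") "," else "\t"
}

#' Read a loading matrix from CSV/TSV
#'
#' Expects a header row of feature labels and a first column of subject
#' identifiers; all remaining cells must be numeric. Non-numeric cells are
#' reported with their row and column; duplicate identifiers fail class
#' validation.
#'
#' @param path file path.
#' @param dialect \code{"auto"} (by extension; default), \code{"csv"} or
#'   \code{"tsv"}.
#' @param symptomCols character vector of feature labels to flag as symptom
#'   columns.
#' @return a validated [LoadingMatrix-class].
#' @export
readLoadingMatrix <- function(path, dialect = "auto",
                              symptomCols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .dialectSep(path, dialect)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected a subject-id column plus features")
  ids <- raw[[1L]]
  labs <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(labs),
                 dimnames = list(ids, labs))
  for (j in seq_along(labs)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   col[bad[1L]], bad[1L], labs[j]))
    vals[, j] <- num
  }
  unknown <- setdiff(symptomCols, labs)
  if (length(unknown))
    stop("symptom columns not present: ", paste(unknown, collapse = ", "))
  LoadingMatrix(vals,
                featureKind = ifelse(labs %in% symptomCols,
                                     "symptom", "imaging"))
}

#' Write a loading matrix to CSV/TSV
#'
#' Values are written with 15 significant digits so a write/read cycle
#' round-trips to at least 12 significant digits.
#'
#' @param mat a [LoadingMatrix-class].
#' @param path output path.
#' @param dialect see [readLoadingMatrix()].
#' @return invisibly, \code{path}.
#' @export
writeLoadingMatrix <- function(mat, path, dialect = "auto") {
  stopifnot(is(mat, "LoadingMatrix"))
  sep <- .dialectSep(path, dialect)
  v <- mat@values
  df <- data.frame(subject = rownames(v),
                   format(v, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a symptom score table from CSV/TSV
#'
#' Same layout as [readLoadingMatrix()]: header of score labels, first
#' column of subject identifiers, numeric cells.
#'
#' @param path file path.
#' @param dialect see [readLoadingMatrix()].
#' @return numeric matrix with subject rownames and score colnames.
#' @export
readSymptomTable <- function(path, dialect = "auto") {
  loadings(readLoadingMatrix(path, dialect))
}

#' Write the bicluster report
#'
#' Emits \code{biclusters.tsv} (one row per bicluster: id, feature labels,
#' subject count, frequency, and per-symptom r / p / adjusted p when an
#' association table is supplied) and \code{biclusters.json} (full subject
#' and feature membership). An empty set yields valid header-only files.
#'
#' @param bics a [BiclusterSet-class].
#' @param dir output directory (created if needed).
#' @param associations optional [associate()] table.
#' @return invisibly, the two file paths.
#' @export
writeBiclusterReport <- function(bics, dir, associations = NULL) {
  stopifnot(is(bics, "BiclusterSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "biclusters.tsv")
  json <- file.path(dir, "biclusters.json")
  df <- as(bics, "data.frame")
  if (!is.null(associations) && nrow(df)) {
    for (lab in unique(associations$symptom)) {
      sel <- associations$symptom == lab
      idx <- match(df$id, associations$bic[sel])
      df[[paste0("r_", lab)]] <- associations$r[sel][idx]
      df[[paste0("p_", lab)]] <- associations$p[sel][idx]
      df[[paste0("p_adj_", lab)]] <- associations$p_adj[sel][idx]
    }
    sig <- tapply(associations$significant, associations$bic, any)
    df$significant <- as.logical(sig[as.character(df$id)])
    sym <- tapply(associations$symbic, associations$bic, any)
    df$symbic <- as.logical(sym[as.character(df$id)])
  }
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  payload <- lapply(seq_len(length(bics)), function(i)
    list(id = i, subjects = as.list(bics[[i]]@subjects),
         features = as.list(bics[[i]]@features),
         frequency = bics[[i]]@frequency))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Read biclusters back from a report directory
#'
#' Reconstructs the [BiclusterSet-class] from \code{biclusters.json},
#' reproducing membership exactly.
#'
#' @param dir directory written by [writeBiclusterReport()].
#' @return a [BiclusterSet-class].
#' @export
readBiclusterReport <- function(dir) {
  json <- file.path(dir, "biclusters.json")
  if (!file.exists(json)) stop("no biclusters.json in ", dir)
  payload <- jsonlite::read_json(json)
  BiclusterSet(lapply(payload, function(p)
    Bicluster(unlist(p$subjects), unlist(p$features),
              frequency = p$frequency)))
}
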