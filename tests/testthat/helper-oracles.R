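# Independent oracles used across the suite. They deliberately avoid the
# package's own similarity/assignment code paths.

# dice similarity by brute-force enumeration of the (subject, feature) cells
bruteDice <- function(a, b) {
  cells <- function(x)
    as.vector(outer(subjects(x), features(x), paste, sep = "\r"))
  ca <- cells(a); cb <- cells(b)
  2 * length(intersect(ca, cb)) / (length(ca) + length(cb))
}

# optimal one-to-one assignment total by exhaustive recursion (small sets)
bruteAssignmentMax <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  best <- function(i, used) {
    if (i > nr) return(0)
    top <- best(i + 1L, used)  # leave row i unassigned
    for (j in seq_len(nc))
      if (!used[j])
        top <- max(top, w[i, j] + best(i + 1L, replace(used, j, TRUE)))
    top
  }
  best(1L, rep(FALSE, nc))
}

# every subset of ids with size >= K, as a canonical sorted set of keys
bruteSubsetKeys <- function(ids, K) {
  out <- character(0)
  for (j in seq(K, length(ids)))
    out <- c(out, apply(utils::combn(sort(ids), j), 2L,
                        paste, collapse = ","))
  sort(out)
}

randomBicluster <- function(subjPool, featPool, minS = 1, minF = 1) {
  ns <- sample(minS:length(subjPool), 1L)
  nf <- sample(minF:length(featPool), 1L)
  Bicluster(sample(subjPool, ns), sample(featPool, nf))
}

# small labelled matrix helper
tinyMatrix <- function(v, n, m) {
  LoadingMatrix(matrix(v, n, m), subjectIds = as.character(seq_len(n)),
                featureLabels = paste0("C", seq_len(m)))
}
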