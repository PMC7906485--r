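test_that("subset enumeration follows depth-first prefix order and counts", {
  got <- enumerateSubsets(1:3, K = 2)
  expect_equal(got, list(c(1L, 2L), c(1L, 2L, 3L), c(1L, 3L), c(2L, 3L)))
  expect_equal(enumerateSubsets(1:4, K = 4), list(1:4))
  expect_length(enumerateSubsets(1:10, K = 1), 2^10 - 1)
  expect_length(enumerateSubsets(1:3, K = 5), 0)
  # count matches sum of binomials for a nontrivial K
  expect_length(enumerateSubsets(1:7, K = 3),
                sum(choose(7, 3:7)))
  # DFS respects the *given* order, not numeric order
  got <- enumerateSubsets(c(3L, 1L, 2L), K = 2)
  expect_equal(got[[1]], c(3L, 1L))
  expect_equal(got[[2]], c(3L, 1L, 2L))
})

test_that("SCOMP intersection is exact, order-independent and identity on singletons", {
  sc <- list(c(1, 2, 3, 4), c(3, 4, 5), c(4, 3, 9))
  expect_setequal(intersectScomps(sc, c(1, 2, 3)), c(3, 4))
  expect_setequal(intersectScomps(sc, c(3, 2, 1)), c(3, 4))
  expect_equal(intersectScomps(sc, 2), c(3, 4, 5))
  expect_length(intersectScomps(list(1:3, 7:9), 1:2), 0)
  expect_error(intersectScomps(sc, c(1, 9)), "unknown")
  # the three disjoint planted subject rows intersect to themselves
  s <- as.integer(subjects(sim2Truth()[[1]]))
  expect_setequal(intersectScomps(list(s, s, s), 1:3), s)
})

test_that("candidate generation equals brute-force power-set enumeration with size gates", {
  set.seed(11)
  for (rep in 1:10) {
    m <- sample(3:5, 1)
    n <- 12
    scomps <- lapply(seq_len(m), function(i) sort(sample(n, sample(3:9, 1))))
    N <- sample(1:3, 1); K <- 2
    cands <- NBiC:::.enumCandidates(scomps, N, K)
    gotKeys <- sort(vapply(cands, function(r) paste(sort(r$f), collapse = ","), ""))
    # brute force over every subset
    wantKeys <- character(0)
    for (key in bruteSubsetKeys(seq_len(m), K)) {
      fs <- as.integer(strsplit(key, ",")[[1]])
      if (length(Reduce(intersect, scomps[fs])) >= N)
        wantKeys <- c(wantKeys, key)
    }
    expect_equal(gotKeys, sort(wantKeys))
    for (r in cands)
      expect_setequal(r$s, Reduce(intersect, scomps[r$f]))
  }
})

test_that("candidate sets are identical across permutations; only order differs", {
  set.seed(3)
  m <- 5
  scomps <- lapply(1:m, function(i) sort(sample(20, sample(6:14, 1))))
  cands <- NBiC:::.enumCandidates(scomps, 2L, 2L)
  idx <- NBiC:::.candidateIndex(cands, 20L, m)
  baseOrder <- NBiC:::.dfsOrder(idx$featMat, 1:m)
  expect_setequal(baseOrder, seq_along(cands))
  for (rep in 1:5) {
    perm <- sample(m)
    ord <- NBiC:::.dfsOrder(idx$featMat, perm)
    expect_setequal(ord, seq_along(cands))
    # the order agrees with lexicographic sorted-position keys (string oracle)
    pos <- integer(m); pos[perm] <- 1:m
    keys <- vapply(cands, function(r)
      paste(sprintf("%03d", sort(pos[r$f])), collapse = ""), "")
    expect_equal(ord, order(keys))
  }
})

test_that("searchBic on disjoint planted components returns one bicluster per block", {
  tr <- sim2Truth()
  scomps <- list()
  # SCOMP for each feature = its block's subjects; unused feature C10 empty-ish
  for (b in seq_len(3)) {
    fs <- as.integer(sub("C", "", features(tr[[b]])))
    for (f in fs) scomps[[f]] <- as.integer(subjects(tr[[b]]))
  }
  scomps[[10]] <- integer(0)
  res <- searchBic(1:10, scomps, NBicParam(N = 11, K = 3, O = 35))
  expect_equal(length(res), 3)
  for (i in 1:3) {
    match <- vapply(seq_len(3), function(b)
      f1Index(res[[i]], Bicluster(subjects(tr[[b]]),
                                  as.character(as.integer(sub("C", "", features(tr[[b]])))))),
      numeric(1))
    expect_equal(max(match), 1)
  }
})

test_that("size gates hold and are monotone in N and K", {
  set.seed(5)
  mat <- tinyMatrix(rnorm(200, 0.15, 0.3), 20, 10)
  res <- runNBiC(mat, NBicParam(N = 4, K = 3, O = 35, permutations = 30,
                                seed = 1, minFrequency = 1))
  for (i in seq_len(length(res))) {
    expect_gte(length(subjects(res[[i]])), 4)
    expect_gte(length(features(res[[i]])), 3)
  }
  nCand <- function(N, K) length(NBiC:::.enumCandidates(
    lapply(seq_len(10), function(j) sortComponent(loadings(mat)[, j], 4)),
    N, K))
  expect_gte(nCand(3, 3), nCand(4, 3))
  expect_gte(nCand(4, 3), nCand(4, 4))
  expect_gte(nCand(4, 3), nCand(5, 3))
})

test_that("enlarging a feature subset never enlarges the intersection", {
  set.seed(9)
  scomps <- lapply(1:6, function(i) sample(30, sample(10:25, 1)))
  for (rep in 1:20) {
    fs <- sample(6, sample(2:5, 1))
    sub <- fs[seq_len(length(fs) - 1L)]
    expect_true(all(intersectScomps(scomps, fs) %in%
                    intersectScomps(scomps, sub)))
  }
})

test_that("the search is deterministic per seed and N > n gives an empty result", {
  fx <- sim2Fixture(seed = 4)
  p <- NBicParam(N = 11, K = 3, O = 35, permutations = 40, seed = 123)
  r1 <- runNBiC(fx$matrix, p)
  r2 <- runNBiC(fx$matrix, p)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  for (i in seq_len(length(r1)))
    expect_identical(subjects(r1[[i]]), subjects(r2[[i]]))
  empty <- runNBiC(fx$matrix, NBicParam(N = 100, K = 3, O = 35,
                                        permutations = 5, seed = 1))
  expect_length(empty, 0)
  expect_error(runNBiC(fx$matrix, NBicParam(N = 5, K = 20, O = 35)),
               "fewer features")
})

test_that("every reported bicluster's subjects equal the exact SCOMP intersection", {
  fx <- sim2Fixture(seed = 2)
  res <- runNBiC(fx$matrix, NBicParam(N = 8, K = 3, O = 35,
                                      permutations = 60, seed = 2,
                                      minFrequency = 1))
  sc <- sortComponents(fx$matrix, method = 4)
  ids <- subjectIds(fx$matrix)
  for (i in seq_len(length(res))) {
    fidx <- match(features(res[[i]]), featureLabels(fx$matrix))
    expect_setequal(subjects(res[[i]]),
                    ids[Reduce(intersect, sc[fidx])])
  }
})

test_that("permutation sets are exhaustive under the budget and distinct above it", {
  all3 <- NBiC:::.permutationSet(3, 10)
  expect_equal(nrow(all3), 6)
  expect_equal(all3[1, ], 1:3)
  expect_equal(nrow(unique(all3)), 6)
  set.seed(1)
  sub <- NBiC:::.permutationSet(8, 50)
  expect_equal(nrow(sub), 50)
  expect_equal(sub[1, ], 1:8)
  expect_equal(nrow(unique(sub)), 50)
})
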