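test_that("mean square residue matches hand computations and additivity", {
  expect_equal(msr(matrix(c(1, 0, 0, 1), 2, 2)), 0.25)
  expect_equal(msr(matrix(3.7, 4, 5)), 0)
  expect_equal(msr(outer(c(1, 2, 5), c(0, 3, 7, 9), "+")), 0)
  expect_equal(msr(matrix(2, 1, 1)), 0)
  expect_error(msr(matrix(numeric(0), 0, 0)), "empty")
  # invariance under row/column constant shifts
  set.seed(2)
  x <- matrix(rnorm(20), 4, 5)
  y <- sweep(x, 1, c(10, -3, 0.5, 7), "+")
  y <- sweep(y, 2, c(1, 2, 3, 4, 5), "+")
  expect_equal(msr(y), msr(x))
})

test_that("consensus score is 1 on identical sets, 0 on disjoint sets, symmetric", {
  tr <- sim1Truth()
  expect_equal(consensusScore(tr, tr), 1)
  a <- BiclusterSet(Bicluster(1:5, paste0("C", 1:2)))
  b <- BiclusterSet(Bicluster(6:9, paste0("C", 3:4)),
                    Bicluster(10:12, paste0("C", 5:6)))
  expect_equal(consensusScore(a, b), 0)
  ab <- BiclusterSet(a[[1]], b[[1]])
  expect_equal(consensusScore(a, ab), 0.5)  # {A} vs {A, B}, F1(A,B)=0
  set.seed(12)
  for (rep in 1:20) {
    s1 <- BiclusterSet(lapply(1:sample(2:4, 1), function(i)
      randomBicluster(as.character(1:10), paste0("C", 1:5))))
    s2 <- BiclusterSet(lapply(1:sample(2:4, 1), function(i)
      randomBicluster(as.character(1:10), paste0("C", 1:5))))
    expect_equal(consensusScore(s1, s2), consensusScore(s2, s1))
  }
  expect_error(consensusScore(BiclusterSet(list()), tr), "nonempty")
})

test_that("the assignment optimum matches exhaustive matching enumeration", {
  set.seed(8)
  for (rep in 1:25) {
    s1 <- BiclusterSet(lapply(seq_len(sample(2:4, 1)), function(i)
      randomBicluster(as.character(1:9), paste0("C", 1:5))))
    s2 <- BiclusterSet(lapply(seq_len(sample(2:4, 1)), function(i)
      randomBicluster(as.character(1:9), paste0("C", 1:5))))
    w <- NBiC:::.f1matrix(s1, s2)
    expect_equal(consensusScore(s1, s2),
                 bruteAssignmentMax(w) / max(length(s1), length(s2)))
  }
})

test_that("consensus never exceeds the mean of row-max F1 values", {
  set.seed(14)
  for (rep in 1:20) {
    s1 <- BiclusterSet(lapply(1:3, function(i)
      randomBicluster(as.character(1:10), paste0("C", 1:5))))
    s2 <- BiclusterSet(lapply(1:3, function(i)
      randomBicluster(as.character(1:10), paste0("C", 1:5))))
    w <- NBiC:::.f1matrix(s1, s2)
    expect_lte(consensusScore(s1, s2), mean(apply(w, 1, max)) + 1e-12)
  }
})

test_that("recovery report finds best matches and handles an empty estimate", {
  tr <- sim2Truth()
  rec <- recoveryReport(tr, tr)
  expect_equal(rec$bestF1, rep(1, 3))
  expect_equal(rec$match, 1:3)
  recEmpty <- recoveryReport(BiclusterSet(list()), tr)
  expect_equal(recEmpty$bestF1, rep(0, 3))
  expect_true(all(is.na(recEmpty$match)))
  # dropping one subject from one truth block: F1 from the cell oracle
  dam <- tr@elements
  dam[[2]] <- Bicluster(subjects(tr[[2]])[-1], features(tr[[2]]))
  rec <- recoveryReport(BiclusterSet(dam), tr)
  expect_equal(rec$bestF1[2], bruteDice(dam[[2]], tr[[2]]))
  expect_equal(rec$bestF1[c(1, 3)], c(1, 1))
})

test_that("planted submatrices are more coherent than random ones of equal size", {
  fx <- sim2Fixture(seed = 3)
  set.seed(99)
  for (b in seq_len(length(fx$truth))) {
    planted <- msr(biclusterValues(fx$matrix, fx$truth[[b]]))
    rand <- replicate(20, {
      rb <- Bicluster(sample(subjectIds(fx$matrix), 13),
                      sample(featureLabels(fx$matrix), 3))
      msr(biclusterValues(fx$matrix, rb))
    })
    expect_lte(planted, mean(rand))
  }
})

test_that("saturated planted signal lets every method recover every block", {
  # planted cells at the column maximum over a tight low background; blocks
  # small enough (13 of 80 subjects) to sit inside every selection rule's
  # window, including the upper quartile
  set.seed(5)
  n <- 80
  v <- matrix(rnorm(n * 10, 0.05, 0.05), n, 10)
  mat <- LoadingMatrix(pmin(pmax(v, -1), 1),
                       subjectIds = as.character(1:n),
                       featureLabels = paste0("C", 1:10))
  tr <- BiclusterSet(Bicluster(1:13, paste0("C", 1:3)),
                     Bicluster(14:26, paste0("C", 4:6)),
                     Bicluster(27:39, paste0("C", 7:9)))
  mat <- embedBiclusters(mat, tr, seed = 6, lo = 0.95, hi = 1.0)
  scores <- vapply(1:4, function(m) {
    res <- runNBiC(mat, NBicParam(N = 11, K = 3, O = 35, M = m,
                                  permutations = 30, seed = 1))
    rec <- recoveryReport(res, tr)
    min(rec$bestF1)
  }, numeric(1))
  expect_true(all(scores >= 0.75))
})

test_that("compareSortingMethods returns a complete, deterministic summary", {
  fx <- sim2Fixture(seed = 1)
  p <- NBicParam(N = 11, K = 3, O = 35, permutations = 20, seed = 1)
  cmp1 <- compareSortingMethods(fx$matrix, fx$truth, p)
  cmp2 <- compareSortingMethods(fx$matrix, fx$truth, p)
  expect_equal(cmp1$summary, cmp2$summary)
  expect_equal(cmp1$summary$method, 1:4)
  expect_true(all(c("meanMSR", "sdMSR", "cScore") %in% names(cmp1$summary)))
  expect_length(cmp1$recovery, 4)
})

test_that("the combined-set variant can merge fragments back into one block", {
  tr <- BiclusterSet(Bicluster(1:10, paste0("C", 1:3)))
  # two halves of the truth block: each fully inside it (sensitivity 1)
  frag <- BiclusterSet(Bicluster(1:5, paste0("C", 1:3)),
                       Bicluster(6:10, paste0("C", 1:3)))
  plain <- consensusScore(frag, tr)
  merged <- consensusScore(frag, tr, mergeSensitivity = 0.9)
  expect_equal(merged, 1)  # union reconstructs the block exactly
  expect_lt(plain, merged)
})
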