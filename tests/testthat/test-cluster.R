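test_that("pointwise t matches the closed form", {
  set.seed(1)
  A <- matrix(rnorm(5 * 20), 5)
  expect_equal(pointwiseT(A, A), rep(0, 20))
  # constant offset with equal within-group variance
  B <- A - 2
  n <- 5
  s2 <- apply(rbind(A, B), 2, function(col)
    (var(col[1:5]) + var(col[6:10])) / 2)
  # direct elementwise recomputation
  direct <- sapply(1:20, function(t) {
    unname(t.test(A[, t], B[, t], var.equal = TRUE)$statistic)
  })
  expect_equal(pointwiseT(A, B), direct, tolerance = 1e-12)
  # zero-variance timepoint -> t = 0 with warning
  A2 <- A; A2[, 3] <- 1
  B2 <- B; B2[, 3] <- 1
  expect_warning(tt <- pointwiseT(A2, B2), "zero pooled variance")
  expect_equal(tt[3], 0)
})

test_that("cluster formation matches the enumerable example", {
  expect_equal(nrow(formClusters(rep(0, 6), 2)), 0)
  cl <- formClusters(c(0, 3, 3, 0, -3, 0), 2)
  expect_equal(cl$startIdx, c(2, 5))
  expect_equal(cl$endIdx, c(3, 5))
  expect_equal(cl$mass, c(6, -3))
  expect_equal(cl$sign, c(1L, -1L))
})

test_that("cluster formation equals a naive run-length scan", {
  for (seed in 1:5) {
    set.seed(seed)
    tv <- rnorm(80, sd = 2)
    thr <- 1.5
    cl <- formClusters(tv, thr)
    # naive scan
    lab <- ifelse(tv > thr, 1L, ifelse(tv < -thr, -1L, 0L))
    ref <- list()
    i <- 1
    while (i <= length(lab)) {
      if (lab[i] != 0) {
        j <- i
        while (j < length(lab) && lab[j + 1] == lab[i]) j <- j + 1
        ref[[length(ref) + 1]] <- c(i, j, sum(tv[i:j]), lab[i])
        i <- j + 1
      } else i <- i + 1
    }
    ref <- do.call(rbind, ref)
    expect_equal(as.matrix(unname(cl)), unname(ref), ignore_attr = TRUE)
  }
})

test_that("observed statistic equals the identity permutation and p > 0", {
  cs <- simulateChangeSeries(8, seq(0, 0.5, by = 0.01), effect = 2,
                             seed = 4)
  cr <- permutationTest(cs$A, cs$B, times = cs$times,
                        nPermutations = 199, seed = 1)
  expect_equal(observedTCourse(cr),
               suppressWarnings(pointwiseT(cs$A, cs$B)))
  tab <- clusterTable(cr)
  expect_true(all(tab$p > 0))
  expect_true(all(tab$p <= 1))
  # cluster masses re-derive from the observed t course
  ref <- formClusters(observedTCourse(cr), cr@threshold)
  expect_equal(tab$mass, ref$mass)
})

test_that("swapping group labels mirrors clusters, p unchanged", {
  cs <- simulateChangeSeries(4, seq(0, 0.5, by = 0.02), effect = 3,
                             seed = 6)
  f <- permutationTest(cs$A, cs$B, times = cs$times,
                       method = "exhaustive")
  g <- permutationTest(cs$B, cs$A, times = cs$times,
                       method = "exhaustive")
  expect_equal(observedTCourse(g), -observedTCourse(f))
  expect_equal(clusterTable(g)$mass, -clusterTable(f)$mass)
  expect_equal(clusterTable(g)$sign, -clusterTable(f)$sign)
  expect_equal(clusterTable(g)$p, clusterTable(f)$p)
})

test_that("Monte Carlo p agrees with exhaustive enumeration at 4+4", {
  cs <- simulateChangeSeries(4, seq(0, 0.5, by = 0.02), effect = 2.5,
                             seed = 12)
  ex <- permutationTest(cs$A, cs$B, times = cs$times,
                        method = "exhaustive")
  mc <- permutationTest(cs$A, cs$B, times = cs$times,
                        nPermutations = 4000, seed = 3)
  pe <- clusterTable(ex)$p
  pm <- clusterTable(mc)$p
  expect_equal(length(pe), length(pm))
  se <- sqrt(pe * (1 - pe) / 4000)
  expect_true(all(abs(pm - pe) <= 2 * se + 1 / 4001))
})

test_that("a strong confined effect yields the minimal p in its window", {
  cs <- simulateChangeSeries(12, seq(0, 0.5, by = 0.005), effect = 4,
                             effectCenter = 0.2, effectWidth = 0.03,
                             noiseSd = 0.5, seed = 8)
  cr <- permutationTest(cs$A, cs$B, times = cs$times,
                        nPermutations = 511, seed = 2)
  tab <- clusterTable(cr)
  top <- tab[which.min(tab$p), ]
  expect_equal(top$p, 1 / 512)
  expect_true(top$start <= 0.25 && top$end >= 0.15)
  expect_equal(top$sign, 1L)
})

test_that("scaling a planted effect up never raises the minimal p", {
  times <- seq(0, 0.5, by = 0.01)
  minp <- sapply(c(1, 2.5, 5), function(eff) {
    ps <- sapply(1:5, function(i) {
      cs <- simulateChangeSeries(10, times, effect = eff,
                                 noiseSd = 1, seed = 900 + i)
      tab <- clusterTable(permutationTest(cs$A, cs$B, times = cs$times,
                                          nPermutations = 255,
                                          seed = i))
      if (nrow(tab)) min(tab$p) else 1
    })
    mean(ps)
  })
  expect_true(all(diff(minp) <= 0))
})
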