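test_that("inner-product matrices match hand-computed values", {
  # two identical Z-scored rows of (-1, 0, 1): every inner product is 2
  z <- rbind(a = c(-1, 0, 1), b = c(-1, 0, 1))
  R <- innerProductMatrix(z)
  expect_equal(gramValues(R),
               matrix(2, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(sampleCount(R), 3L)

  # anti-correlated pair
  R2 <- innerProductMatrix(rbind(a = c(-1, 0, 1), b = c(1, 0, -1)))
  expect_equal(unname(gramValues(R2)), rbind(c(2, -2), c(-2, 2)))

  # orthogonal rows have zero off-diagonal
  R3 <- innerProductMatrix(rbind(a = c(-1, 1, -1, 1) / sqrt(4 / 3),
                                 b = c(-1, -1, 1, 1) / sqrt(4 / 3)))
  expect_equal(gramValues(R3)[1, 2], 0, tolerance = 1e-12)

  # non-centered input is refused unless overridden
  raw <- rbind(a = c(1, 2, 3), b = c(4, 5, 7))
  expect_error(innerProductMatrix(raw), "Z-scored")
  expect_s4_class(innerProductMatrix(raw, check = FALSE), "GramMatrix")
})

test_that("Gram diagonal equals the sd divisor used for Z-scoring", {
  set.seed(4)
  m <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("g", 1:6), NULL))
  expect_equal(diag(gramValues(innerProductMatrix(zscoreRows(m)))),
               rep(9, 6), ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(
    diag(gramValues(innerProductMatrix(zscoreRows(m, sdDivisor = "m")))),
    rep(10, 6), ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("normalized spectra match closed forms and clamp tiny negatives", {
  expect_equal(spectrumValues(normalizedEigenvalues(diag(3))),
               rep(1 / 3, 3))
  expect_equal(
    spectrumValues(normalizedEigenvalues(equicorrMatrix(4, 0.6))),
    c(0.7, 0.1, 0.1, 0.1))
  # rank-1 all-ones matrix: perfect coordination
  ones <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_equal(spectrumValues(normalizedEigenvalues(ones)),
               c(1, 0, 0, 0, 0))

  # genuinely indefinite input is rejected
  bad <- diag(c(1, 1, -0.5))
  expect_error(normalizedEigenvalues(bad), "positive semi-definite")
  expect_error(normalizedEigenvalues(matrix(0, 2, 2)), "degenerate")
})

test_that("spectra are unit-sum, descending, and solver-independent", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    m <- sample(5:30, 1)
    x <- zscoreRows(matrix(rnorm(n * m), n, m,
                           dimnames = list(paste0("g", 1:n), NULL)))
    s <- spectrumValues(normalizedEigenvalues(innerProductMatrix(x)))
    expect_equal(sum(s), 1, tolerance = 1e-10)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
    # oracle: the normalized spectrum of the sample correlation matrix
    oracle <- eigen(cor(t(x)), symmetric = TRUE,
                    only.values = TRUE)$values
    oracle <- sort(pmax(oracle, 0) / sum(pmax(oracle, 0)),
                   decreasing = TRUE)
    expect_equal(s, oracle, tolerance = 1e-8)
  }
})

test_that("spectra are invariant to data scale and sd divisor", {
  set.seed(6)
  m <- matrix(rnorm(48), 4, 12, dimnames = list(paste0("g", 1:4), NULL))
  base <- spectrumValues(normalizedEigenvalues(
    innerProductMatrix(zscoreRows(m))))
  scaled <- spectrumValues(normalizedEigenvalues(
    innerProductMatrix(zscoreRows(m * 250))))
  divisor <- spectrumValues(normalizedEigenvalues(
    innerProductMatrix(zscoreRows(m, sdDivisor = "m"))))
  expect_equal(scaled, base, tolerance = 1e-10)
  expect_equal(divisor, base, tolerance = 1e-10)
})

test_that("raising rho never lowers the population leading eigenvalue", {
  rhos <- seq(0, 0.95, by = 0.05)
  lead <- vapply(rhos, function(r)
    spectrumValues(normalizedEigenvalues(equicorrMatrix(5, r)))[1],
    numeric(1))
  expect_true(all(diff(lead) >= -1e-12))
})

test_that("compareSpectra reports conserved per-rank deltas", {
  s1 <- normalizedEigenvalues(equicorrMatrix(4, 0.2))
  s2 <- normalizedEigenvalues(equicorrMatrix(4, 0.7))
  comp <- compareSpectra(s1, s2, groupA = "CON", groupB = "AD")
  expect_equal(sum(perRankDelta(comp)), 0, tolerance = 1e-10)
  expect_equal(largestDelta(comp),
               spectrumValues(s2)[1] - spectrumValues(s1)[1])
  expect_gt(largestDelta(comp), 0)

  same <- compareSpectra(s1, s1)
  expect_equal(perRankDelta(same), rep(0, 4))

  s3 <- normalizedEigenvalues(equicorrMatrix(5, 0.2))
  expect_error(compareSpectra(s1, s3), "length")
})

test_that("spectrum endpoint deltas reproduce reported-style arithmetic", {
  # endpoint eigenvalues observed in a published two-group comparison of
  # a 4-gene hub-plus-anchor set; middle ranks absorb the remainder
  con <- c(0.543, 0.3, 0.1557, 0.0013)
  ad <- c(0.672, 0.2, 0.0751, 0.0529)
  sCon <- new("EigenSpectrum", values = con, geneIds = letters[1:4])
  sAd <- new("EigenSpectrum", values = ad, geneIds = letters[1:4])
  comp <- compareSpectra(sCon, sAd, groupA = "CON", groupB = "AD")
  expect_equal(largestDelta(comp), 0.129, tolerance = 1e-10)
  expect_equal(smallestDelta(comp), 0.0516, tolerance = 1e-10)
})

test_that("coordinationAnalysis detects group-specific coordination", {
  # anchor tied into the module in AD only: delta must point toward AD
  d <- syntheticDesign(
    modules = list(M1 = c("h1", "h2", "h3", "anchor")),
    rho = list(AD = c(M1 = 0.9), CON = c(M1 = 0.1)),
    groupSizes = c(AD = 1000L, CON = 1000L), seed = 31L)
  comp <- coordinationAnalysis(simulateExpression(d), c("h1", "h2", "h3"),
                               anchorGene = "anchor", refGroup = "CON")
  expect_equal(comp@groupB, "AD")
  expect_gt(largestDelta(comp), 0)
  expect_length(perRankDelta(comp), 4L)

  # null case: no coordination anywhere, deltas stay small
  d0 <- syntheticDesign(
    modules = list(M1 = c("h1", "h2", "h3", "anchor")),
    rho = list(AD = c(M1 = 0), CON = c(M1 = 0)),
    groupSizes = c(AD = 1000L, CON = 1000L), seed = 32L)
  comp0 <- coordinationAnalysis(simulateExpression(d0), c("h1", "h2", "h3"),
                                anchorGene = "anchor", refGroup = "CON")
  expect_lt(abs(largestDelta(comp0)), 0.05)
})

test_that("global-scope standardization is available for sensitivity", {
  se <- simulateExpression(syntheticDesign(seed = 12L))
  w <- coordinationAnalysis(se, c("hubA", "hubB", "hubC"),
                            anchorGene = "anchor", refGroup = "CON")
  g <- coordinationAnalysis(se, c("hubA", "hubB", "hubC"),
                            anchorGene = "anchor", refGroup = "CON",
                            scope = "global")
  expect_s4_class(g, "SpectrumComparison")
  # both scopes agree on the direction for a strong contrast
  expect_equal(sign(largestDelta(g)), sign(largestDelta(w)))
})
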