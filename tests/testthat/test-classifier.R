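test_that("train/test splits are disjoint, exhaustive and reproducible", {
  labels <- rep(c("AD", "CON"), c(60, 40))
  sp <- trainTestSplit(labels, trainFraction = 0.8, seed = 4)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  # stratification: 48/32 in train within one sample
  expect_equal(sum(labels[sp$train] == "AD"), 48, tolerance = 1)
  expect_equal(sum(labels[sp$train] == "CON"), 32, tolerance = 1)

  expect_identical(trainTestSplit(labels, seed = 4), sp)
  expect_false(identical(trainTestSplit(labels, seed = 5)$train,
                         sp$train))
  expect_error(trainTestSplit(labels, trainFraction = 1), "between")
})

test_that("soft voting does the weighted-average arithmetic", {
  p <- lapply(c(0.9, 0.8, 0.2, 0.4), function(q)
    matrix(c(1 - q, q), 1, dimnames = list("s1", c("CON", "AD"))))
  names(p) <- c("RF", "SVM", "GMM", "LM")
  ens <- softVote(p)
  expect_equal(ens["s1", "AD"], (1.8 + 1.6 + 0.2 + 0.4) / 6)
  expect_equal(ens["s1", "AD"], 0.6667, tolerance = 1e-4)
  expect_equal(sum(ens), 1, tolerance = 1e-10)

  # rescaling all weights leaves the ensemble unchanged
  expect_equal(softVote(p, c(RF = 20, SVM = 20, GMM = 10, LM = 10)), ens)
  # equal weights give the plain mean
  expect_equal(softVote(p, c(RF = 1, SVM = 1, GMM = 1, LM = 1))[1, "AD"],
               mean(c(0.9, 0.8, 0.2, 0.4)))
  # identical inputs are a fixed point
  same <- list(RF = p$RF, SVM = p$RF, GMM = p$RF, LM = p$RF)
  expect_equal(softVote(same), p$RF)

  expect_error(softVote(p, c(RF = 2, SVM = 2, GMM = 1)), "LM")
  p$LM <- matrix(c(0.5, 0.5), 1, dimnames = list("s2", c("CON", "AD")))
  expect_error(softVote(p), "identical samples")
})

test_that("label calls use a strict threshold with ties negative", {
  probs <- matrix(c(0.3333, 0.5, 1, 0.6667, 0.5, 0), 3,
                  dimnames = list(paste0("s", 1:3), c("CON", "AD")))
  out <- predictLabels(probs, posClass = "AD")
  expect_equal(unname(out), c("AD", "CON", "CON"))
})

test_that("ROC curves are monotone staircases with correct endpoints", {
  rc <- rocCurve(c(0.9, 0.8, 0.4, 0.2), c("AD", "AD", "CON", "CON"),
                 posClass = "AD")
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  # perfect separation passes through (0, 1)
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_equal(aucScore(c(0.9, 0.8, 0.4, 0.2),
                        c("AD", "AD", "CON", "CON"), "AD"), 1)

  # all scores equal: chance
  rc2 <- rocCurve(rep(0.5, 6), rep(c("AD", "CON"), 3), "AD")
  expect_equal(nrow(rc2), 2L)
  expect_equal(aucScore(rep(0.5, 6), rep(c("AD", "CON"), 3), "AD"), 0.5)

  expect_error(rocCurve(1:3, rep("AD", 3)), "both classes")
})

test_that("trapezoidal AUC equals the pair-counting oracle", {
  expect_equal(aucScore(c(0.9, 0.4, 0.8, 0.2),
                        c("AD", "CON", "CON", "AD"), "AD"), 0.5)
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- c("AD", "CON", sample(c("AD", "CON"), n - 2, replace = TRUE))
    expect_equal(aucScore(scores, labels, "AD"),
                 pairCountAUC(scores, labels, "AD"), tolerance = 1e-10)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  scores <- runif(60)
  labels <- sample(c("AD", "CON"), 60, replace = TRUE,
                   prob = c(0.4, 0.6))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("CON", "AD"),
    direction = "<", quiet = TRUE)))
  expect_equal(aucScore(scores, labels, "AD"), ref, tolerance = 1e-10)
})

test_that("accuracy is the agreement fraction", {
  expect_equal(accuracy(rep("AD", 4), rep("AD", 4)), 1)
  expect_equal(accuracy(c(rep("AD", 78), rep("CON", 22)),
                        rep("AD", 100)), 0.78)
  expect_error(accuracy(character(0), character(0)), "empty")
  expect_error(accuracy("AD", c("AD", "CON")), "equal length")
})

test_that("base learners emit valid probability matrices", {
  set.seed(33)
  x <- rbind(matrix(rnorm(60, 1), 20), matrix(rnorm(60, -1), 20))
  colnames(x) <- paste0("f", 1:3)
  rownames(x) <- paste0("s", 1:40)
  y <- factor(rep(c("AD", "CON"), each = 20), levels = c("CON", "AD"))
  learners <- trainBaseLearners(x, y, seed = 1)
  probs <- predictProbs(learners, x)
  expect_named(probs, c("RF", "SVM", "GMM", "LM"))
  for (p in probs) {
    expect_equal(dim(p), c(40L, 2L))
    expect_equal(colnames(p), c("CON", "AD"))
    expect_equal(unname(rowSums(p)), rep(1, 40), tolerance = 1e-8)
    expect_true(all(p >= 0 & p <= 1))
  }
  # on this cleanly separated training data every learner should learn
  # the direction: mean p_AD higher for true AD samples
  for (p in probs)
    expect_gt(mean(p[y == "AD", "AD"]), mean(p[y == "CON", "AD"]))
})

test_that("the ensemble separates a strongly shifted hub signature", {
  d <- syntheticDesign(
    modules = list(M1 = c("hubA", "hubB", "hubC")),
    rho = list(AD = c(M1 = 0.3), CON = c(M1 = 0.3)),
    meanShift = c(hubA = 2, hubB = 2, hubC = 2), shiftGroup = "AD",
    groupSizes = c(AD = 100L, CON = 100L), seed = 41L, extraGenes = 5L)
  se <- simulateExpression(d)
  res <- runClassification(se, c("hubA", "hubB", "hubC"),
                           posClass = "AD", seed = 41L)
  expect_gt(res$auc, 0.9)
  expect_gt(res$accuracy, 0.8)
  expect_equal(length(res$truth), 40L)
  expect_equal(unname(rowSums(res$ensemble)), rep(1, 40),
               tolerance = 1e-8)
})
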