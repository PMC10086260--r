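#' Seeded, optionally stratified train/test split
#'
#' Splits sample indices into disjoint, exhaustive train and test sets.
#' With `stratified = TRUE` (default) class proportions are preserved to
#' within one sample per class.
#'
#' @param labels vector of class labels, one per sample.
#' @param trainFraction fraction of samples used for training, in (0, 1);
#'   default 0.8 for the usual 80/20 split.
#' @param seed integer seed making the split reproducible.
#' @param stratified preserve class proportions.
#' @return list with integer vectors `train` and `test`.
#' @examples
#' trainTestSplit(rep(c("AD", "CON"), c(60, 40)), seed = 1)$train |> length()
#' @export
trainTestSplit <- function(labels, trainFraction = 0.8, seed = 1L,
                           stratified = TRUE) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("'trainFraction' must lie strictly between 0 and 1")
  n <- length(labels)
  set.seed(seed)
  if (stratified) {
    if (any(table(labels) < 2L))
      stop("stratified split needs at least 2 samples per class")
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nTr <- max(1L, min(length(idx) - 1L,
                         round(trainFraction * length(idx))))
      train <- c(train, sample(idx, nTr))
    }
    train <- sort(train)
  } else {
    train <- sort(sample.int(n, max(1L, min(n - 1L,
                                            round(trainFraction * n)))))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

# ---- base learners -------------------------------------------------------
# Any object with a fit/predict-probability contract can join the
# ensemble; the four reference learners below cover the usual suspects.
# Probability matrices are samples x classes with column names = class
# levels and rows summing to 1.

.probMatrix <- function(p, levels, sampleIds) {
  p <- p[, levels, drop = FALSE]
  p <- p / rowSums(p)
  rownames(p) <- sampleIds
  p
}

.fitRF <- function(x, y) {
  fit <- randomForest::randomForest(x = x, y = y)
  function(newx) .probMatrix(
    stats::predict(fit, newx, type = "prob"), levels(y), rownames(newx))
}

.fitSVM <- function(x, y) {
  fit <- e1071::svm(x = x, y = y, kernel = "radial", probability = TRUE)
  function(newx) {
    pr <- attr(stats::predict(fit, newx, probability = TRUE),
               "probabilities")
    .probMatrix(pr, levels(y), rownames(newx))
  }
}

# Per-class Gaussian class-conditional densities (diagonal covariance)
# with empirical priors; posterior by Bayes' rule in log space.
.fitGMM <- function(x, y) {
  classes <- levels(y)
  prior <- as.numeric(table(y)[classes]) / length(y)
  mu <- lapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  sd <- lapply(classes, function(cl)
    pmax(apply(x[y == cl, , drop = FALSE], 2L, stats::sd), 1e-6))
  function(newx) {
    ll <- vapply(seq_along(classes), function(k)
      colSums(stats::dnorm(t(newx), mu[[k]], sd[[k]], log = TRUE)) +
        log(prior[k]),
      numeric(nrow(newx)))
    ll <- matrix(ll, nrow = nrow(newx),
                 dimnames = list(rownames(newx), classes))
    ll <- ll - apply(ll, 1L, max)
    .probMatrix(exp(ll), classes, rownames(newx))
  }
}

.fitLM <- function(x, y) {
  df <- data.frame(x, check.names = FALSE)
  df$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  function(newx) {
    p2 <- suppressWarnings(
      stats::predict(fit, data.frame(newx, check.names = FALSE),
                     type = "response"))
    p <- cbind(1 - p2, p2)
    colnames(p) <- levels(y)
    .probMatrix(p, levels(y), rownames(newx))
  }
}

#' Train the four reference base learners
#'
#' Fits a random forest, a radial-kernel SVM, a per-class Gaussian
#' density model ("GMM") and a logistic linear model ("LM") on a
#' samples x features matrix, returning per-model probability predictors.
#'
#' @param x numeric samples x features matrix (row names = sample IDs).
#' @param y two-level factor of class labels.
#' @param models which learners to fit.
#' @param seed integer seed for the stochastic learners.
#' @return named list of predictor functions; each maps a new
#'   samples x features matrix to a samples x classes probability matrix.
#' @export
trainBaseLearners <- function(x, y,
                              models = c("RF", "SVM", "GMM", "LM"),
                              seed = 1L) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("need exactly 2 classes")
  fitters <- list(RF = .fitRF, SVM = .fitSVM, GMM = .fitGMM, LM = .fitLM)
  unknown <- setdiff(models, names(fitters))
  if (length(unknown))
    stop("unknown model(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  out <- lapply(models, function(m) fitters[[m]](x, y))
  names(out) <- models
  out
}

#' @describeIn trainBaseLearners apply each trained predictor to new
#'   data, returning a named list of probability matrices.
#' @param learners list returned by `trainBaseLearners`.
#' @param newx samples x features matrix to predict.
#' @export
predictProbs <- function(learners, newx) {
  newx <- as.matrix(newx)
  if (is.null(rownames(newx)))
    rownames(newx) <- paste0("s", seq_len(nrow(newx)))
  lapply(learners, function(f) f(newx))
}

#' Weighted soft-voting ensemble aggregation
#'
#' Combines per-model class-probability matrices into one by the weighted
#' average \eqn{\sum_k w_k p_k / \sum_k w_k}.  The default weights — 2
#' for the random forest and SVM, 1 for the Gaussian and linear models —
#' favor the stronger learners.  The result is invariant to rescaling all
#' weights by a positive constant.
#'
#' @param probs named list of samples x classes probability matrices over
#'   identical samples and classes.
#' @param weights named non-negative weights covering every matrix in
#'   `probs`; at least one must be positive.
#' @return ensemble probability matrix, rows summing to 1.
#' @examples
#' p <- lapply(c(0.9, 0.8, 0.2, 0.4), function(q)
#'   matrix(c(1 - q, q), 1, dimnames = list("s1", c("CON", "AD"))))
#' names(p) <- c("RF", "SVM", "GMM", "LM")
#' softVote(p)  # p_AD = 0.6667
#' @export
softVote <- function(probs, weights = c(RF = 2, SVM = 2, GMM = 1, LM = 1)) {
  if (length(probs) == 0L) stop("no probability matrices supplied")
  missing <- setdiff(names(probs), names(weights))
  if (length(missing))
    stop("no weight for model(s): ", paste(missing, collapse = ", "))
  w <- weights[names(probs)]
  if (any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with a positive sum")
  ref <- probs[[1L]]
  for (p in probs[-1L]) {
    if (!identical(dimnames(p), dimnames(ref)))
      stop("probability matrices must cover identical samples and classes")
  }
  bad <- vapply(probs, function(p)
    any(p < -1e-12 | p > 1 + 1e-12) ||
      max(abs(rowSums(p) - 1)) > 1e-8, logical(1))
  if (any(bad))
    stop("invalid probability matrix from model(s): ",
         paste(names(probs)[bad], collapse = ", "))
  out <- Reduce(`+`, Map(function(p, wk) p * wk, probs, w)) / sum(w)
  out
}

#' Hard labels from class probabilities
#'
#' @param probs samples x classes probability matrix.
#' @param posClass name of the positive class (default: last column).
#' @param threshold call the positive class when its probability strictly
#'   exceeds this; an exact tie goes to the negative class.
#' @return character vector of predicted labels, named by sample.
#' @export
predictLabels <- function(probs, posClass = colnames(probs)[ncol(probs)],
                          threshold = 0.5) {
  if (!posClass %in% colnames(probs))
    stop("'posClass' not among the probability columns")
  neg <- setdiff(colnames(probs), posClass)[1L]
  stats::setNames(
    ifelse(probs[, posClass] > threshold, posClass, neg),
    rownames(probs))
}

#' ROC curve by threshold sweep
#'
#' Sweeps a decision threshold over the distinct scores in descending
#' order; each point is the (false-positive rate, true-positive rate) of
#' calling positive at `score >= threshold`.  The curve is the usual
#' monotone staircase from (0, 0) to (1, 1).
#'
#' @param scores numeric vector of positive-class scores.
#' @param labels vector of true labels.
#' @param posClass which label is positive (default: the label of the
#'   highest score's class order, i.e. the last sorted unique label).
#' @return data.frame with columns `threshold`, `fpr`, `tpr`; the first
#'   row is the empty call set (threshold Inf), the last calls everything.
#' @export
rocCurve <- function(scores, labels,
                     posClass = sort(unique(as.character(labels)))[1L]) {
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length")
  pos <- labels == posClass
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("both classes must be present to build a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & pos), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !pos), numeric(1))
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fp / nN),
             tpr = c(0, tp / nP))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the [rocCurve()] staircase.  Equals the
#' Mann-Whitney statistic: the fraction of (positive, negative) sample
#' pairs in which the positive sample scores higher, ties counting one
#' half.
#'
#' @inheritParams rocCurve
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels,
                     posClass = sort(unique(as.character(labels)))[1L]) {
  rc <- rocCurve(scores, labels, posClass)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1L) + utils::tail(rc$tpr, -1L)) / 2)
}

#' Classification accuracy
#'
#' @param predicted,truth equal-length label vectors.
#' @return fraction of agreeing positions.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have equal length")
  if (length(predicted) == 0L) stop("empty label vectors")
  mean(as.character(predicted) == as.character(truth))
}

#' Train and evaluate the soft-voting ensemble on a gene signature
#'
#' End-to-end classifier evaluation: restrict the expression matrix to a
#' gene signature, make a seeded stratified 80/20 split, train the four
#' base learners on the training samples, soft-vote their test-set
#' probabilities with the given weights, and report test accuracy, AUC
#' and the ROC curve.
#'
#' @param se expression `SummarizedExperiment` with two-group
#'   `colData$group`.
#' @param genes gene signature to use as features.
#' @param posClass positive (case) class label; default the
#'   alphabetically first group.
#' @param weights soft-voting weights (see [softVote()]).
#' @param trainFraction,seed,stratified split parameters
#'   (see [trainTestSplit()]).
#' @return list with elements `probs` (per-model test probabilities),
#'   `ensemble` (ensemble probability matrix), `predicted`, `truth`,
#'   `accuracy`, `auc`, `roc`, and `split`.
#' @export
runClassification <- function(se, genes,
                              posClass = NULL,
                              weights = c(RF = 2, SVM = 2, GMM = 1, LM = 1),
                              trainFraction = 0.8, seed = 1L,
                              stratified = TRUE) {
  labels <- groupLabels(se)
  if (is.null(labels)) stop("expression data carries no group labels")
  if (length(unique(labels)) != 2L) stop("need exactly 2 groups")
  if (is.null(posClass)) posClass <- sort(unique(labels))[1L]
  x <- t(exprsMatrix(selectGenes(se, genes)))
  y <- factor(labels, levels = c(setdiff(sort(unique(labels)), posClass),
                                 posClass))
  split <- trainTestSplit(as.character(y), trainFraction = trainFraction,
                          seed = seed, stratified = stratified)
  learners <- trainBaseLearners(x[split$train, , drop = FALSE],
                                y[split$train],
                                models = names(weights), seed = seed)
  probs <- predictProbs(learners, x[split$test, , drop = FALSE])
  ens <- softVote(probs, weights)
  predicted <- predictLabels(ens, posClass = posClass)
  truth <- as.character(y[split$test])
  list(probs = probs, ensemble = ens, predicted = predicted,
       truth = truth,
       accuracy = accuracy(predicted, truth),
       auc = aucScore(ens[, posClass], truth, posClass = posClass),
       roc = rocCurve(ens[, posClass], truth, posClass = posClass),
       split = split)
}
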