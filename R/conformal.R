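# Mondrian inductive conformal classification on similarity features.
#
# Nonconformity of an example is 1 - P(true class) under the base
# classifier. Calibration is class-conditional (Mondrian), so each class
# carries its own error guarantee at significance level epsilon under
# exchangeability of calibration and test examples.

#' Base learners for the conformal classifier
#'
#' The conformal machinery is learner-agnostic: any object providing a
#' \code{fit(x, y)} function returning a model and a
#' \code{predictProb(model, x)} function returning the probability of the
#' active class works. \code{randomForestLearner()} (bagged trees, the
#' default; \code{classWeight} upweights the active class for imbalanced
#' assays) and \code{xgboostLearner()} (gradient-boosted trees, much
#' faster at high feature counts) are provided.
#'
#' @param ntree number of trees.
#' @param classWeight optional weight of the active class relative to 1
#'   for the inactive class.
#' @return list with elements \code{fit} and \code{predictProb}.
#' @export
randomForestLearner <- function(ntree = 200L, classWeight = NULL) {
    list(
        fit = function(x, y) {
            cw <- if (is.null(classWeight)) NULL else c("0" = 1, "1" = classWeight)
            randomForest::randomForest(
                x = x, y = factor(y, levels = c(0L, 1L)),
                ntree = ntree, classwt = cw)
        },
        predictProb = function(model, x)
            unname(stats::predict(model, x, type = "prob")[, "1"])
    )
}

#' @rdname randomForestLearner
#' @param nrounds,maxDepth,eta boosting rounds, tree depth and learning
#'   rate for the gradient-boosted learner.
#' @export
xgboostLearner <- function(nrounds = 50L, maxDepth = 3L, eta = 0.3) {
    list(
        fit = function(x, y)
            xgboost::xgboost(x, factor(y, levels = c(0L, 1L)),
                             objective = "binary:logistic",
                             nrounds = nrounds, max_depth = maxDepth,
                             learning_rate = eta, nthreads = 1L, seed = 1L),
        predictProb = function(model, x) unname(stats::predict(model, x))
    )
}

#' Similarity feature vectors
#'
#' Represents compounds by their similarity to every compound of a fixed
#' training panel: row \code{q} of the result is the similarity of query
#' \code{q} to each training compound, in training order. These vectors
#' are the input space of the conformal classifier.
#'
#' @param simMat a \linkS4class{SimilarityMatrix} covering queries and
#'   training compounds.
#' @param queryIds compound ids to featurize.
#' @param trainIds training-panel compound ids (feature order).
#' @return numeric matrix, \code{length(queryIds)} x
#'   \code{length(trainIds)}, values in \code{[0, 1]}.
#' @export
similarityFeatures <- function(simMat, queryIds, trainIds) {
    stopifnot(is(simMat, "SimilarityMatrix"))
    ids <- compoundIds(simMat)
    bad <- setdiff(c(queryIds, trainIds), ids)
    if (length(bad))
        stop("ids absent from similarity matrix: ",
             paste(utils::head(bad, 5), collapse = ", "))
    m <- similarityValues(simMat)[queryIds, trainIds, drop = FALSE]
    dimnames(m) <- list(queryIds, trainIds)
    m
}

#' Fit a Mondrian inductive conformal classifier
#'
#' Splits the training data into a proper-training part and a calibration
#' part (stratified at \code{calibrationFraction} unless explicit
#' calibration rows are given), fits the base classifier on the
#' proper-training part only, and stores the calibration nonconformity
#' scores \code{1 - P(true class)} separately per class.
#'
#' @param features numeric feature matrix (rows = compounds); see
#'   [similarityFeatures()].
#' @param labels 0/1 vector (active = 1), one per row.
#' @param calibrationFraction fraction of rows used for calibration
#'   (default 0.2).
#' @param seed integer seed for the stratified calibration split.
#' @param learner base learner (default [randomForestLearner()]).
#' @param calibrationIndices optional explicit row indices of the
#'   calibration part, overriding the internal split.
#' @return a \linkS4class{ConformalModel}.
#' @export
fitICP <- function(features, labels, calibrationFraction = 0.2, seed = 1L,
                   learner = randomForestLearner(),
                   calibrationIndices = NULL) {
    features <- as.matrix(features)
    labels <- as.integer(labels)
    stopifnot(nrow(features) == length(labels),
              all(labels %in% c(0L, 1L)))
    n <- nrow(features)
    if (is.null(calibrationIndices)) {
        stopifnot(calibrationFraction > 0, calibrationFraction < 1)
        calibrationIndices <- integer(0)
        .withSeed(seed, {
            for (cls in c(0L, 1L)) {
                ix <- which(labels == cls)
                k <- round(length(ix) * calibrationFraction)
                calibrationIndices <- c(calibrationIndices, sample(ix, k))
            }
        })
    }
    calibrationIndices <- sort(as.integer(calibrationIndices))
    properIx <- setdiff(seq_len(n), calibrationIndices)
    for (part in list(proper = properIx, calibration = calibrationIndices)) {
        if (length(unique(labels[part])) != 2L)
            stop("both classes must be present in the proper-training and calibration parts")
    }
    base <- .withSeed(seed, learner$fit(features[properIx, , drop = FALSE],
                                        labels[properIx]))
    pCal <- learner$predictProb(base, features[calibrationIndices, , drop = FALSE])
    .assertProb(pCal, "base-model probabilities")
    yCal <- labels[calibrationIndices]
    alpha <- ifelse(yCal == 1L, 1 - pCal, pCal)  # 1 - P(true class)
    new("ConformalModel", baseModel = base, learner = learner,
        calibrationScores = list(
            active = sort(alpha[yCal == 1L], decreasing = TRUE),
            inactive = sort(alpha[yCal == 0L], decreasing = TRUE)),
        featureNames = colnames(features) %||% character(0),
        seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conformal p-values
#'
#' For each query row and class c, computes the nonconformity
#' \code{alpha = 1 - P(c | x)} and the smoothed rank p-value
#' \code{(#\{calibration alpha >= alpha_x\} + 1) / (n_c + 1)}; ties count
#' toward the numerator (conservative).
#'
#' @param model a \linkS4class{ConformalModel}.
#' @param features feature matrix with the training feature columns.
#' @param class \code{"active"} or \code{"inactive"}.
#' @return numeric vector of p-values in \code{(0, 1]}.
#' @export
conformalPValue <- function(model, features, class = c("active", "inactive")) {
    class <- match.arg(class)
    stopifnot(is(model, "ConformalModel"))
    features <- as.matrix(features)
    pAct <- model@learner$predictProb(model@baseModel, features)
    alphaX <- if (class == "active") 1 - pAct else pAct
    cal <- model@calibrationScores[[class]]
    vapply(alphaX, function(a) (sum(cal >= a) + 1) / (length(cal) + 1),
           numeric(1))
}

#' Conformal prediction sets
#'
#' At significance level \code{epsilon}, a class belongs to a query's
#' prediction set when its conformal p-value exceeds \code{epsilon}. Sets
#' may contain both labels (uninformative), one (efficient) or none.
#'
#' @inheritParams conformalPValue
#' @param epsilon significance level in (0, 1); conventional levels are
#'   0.15, 0.20, 0.25, 0.30.
#' @return data.frame with columns \code{pActive}, \code{pInactive},
#'   \code{setActive}, \code{setInactive}, \code{setSize}.
#' @export
predictSet <- function(model, features, epsilon = 0.2) {
    if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
    pA <- conformalPValue(model, features, "active")
    pI <- conformalPValue(model, features, "inactive")
    data.frame(pActive = pA, pInactive = pI,
               setActive = pA > epsilon, setInactive = pI > epsilon,
               setSize = (pA > epsilon) + (pI > epsilon))
}

#' Validity and efficiency of a conformal classifier
#'
#' For every significance level, reports the per-class empirical error
#' (fraction of test examples of that class whose prediction set excludes
#' it — validity requires this to stay at or below epsilon) and the
#' overall efficiency (fraction of test examples receiving exactly one
#' label).
#'
#' @inheritParams conformalPValue
#' @param labels 0/1 test labels.
#' @param epsilons significance levels (default \code{c(0.15, 0.20, 0.25,
#'   0.30)}).
#' @return data.frame with columns \code{epsilon}, \code{class},
#'   \code{error}, \code{efficiency}.
#' @export
validityEfficiency <- function(model, features, labels,
                               epsilons = c(0.15, 0.20, 0.25, 0.30)) {
    features <- as.matrix(features)
    labels <- as.integer(labels)
    if (!nrow(features)) stop("empty test set")
    pA <- conformalPValue(model, features, "active")
    pI <- conformalPValue(model, features, "inactive")
    do.call(rbind, lapply(epsilons, function(eps) {
        inA <- pA > eps; inI <- pI > eps
        eff <- mean(xor(inA, inI))
        data.frame(
            epsilon = eps,
            class = c("active", "inactive"),
            error = c(mean(!inA[labels == 1L]), mean(!inI[labels == 0L])),
            efficiency = eff)
    }))
}
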