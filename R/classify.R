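#' Specify an interaction classifier
#'
#' The default classifier is gradient boosted decision trees (100 trees,
#' depth 3, learning rate 0.1).  Comparators: random forest (500 trees),
#' an RBF-kernel SVM (C = 1, default gamma, Platt-scaled probabilities)
#' and L2-regularized-by-default logistic regression via `glm`.
#'
#' @param algorithm `"gbdt"` (default), `"rf"`, `"svm-rbf"` or `"logreg"`
#' @param threshold decision threshold in (0, 1); a score at or above it
#'   is called interactive
#' @param seed integer seed
#' @param params named list overriding algorithm hyperparameters
#'   (`nrounds`, `max_depth`, `eta` for gbdt; `ntree` for rf; `cost`,
#'   `gamma` for svm-rbf)
#' @return a classifier specification list
#' @export
classifierSpec <- function(algorithm = c("gbdt", "rf", "svm-rbf", "logreg"),
                           threshold = 0.5, seed = 1L, params = list()) {
    algorithm <- match.arg(algorithm)
    if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
        stop("'threshold' must lie strictly between 0 and 1")
    defaults <- switch(algorithm,
        "gbdt" = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
        "rf" = list(ntree = 500L),
        "svm-rbf" = list(cost = 1, gamma = NULL),
        "logreg" = list())
    defaults[names(params)] <- params
    list(algorithm = algorithm, threshold = threshold,
         seed = as.integer(seed), params = defaults)
}

#' Train an interaction classifier
#'
#' @param x numeric feature matrix
#' @param y binary labels (0/1); both classes must be present
#' @param spec from [classifierSpec()]
#' @return a [DTIModel] exposing per-sample interaction probabilities
#'   through [predictScores()]
#' @export
trainClassifier <- function(x, y, spec = classifierSpec()) {
    x <- as.matrix(x)
    y <- as.integer(y)
    if (length(unique(y)) < 2L)
        stop("training data must contain both classes")
    set.seed(spec$seed)
    p <- spec$params
    fit <- switch(spec$algorithm,
        "gbdt" = {
            d <- xgboost::xgb.DMatrix(x, label = y)
            xgboost::xgb.train(
                params = list(objective = "binary:logistic",
                              max_depth = p$max_depth, eta = p$eta,
                              nthread = 1L, seed = spec$seed),
                data = d, nrounds = p$nrounds, verbose = 0)
        },
        "rf" = randomForest::randomForest(x, factor(y, levels = c(0L, 1L)),
                                          ntree = p$ntree),
        "svm-rbf" = {
            args <- list(x = x, y = factor(y, levels = c(0L, 1L)),
                         kernel = "radial", cost = p$cost,
                         probability = TRUE)
            if (!is.null(p$gamma)) args$gamma <- p$gamma
            do.call(e1071::svm, args)
        },
        "logreg" = {
            df <- data.frame(y = y, x)
            suppressWarnings(stats::glm(y ~ ., data = df,
                                        family = stats::binomial()))
        })
    new("DTIModel", algorithm = spec$algorithm, fit = fit, spec = spec)
}

setMethod("show", "DTIModel", function(object) {
    cat("DTIModel: ", object@algorithm, " (threshold ",
        object@spec$threshold, ", seed ", object@spec$seed, ")\n", sep = "")
})

#' @rdname predictScores
#' @export
setMethod("predictScores", "DTIModel", function(object, x) {
    x <- as.matrix(x)
    switch(object@algorithm,
        "gbdt" = stats::predict(object@fit, xgboost::xgb.DMatrix(x)),
        "rf" = unname(stats::predict(object@fit, x, type = "prob")[, "1"]),
        "svm-rbf" = {
            pr <- stats::predict(object@fit, x, probability = TRUE)
            unname(attr(pr, "probabilities")[, "1"])
        },
        "logreg" = unname(suppressWarnings(
            stats::predict(object@fit, data.frame(x), type = "response"))))
})

#' Threshold scores into interaction calls
#'
#' A score at or above the threshold is called interactive (label 1);
#' the boundary score itself is positive.
#'
#' @param scores numeric vector in \[0, 1\]
#' @param threshold decision threshold (default 0.5)
#' @return integer vector of 0/1 labels
#' @export
classifyScores <- function(scores, threshold = 0.5) {
    as.integer(scores >= threshold)
}
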