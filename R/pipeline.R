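#' Pipeline configuration
#'
#' One object carries every stage's hyperparameters; all stages read
#' their settings from it and it is echoed into outputs for provenance.
#' A single global seed fans out to per-stage seeds by fixed offsets, so
#' stages can be rerun independently yet deterministically.
#'
#' @param wordbookK fixed word counts `c(B=, C=, D=)` (default
#'   `c(16, 62, 16)`) or `"auto"` for WSC selection
#' @param kCandidates candidate K range for `"auto"` selection
#' @param drugMode `"dwt"` (default) or `"dft"`
#' @param useSMOTE balance training folds with SMOTE (default `TRUE`)
#' @param smoteK SMOTE neighbor count (default 5)
#' @param smotePaperLiteral flip the SMOTE interpolation sign
#' @param useANN compress features with the trained network (default
#'   `TRUE`)
#' @param annHiddenLayers,annTapLayer,annEpochs,annBatchSize network
#'   settings, see [annConfig()]
#' @param annLearningRate,annLeakySlope network settings
#' @param selfInclusiveWSC internal silhouette mean includes the sample
#'   itself (default `TRUE`); `FALSE` gives the classical variant
#' @param classifier algorithm name, see [classifierSpec()]
#' @param classifierParams hyperparameter overrides
#' @param threshold decision threshold (default 0.5)
#' @param leakage `"fold"` (default: wordbooks, SMOTE and the network are
#'   fitted inside each training fold) or `"full"` (fitted once on the
#'   complete dataset before cross-validation; optimistic, kept for
#'   comparison and clearly recorded in the config echo)
#' @param seed global integer seed
#' @return configuration list
#' @export
pipelineConfig <- function(wordbookK = c(B = 16L, C = 62L, D = 16L),
                           kCandidates = 2:100,
                           drugMode = c("dwt", "dft"),
                           useSMOTE = TRUE, smoteK = 5L,
                           smotePaperLiteral = FALSE,
                           useANN = TRUE, annHiddenLayers = 2L,
                           annTapLayer = 2L, annEpochs = 100L,
                           annBatchSize = 128L, annLearningRate = 0.01,
                           annLeakySlope = 0.3,
                           selfInclusiveWSC = TRUE,
                           classifier = "gbdt", classifierParams = list(),
                           threshold = 0.5,
                           leakage = c("fold", "full"), seed = 42L) {
    list(wordbookK = wordbookK, kCandidates = kCandidates,
         drugMode = match.arg(drugMode),
         useSMOTE = useSMOTE, smoteK = as.integer(smoteK),
         smotePaperLiteral = smotePaperLiteral,
         useANN = useANN, annHiddenLayers = as.integer(annHiddenLayers),
         annTapLayer = as.integer(annTapLayer),
         annEpochs = as.integer(annEpochs),
         annBatchSize = as.integer(annBatchSize),
         annLearningRate = annLearningRate, annLeakySlope = annLeakySlope,
         selfInclusiveWSC = selfInclusiveWSC,
         classifier = classifier, classifierParams = classifierParams,
         threshold = threshold, leakage = match.arg(leakage),
         seed = as.integer(seed))
}

stageSeed <- function(config, stage, fold = 0L) {
    off <- c(folds = 5000L, wordbooks = 1000L, smote = 2000L,
             ann = 3000L, classifier = 4000L)[[stage]]
    config$seed + off + 7L * as.integer(fold)
}

#' Cross-validation scheme
#'
#' @param kind `"kfold"` (default) or `"loocv"`
#' @param k number of folds for `"kfold"` (default 10)
#' @return scheme list
#' @export
cvScheme <- function(kind = c("kfold", "loocv"), k = 10L) {
    kind <- match.arg(kind)
    list(kind = kind, k = as.integer(k))
}

# stratified fold assignment; LOOCV puts each sample in its own fold
makeFolds <- function(labels, scheme, seed) {
    n <- length(labels)
    if (scheme$kind == "loocv") return(as.list(seq_len(n)))
    k <- scheme$k
    set.seed(seed)
    fold <- integer(n)
    for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(f) which(fold == f))
}

fitFoldModel <- function(trainX, trainY, config, fold) {
    extractor <- NULL
    if (config$useSMOTE && length(unique(trainY)) == 2L &&
        min(table(trainY)) > config$smoteK) {
        bal <- smoteMatrix(trainX, trainY, k = config$smoteK,
                           seed = stageSeed(config, "smote", fold),
                           paperLiteral = config$smotePaperLiteral)
        trainX <- bal$x
        trainY <- bal$y
    }
    if (config$useANN) {
        cfg <- annConfig(inputDim = ncol(trainX),
                         hiddenLayers = config$annHiddenLayers,
                         tapLayer = config$annTapLayer,
                         learningRate = config$annLearningRate,
                         epochs = config$annEpochs,
                         batchSize = config$annBatchSize,
                         leakySlope = config$annLeakySlope,
                         seed = stageSeed(config, "ann", fold))
        extractor <- trainANN(trainX, trainY, cfg)
        trainX <- compress(extractor, trainX)
    }
    spec <- classifierSpec(config$classifier, threshold = config$threshold,
                           seed = stageSeed(config, "classifier", fold),
                           params = config$classifierParams)
    list(model = trainClassifier(trainX, trainY, spec),
         extractor = extractor)
}

scoreWithFoldModel <- function(fit, x) {
    if (!is.null(fit$extractor)) x <- compress(fit$extractor, x)
    predictScores(fit$model, x)
}

#' Cross-validated evaluation of the full pipeline
#'
#' For each fold the wordbooks (unless `leakage = "full"`), SMOTE and the
#' network compressor are fitted on the training portion only; the
#' held-out pairs are scored and all held-out predictions are pooled
#' before the metric suite is computed once on the pooled confusion
#' counts.
#'
#' @param sequences named character vector (or `AAStringSet`) of
#'   receptor sequences
#' @param fingerprints named character vector of 256-character hex
#'   fingerprints
#' @param pairs data.frame with `gpcr_id`, `drug_id`, `label`
#' @param config from [pipelineConfig()]
#' @param scheme from [cvScheme()]
#' @return a [CVResult]
#' @export
runCV <- function(sequences, fingerprints, pairs,
                  config = pipelineConfig(),
                  scheme = cvScheme("kfold", 10L)) {
    sequences <- seqsAsCharacter(sequences)
    labels <- as.integer(pairs$label)
    n <- nrow(pairs)
    folds <- makeFolds(labels, scheme, stageSeed(config, "folds"))
    drugFeats <- drugFeatureMatrix(fingerprints, mode = config$drugMode)
    globalWB <- NULL
    globalG <- NULL
    if (config$leakage == "full") {
        globalWB <- buildWordbooks(sequences, K = config$wordbookK,
                                   kCandidates = config$kCandidates,
                                   seed = stageSeed(config, "wordbooks"),
                                   selfInclusive = config$selfInclusiveWSC)
        globalG <- featurizeSequences(sequences, globalWB)
    }
    scores <- numeric(n)
    foldOf <- integer(n)
    for (f in seq_along(folds)) {
        testIdx <- folds[[f]]
        if (length(testIdx) == 0L) next
        trainIdx <- setdiff(seq_len(n), testIdx)
        if (length(unique(labels[trainIdx])) < 2L)
            stop("training fold ", f, " contains a single class; ",
                 "use stratified folds or fewer folds")
        if (config$leakage == "full") {
            gFeats <- globalG
        } else {
            trainSeqIds <- unique(pairs$gpcr_id[trainIdx])
            wb <- buildWordbooks(sequences[trainSeqIds],
                                 K = config$wordbookK,
                                 kCandidates = config$kCandidates,
                                 seed = stageSeed(config, "wordbooks", f),
                                 selfInclusive = config$selfInclusiveWSC)
            gFeats <- featurizeSequences(sequences, wb)
        }
        trainPF <- assemblePairs(gFeats, drugFeats, pairs[trainIdx, ])
        testPF <- assemblePairs(gFeats, drugFeats, pairs[testIdx, ])
        fit <- fitFoldModel(featureMatrix(trainPF), pairLabels(trainPF),
                            config, f)
        scores[testIdx] <- scoreWithFoldModel(fit, featureMatrix(testPF))
        foldOf[testIdx] <- f
    }
    metrics <- metricsFromScores(labels, scores, config$threshold,
                                 auc = length(unique(labels)) == 2L)
    preds <- data.frame(gpcr_id = pairs$gpcr_id, drug_id = pairs$drug_id,
                        fold = foldOf, score = scores,
                        label_pred = classifyScores(scores, config$threshold),
                        label_true = labels)
    new("CVResult", metrics = metrics, predictions = preds, folds = folds,
        config = c(config, list(cv = scheme)))
}

setMethod("show", "CVResult", function(object) {
    cat("CVResult (", object@config$cv$kind, ", ",
        length(object@folds), " folds, pooled)\n", sep = "")
    show(object@metrics)
})

#' DTIPipeline: a fully fitted prediction pipeline
#'
#' @slot wordbooks a [WordbookSet]
#' @slot extractor an [AnnExtractor] or `NULL`
#' @slot model a [DTIModel]
#' @slot config configuration echo
#' @export
setClass("DTIPipeline",
    slots = c(wordbooks = "WordbookSet", extractor = "ANY",
              model = "DTIModel", config = "list"))

#' Fit the pipeline on a complete training set
#'
#' Learns the wordbooks, balances the training pairs, trains the
#' compressor and the classifier on all supplied pairs; the result can
#' score new pairs with [predictPipeline()].
#'
#' @inheritParams runCV
#' @return a [DTIPipeline]
#' @export
trainPipeline <- function(sequences, fingerprints, pairs,
                          config = pipelineConfig()) {
    sequences <- seqsAsCharacter(sequences)
    wb <- buildWordbooks(sequences, K = config$wordbookK,
                         kCandidates = config$kCandidates,
                         seed = stageSeed(config, "wordbooks"),
                         selfInclusive = config$selfInclusiveWSC)
    gFeats <- featurizeSequences(sequences, wb)
    drugFeats <- drugFeatureMatrix(fingerprints, mode = config$drugMode)
    pf <- assemblePairs(gFeats, drugFeats, pairs)
    fit <- fitFoldModel(featureMatrix(pf), pairLabels(pf), config, 0L)
    new("DTIPipeline", wordbooks = wb,
        extractor = if (is.null(fit$extractor)) NULL else fit$extractor,
        model = fit$model, config = config)
}

#' Score new pairs with a fitted pipeline
#'
#' @param pipeline a [DTIPipeline]
#' @param sequences,fingerprints feature sources covering the pair ids
#' @param pairs data.frame with `gpcr_id`, `drug_id` (a `label` column,
#'   if present, is echoed into the output)
#' @return data.frame with `gpcr_id`, `drug_id`, `score`, `label_pred`
#'   (and `label_true` when labels were supplied)
#' @export
predictPipeline <- function(pipeline, sequences, fingerprints, pairs) {
    stopifnot(is(pipeline, "DTIPipeline"))
    sequences <- seqsAsCharacter(sequences)
    hasLabel <- "label" %in% names(pairs)
    p2 <- pairs
    if (!hasLabel) p2$label <- 0L
    gFeats <- featurizeSequences(sequences, pipeline@wordbooks)
    drugFeats <- drugFeatureMatrix(fingerprints,
                                   mode = pipeline@config$drugMode)
    pf <- assemblePairs(gFeats, drugFeats, p2)
    x <- featureMatrix(pf)
    if (!is.null(pipeline@extractor)) x <- compress(pipeline@extractor, x)
    scores <- predictScores(pipeline@model, x)
    out <- data.frame(gpcr_id = p2$gpcr_id, drug_id = p2$drug_id,
                      score = scores,
                      label_pred = classifyScores(scores,
                                                  pipeline@config$threshold))
    if (hasLabel) out$label_true <- as.integer(pairs$label)
    out
}

setMethod("show", "DTIPipeline", function(object) {
    cat("DTIPipeline: ", object@model@algorithm, " on ",
        if (is.null(object@extractor)) "raw" else
            paste0("compressed (", featureDim(object@extractor), "-D)"),
        " features; wordbook dimension ", featureDim(object@wordbooks),
        "\n", sep = "")
})
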