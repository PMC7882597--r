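#' Accessors for package classes
#'
#' `wordCount()` returns the number of words K; `wordMatrix()` the K x d
#' matrix of words; `shapeOffsets()` the residue offsets of a shape;
#' `featureMatrix()` the numeric matrix of a [PairFeatures] object;
#' `pairLabels()` its 0/1 label vector; `featureDim()` the feature
#' dimension an object produces or holds.
#'
#' @param x an object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wordCount", function(x) standardGeneric("wordCount"))

#' @rdname accessors
#' @export
setGeneric("wordMatrix", function(x) standardGeneric("wordMatrix"))

#' @rdname accessors
#' @export
setGeneric("shapeOffsets", function(x) standardGeneric("shapeOffsets"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname accessors
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' Compress pair features through a trained network
#'
#' Runs the forward pass of a trained [AnnExtractor] and returns the
#' activations of its tap layer (by default hidden layer 2), the
#' compressed feature representation.
#'
#' @param object an [AnnExtractor]
#' @param x numeric matrix whose column count matches the network input
#' @return numeric matrix, one row per input row, tap-layer width columns
#' @export
setGeneric("compress", function(object, x) standardGeneric("compress"))

#' Score samples with a fitted classifier
#'
#' @param object a [DTIModel]
#' @param x numeric feature matrix
#' @return numeric vector of interaction probabilities in \[0, 1\]
#' @export
setGeneric("predictScores", function(object, x) standardGeneric("predictScores"))

#' Balance a two-class dataset by SMOTE oversampling
#'
#' @param x a numeric matrix (or a [PairFeatures] object)
#' @param ... passed on to methods; see [smoteMatrix()] for the matrix
#'   work-horse and its arguments
#' @export
setGeneric("smoteOversample", function(x, ...) standardGeneric("smoteOversample"))
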