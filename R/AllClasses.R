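#' @import methods
NULL

#' FragmentShape: the geometry of one wordbook's sequence window
#'
#' A fragment shape describes how residues are sampled from a sliding
#' window: `offsets` are the residue offsets (from the window start) that
#' enter the fragment vector, and the window always advances by
#' `stride = 1`.  The four wordbooks use the shapes single residue
#' (`(0)`), contiguous pair (`(0,1)`), contiguous triple (`(0,1,2)`) and
#' gapped pair separated by one residue (`(0,2)`).
#'
#' @slot offsets integer vector, strictly increasing, starting at 0
#' @slot stride integer, always 1
#' @export
setClass("FragmentShape",
    slots = c(offsets = "integer", stride = "integer"))

setValidity("FragmentShape", function(object) {
    o <- object@offsets
    if (length(o) < 1L) return("offsets must be non-empty")
    if (o[1L] != 0L) return("offsets must start at 0")
    if (length(o) > 1L && any(diff(o) <= 0L))
        return("offsets must be strictly increasing")
    if (!identical(object@stride, 1L)) return("stride must be 1")
    TRUE
})

#' Wordbook: a learned vocabulary of sequence-fragment prototypes
#'
#' Words are K-means cluster centers of hydropathy-encoded sequence
#' fragments sharing one [FragmentShape].  The composition wordbook
#' (id `"A"`) is fixed: its 20 words are the standard amino acids and no
#' clustering is involved.
#'
#' @slot id one of `"A"`, `"B"`, `"C"`, `"D"`
#' @slot shape a [FragmentShape]
#' @slot words K x d numeric matrix of cluster centers (d = number of
#'   offsets); for id `"A"` the rownames are the 20 amino-acid letters
#' @export
setClass("Wordbook",
    slots = c(id = "character", shape = "FragmentShape", words = "matrix"))

setValidity("Wordbook", function(object) {
    if (!object@id %in% c("A", "B", "C", "D")) return("id must be A, B, C or D")
    w <- object@words
    if (nrow(w) < 1L) return("a wordbook needs at least one word")
    if (ncol(w) != length(object@shape@offsets))
        return("word width must match the number of shape offsets")
    if (object@id == "A") {
        if (nrow(w) != 20L || is.null(rownames(w)) ||
            anyDuplicated(rownames(w)))
            return("wordbook A must hold exactly the 20 amino-acid letters")
    } else if (anyDuplicated(w)) {
        return("words must be distinct")
    }
    TRUE
})

#' WordbookSet: the four wordbooks plus featurization provenance
#'
#' @slot books named list of four [Wordbook]s, in order A, B, C, D
#' @slot scale named numeric hydropathy scale used for encoding
#' @slot scaleName name of the scale
#' @slot seed integer seed the wordbooks were learned with
#' @export
setClass("WordbookSet",
    slots = c(books = "list", scale = "numeric", scaleName = "character",
              seed = "integer"))

setValidity("WordbookSet", function(object) {
    if (!identical(names(object@books), c("A", "B", "C", "D")))
        return("books must be named A, B, C, D in order")
    if (!all(vapply(object@books, is, logical(1), "Wordbook")))
        return("all books must be Wordbook objects")
    if (length(object@scale) != 20L)
        return("scale must map exactly 20 amino acids")
    TRUE
})

#' PairFeatures: assembled GPCR-drug pair feature matrix
#'
#' Rows are GPCR-drug pairs; columns are the concatenated GPCR wordbook
#' blocks (A, B, C, D) followed by the 128 drug transform coefficients.
#'
#' @slot features n x D numeric matrix
#' @slot gpcrId,drugId character vectors of length n
#' @slot label integer vector in \{0, 1\} (1 = interactive)
#' @slot synthetic logical vector flagging SMOTE-generated rows
#' @export
setClass("PairFeatures",
    slots = c(features = "matrix", gpcrId = "character", drugId = "character",
              label = "integer", synthetic = "logical"))

setValidity("PairFeatures", function(object) {
    n <- nrow(object@features)
    if (length(object@gpcrId) != n || length(object@drugId) != n ||
        length(object@label) != n || length(object@synthetic) != n)
        return("row metadata lengths must match the feature matrix")
    if (n > 0L && !all(object@label %in% c(0L, 1L)))
        return("labels must be 0 or 1")
    TRUE
})

#' AnnExtractor: trained feed-forward network used as a feature compressor
#'
#' @slot weights list with per-layer weight matrices `W` and bias vectors `b`
#' @slot config list echo of the training configuration (see [annConfig()])
#' @slot tapLayer hidden layer whose activations are emitted by [compress()]
#' @slot lossHistory mean training loss per epoch
#' @export
setClass("AnnExtractor",
    slots = c(weights = "list", config = "list", tapLayer = "integer",
              lossHistory = "numeric"))

#' DTIModel: a fitted interaction classifier
#'
#' @slot algorithm one of `"gbdt"`, `"rf"`, `"svm-rbf"`, `"logreg"`
#' @slot fit the underlying fitted model object
#' @slot spec list echo of the classifier specification
#' @export
setClass("DTIModel",
    slots = c(algorithm = "character", fit = "ANY", spec = "list"))

#' MetricsReport: the evaluation metric suite
#'
#' Holds the confusion counts and the derived metrics: sensitivity (Sn),
#' specificity (Sp), accuracy (Acc), strength (Str, the mean of Sn and
#' Sp), the Matthews correlation coefficient and (optionally) the area
#' under the ROC curve.  Rates are stored as proportions in \[0, 1\].
#'
#' @slot tp,tn,fp,fn confusion counts
#' @slot sn,sp,acc,str proportions in \[0, 1\]
#' @slot mcc Matthews correlation coefficient in \[-1, 1\]
#' @slot auc area under the ROC curve, `NA` when not computed
#' @export
setClass("MetricsReport",
    slots = c(tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric",
              sn = "numeric", sp = "numeric", acc = "numeric", str = "numeric",
              mcc = "numeric", auc = "numeric"))

#' CVResult: pooled cross-validation outcome
#'
#' @slot metrics a [MetricsReport] on the pooled held-out predictions
#' @slot predictions data.frame with `gpcr_id`, `drug_id`, `fold`,
#'   `score`, `label_pred`, `label_true`
#' @slot folds list of held-out index vectors
#' @slot config list echo of the pipeline configuration
#' @export
setClass("CVResult",
    slots = c(metrics = "MetricsReport", predictions = "data.frame",
              folds = "list", config = "list"))
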