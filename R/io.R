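#' Read receptor sequences from FASTA
#'
#' Standard FASTA parsing via Biostrings; the record id is the first
#' whitespace-delimited token of the header.  Duplicate ids are an
#' error; an empty file yields an empty set with a warning.
#'
#' @param path FASTA file
#' @return named character vector of amino-acid sequences
#' @export
readSequences <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    set <- Biostrings::readAAStringSet(path)
    if (length(set) == 0L) {
        warning("no sequences found in ", path)
        return(stats::setNames(character(0), character(0)))
    }
    ids <- sub("\\s.*$", "", names(set))
    if (anyDuplicated(ids))
        stop("duplicate sequence ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    out <- toupper(as.character(set))
    names(out) <- ids
    out
}

#' Read drug fingerprints from TSV
#'
#' Expects two tab-separated columns, drug id and 256-character
#' hexadecimal string, one row per drug, no header.  CRLF endings are
#' accepted.  Every row is validated (length and hex alphabet).
#'
#' @param path TSV file
#' @return named character vector of hex strings
#' @export
readFingerprints <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(stats::setNames(character(0), character(0)))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
        stop("row ", bad[1L], " of ", path,
             " does not have two tab-separated fields")
    ids <- vapply(parts, `[[`, character(1), 1L)
    hex <- vapply(parts, `[[`, character(1), 2L)
    for (i in seq_along(hex))
        tryCatch(parseFingerprint(hex[i]),
                 error = function(e)
                     stop("row ", i, " (", ids[i], ") of ", path, ": ",
                          conditionMessage(e), call. = FALSE))
    if (anyDuplicated(ids))
        stop("duplicate drug ids in ", path)
    stats::setNames(hex, ids)
}

#' Read the labelled pair table from TSV
#'
#' Expects a header row with columns `gpcr_id`, `drug_id`, `label` and
#' 0/1 labels.  Duplicate pairs are preserved with a warning.
#'
#' @param path TSV file
#' @return data.frame with `gpcr_id`, `drug_id`, `label` (integer)
#' @export
readPairs <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("gpcr_id", "drug_id", "label")
    if (!all(need %in% names(df)))
        stop(path, " must have a header with columns gpcr_id, drug_id, label")
    labTok <- trimws(as.character(df$label))
    if (!all(labTok %in% c("0", "1")))
        stop("unknown label token(s) in ", path, ": ",
             paste(unique(labTok[!labTok %in% c("0", "1")]), collapse = ", "))
    df$label <- as.integer(labTok)
    df$gpcr_id <- as.character(df$gpcr_id)
    df$drug_id <- as.character(df$drug_id)
    key <- paste(df$gpcr_id, df$drug_id)
    if (anyDuplicated(key))
        warning("duplicate pairs in ", path, " (kept)")
    df[need]
}

#' Export a feature matrix as CSV
#'
#' @param m numeric matrix with rownames as ids
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeFeatureCSV <- function(m, path) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     row.names = NULL)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Export pooled cross-validation predictions as CSV
#'
#' @param result a [CVResult]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writePredictionsCSV <- function(result, path) {
    stopifnot(is(result, "CVResult"))
    utils::write.csv(result@predictions, path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' Write a metrics report (with config echo) as JSON
#'
#' The JSON is deterministic: identical metrics and configuration give
#' byte-identical files.
#'
#' @param metrics a [MetricsReport]
#' @param path output JSON path
#' @param config optional configuration list echoed for provenance
#' @return `path`, invisibly
#' @export
writeMetricsJSON <- function(metrics, path, config = NULL) {
    stopifnot(is(metrics, "MetricsReport"))
    obj <- list(
        counts = list(TP = metrics@tp, TN = metrics@tn,
                      FP = metrics@fp, FN = metrics@fn),
        Sn_pct = 100 * metrics@sn, Sp_pct = 100 * metrics@sp,
        Acc_pct = 100 * metrics@acc, Str_pct = 100 * metrics@str,
        MCC = metrics@mcc,
        AUC = if (is.na(metrics@auc)) NULL else metrics@auc)
    if (!is.null(config)) obj$config <- config
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}
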