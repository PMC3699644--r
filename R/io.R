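#' Read a gene x sample expression table
#'
#' Parses a tab-separated expression table: first column gene identifiers,
#' header row of sample identifiers, numeric body. Thousands separators
#' (`"2,312"`) are accepted and stripped, so `"1,204"` and `"1204"` parse to
#' the same value.
#'
#' @param path path to a TSV file (UTF-8, header mandatory).
#' @param unit the unit the stored values are in: `"counts"` or `"rpm"`.
#' @return A [MarkerExperiment-class] with the declared unit.
#' @details Duplicate gene identifiers (case-insensitive) are a hard error
#'   listing the offending ids, never silently merged. A non-numeric cell is
#'   a parse error naming its gene row and sample column.
#' @export
readExpressionTable <- function(path, unit = c("counts", "rpm")) {
    unit <- match.arg(unit)
    raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                             check.names = FALSE, fileEncoding = "UTF-8")
    if (ncol(raw) < 2L)
        stop("expression table needs a gene-id column plus >= 1 sample column")
    genes <- trimws(raw[[1L]])
    dup <- unique(genes[duplicated(tolower(genes))])
    if (length(dup))
        stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
    body <- raw[, -1L, drop = FALSE]
    num <- vapply(seq_along(body), function(j) {
        cell <- gsub(",", "", trimws(body[[j]]), fixed = TRUE)
        val <- suppressWarnings(as.numeric(cell))
        bad <- which(is.na(val) & !(is.na(cell) | cell == ""))
        if (length(bad))
            stop("non-numeric value ", sQuote(body[[j]][bad[1L]]),
                 " at gene ", sQuote(genes[bad[1L]]),
                 ", sample ", sQuote(colnames(body)[j]))
        val[is.na(val)] <- 0
        val
    }, numeric(nrow(raw)))
    if (is.null(dim(num))) num <- matrix(num, nrow = nrow(raw))
    dimnames(num) <- list(genes, colnames(body))
    if (any(num < 0))
        stop("negative expression values are not allowed")
    MarkerExperiment(num, unit = unit)
}

#' Read sample metadata / gene annotation tables
#'
#' `readSampleMetadata()` expects a TSV with columns `sample_id`,
#' `class_label`, `library_size`; `readGeneAnnotation()` a TSV with columns
#' `gene_id`, `categories` (semicolon-delimited labels) and `specificity`
#' (`specific`, `ubiquitous`, `inconclusive` or `restricted:<site>`).
#'
#' @param path path to the TSV file.
#' @return a `data.frame`.
#' @export
readSampleMetadata <- function(path) {
    meta <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                              fileEncoding = "UTF-8")
    need <- c("sample_id", "class_label", "library_size")
    if (!all(need %in% colnames(meta)))
        stop("sample metadata must have columns ", paste(need, collapse = ", "))
    meta$sample_id <- as.character(meta$sample_id)
    meta$class_label <- as.character(meta$class_label)
    meta$library_size <- suppressWarnings(as.numeric(gsub(",", "", meta$library_size)))
    if (anyNA(meta$library_size) || any(meta$library_size <= 0))
        stop("library_size must be a positive number for every sample")
    meta
}

#' @rdname readSampleMetadata
#' @export
readGeneAnnotation <- function(path) {
    ann <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character", fileEncoding = "UTF-8")
    need <- c("gene_id", "categories", "specificity")
    if (!all(need %in% colnames(ann)))
        stop("gene annotation must have columns ", paste(need, collapse = ", "))
    ann$specificity[is.na(ann$specificity) | ann$specificity == ""] <- "inconclusive"
    .checkSpecificity(ann$specificity)
    if (anyDuplicated(tolower(ann$gene_id)))
        stop("duplicate gene_id in annotation: ",
             paste(unique(ann$gene_id[duplicated(tolower(ann$gene_id))]),
                   collapse = ", "))
    ann
}

.reportColumns <- c("gene_id", "rpm_cec_young", "rpm_cec_old",
                    "rpm_cec_culture", "rpm_stroma", "fold_young_old",
                    "fold_young_culture", "fold_young_stroma", "flaws",
                    "specificity_note")

#' Write a marker report (TSV + JSON twin)
#'
#' Writes marker records as a deterministic TSV with fixed column order —
#' gene id, per-class RPM, the three fold changes, flaw flags, specificity
#' note — plus a machine-readable JSON twin (same path with a `.json`
#' extension) that keeps full numeric precision.
#'
#' In the TSV, RPM values are printed half-up rounded to `rpmDigits` decimals
#' (default 0, the convention of the human-readable screen tables; use 2 for
#' low-expression tables) and fold changes to one decimal with `"n/a"` for an
#' undefined fold (stroma RPM of exactly 0).
#'
#' @param records a marker record table as produced by [markerTable()],
#'   [stableCecFilter()] or [stromaAbsentFilter()]; may have zero rows, in
#'   which case a header-only TSV is written.
#' @param path output TSV path.
#' @param rpmDigits integer, decimals for RPM columns in the TSV.
#' @return invisibly, a character vector with the TSV and JSON paths.
#' @export
writeMarkerReport <- function(records, path, rpmDigits = 0) {
    df <- as.data.frame(records)
    for (col in .reportColumns)
        if (!col %in% colnames(df))
            df[[col]] <- if (col %in% c("gene_id", "flaws", "specificity_note"))
                character(nrow(df)) else rep(NA_real_, nrow(df))
    df <- df[, .reportColumns, drop = FALSE]
    out <- df
    for (col in grep("^rpm_", .reportColumns, value = TRUE))
        out[[col]] <- sprintf(paste0("%.", rpmDigits, "f"),
                              roundHalfUp(df[[col]], rpmDigits))
    for (col in grep("^fold_", .reportColumns, value = TRUE))
        out[[col]] <- formatFold(df[[col]])
    ok <- tryCatch({
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, fileEncoding = "UTF-8")
        TRUE
    }, error = function(e) stop("cannot write report to ", path, ": ",
                                conditionMessage(e)))
    jsonPath <- paste0(tools::file_path_sans_ext(path), ".json")
    jsonlite::write_json(df, jsonPath, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE)
    invisible(c(tsv = path, json = jsonPath))
}

#' Read back a marker report
#'
#' Reads the JSON twin written by [writeMarkerReport()] (full precision), or
#' the TSV itself if no JSON twin exists (values then carry the formatting
#' precision of the report).
#'
#' @param path path to the `.tsv` or `.json` report.
#' @return a `data.frame` with the fixed report columns; undefined folds are
#'   `NA`.
#' @export
readMarkerReport <- function(path) {
    jsonPath <- paste0(tools::file_path_sans_ext(path), ".json")
    if (file.exists(jsonPath)) {
        df <- jsonlite::fromJSON(jsonPath)
        if (length(df) == 0L || is.null(dim(df)))
            df <- as.data.frame(stats::setNames(
                rep(list(character(0)), length(.reportColumns)), .reportColumns))
        return(as.data.frame(df))
    }
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            colClasses = "character", fileEncoding = "UTF-8")
    for (col in grep("^(rpm|fold)_", colnames(df), value = TRUE)) {
        x <- df[[col]]
        x[x == "n/a"] <- NA
        df[[col]] <- as.numeric(x)
    }
    df
}
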