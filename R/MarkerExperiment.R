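#' Construct a MarkerExperiment
#'
#' Builds the central gene x sample container of the workflow from a numeric
#' matrix of expression values.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids); all values finite and >= 0.
#' @param unit `"counts"` (raw uniquely-mapped read counts) or `"rpm"`.
#' @param classLabels optional character vector of sample class labels
#'   (`cec_young`, `cec_old`, `cec_culture`, `stroma`, `tissue_panel:<name>`),
#'   either named by sample id or in column order.
#' @param librarySizes optional numeric vector of total uniquely mapping reads
#'   per sample (required later by [rpmNormalize()]).
#' @param categories optional per-gene functional categories, a character
#'   vector of semicolon-delimited labels (named by gene id or in row order).
#' @param specificity optional per-gene external tissue-specificity verdict:
#'   `specific`, `ubiquitous`, `inconclusive`, or `restricted:<site>`.
#'   Unannotated genes default to `inconclusive`.
#' @return A [MarkerExperiment-class] object.
#' @examples
#' m <- matrix(c(250, 10, 0, 40), 2, 2,
#'             dimnames = list(c("SLC4A11", "CYYR1"), c("s1", "s2")))
#' me <- MarkerExperiment(m, unit = "counts",
#'                        classLabels = c("cec_young", "stroma"),
#'                        librarySizes = c(2.5e6, 2e6))
#' exprUnit(me)
#' @export
MarkerExperiment <- function(values, unit = c("counts", "rpm"),
                             classLabels = NULL, librarySizes = NULL,
                             categories = NULL, specificity = NULL) {
    unit <- match.arg(unit)
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("'values' must have gene identifiers as rownames")
    if (is.null(colnames(values)))
        colnames(values) <- paste0("sample", seq_len(ncol(values)))
    cd <- DataFrame(row.names = colnames(values))
    cd$class_label <- .alignMeta(classLabels, colnames(values), NA_character_)
    cd$library_size <- .alignMeta(librarySizes, colnames(values), NA_real_)
    rd <- DataFrame(row.names = rownames(values))
    rd$categories <- .alignMeta(categories, rownames(values), "")
    spec <- .alignMeta(specificity, rownames(values), "inconclusive")
    spec[is.na(spec) | spec == ""] <- "inconclusive"
    .checkSpecificity(spec)
    rd$specificity <- spec
    se <- SummarizedExperiment(assays = SimpleList(values = values),
                               colData = cd, rowData = rd)
    new("MarkerExperiment", se, unit = unit)
}

## align a possibly named metadata vector to ids, filling with `fill`
.alignMeta <- function(x, ids, fill) {
    out <- rep(fill, length(ids))
    if (is.null(x)) return(out)
    if (!is.null(names(x))) {
        hit <- match(ids, names(x))
        out[!is.na(hit)] <- x[hit[!is.na(hit)]]
    } else {
        if (length(x) != length(ids))
            stop("unnamed metadata must have one entry per id")
        out <- x
    }
    out
}

.checkSpecificity <- function(x) {
    ok <- x %in% c("specific", "ubiquitous", "inconclusive") |
        grepl("^restricted:", x)
    if (any(!ok))
        stop("invalid specificity value(s): ",
             paste(unique(x[!ok]), collapse = ", "),
             " (expected specific, ubiquitous, inconclusive or restricted:<site>)")
    invisible(x)
}

#' @describeIn MarkerExperiment expression unit, `"counts"` or `"rpm"`.
#' @param x,object a `MarkerExperiment`.
#' @export
exprUnit <- function(x) {
    stopifnot(is(x, "MarkerExperiment"))
    x@unit
}

#' @describeIn MarkerExperiment the gene x sample matrix of values.
#' @export
exprValues <- function(x) {
    stopifnot(is(x, "MarkerExperiment"))
    assay(x, "values")
}

#' @describeIn MarkerExperiment per-sample class labels (named).
#' @export
classLabels <- function(x) {
    stopifnot(is(x, "MarkerExperiment"))
    stats::setNames(colData(x)$class_label, colnames(x))
}

#' @describeIn MarkerExperiment per-sample library sizes (named).
#' @export
librarySizes <- function(x) {
    stopifnot(is(x, "MarkerExperiment"))
    stats::setNames(colData(x)$library_size, colnames(x))
}

#' @describeIn MarkerExperiment per-gene category labels as a named list of
#'   character vectors (split on `;`).
#' @export
geneCategories <- function(x) {
    stopifnot(is(x, "MarkerExperiment"))
    raw <- rowData(x)$categories
    out <- strsplit(ifelse(is.na(raw), "", raw), ";", fixed = TRUE)
    out <- lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
    names(out) <- rownames(x)
    out
}

#' @describeIn MarkerExperiment per-gene specificity verdicts (named).
#' @export
geneSpecificity <- function(x) {
    stopifnot(is(x, "MarkerExperiment"))
    stats::setNames(rowData(x)$specificity, rownames(x))
}

#' Attach sample metadata or gene annotation to a MarkerExperiment
#'
#' @param x a [MarkerExperiment-class].
#' @param meta a `data.frame`/`DataFrame` with columns `sample_id`,
#'   `class_label`, `library_size` (as read by [readSampleMetadata()]).
#' @return the updated `MarkerExperiment`.
#' @details Every sample of `x` must have exactly one metadata row; extra
#'   metadata rows for unknown samples are an error.
#' @export
attachSampleMetadata <- function(x, meta) {
    stopifnot(is(x, "MarkerExperiment"))
    meta <- as.data.frame(meta)
    need <- c("sample_id", "class_label", "library_size")
    if (!all(need %in% colnames(meta)))
        stop("metadata must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(meta$sample_id))
        stop("duplicated sample_id in metadata: ",
             paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
    hit <- match(colnames(x), meta$sample_id)
    if (anyNA(hit))
        stop("no metadata row for sample(s): ",
             paste(colnames(x)[is.na(hit)], collapse = ", "))
    extra <- setdiff(meta$sample_id, colnames(x))
    if (length(extra))
        stop("metadata for unknown sample(s): ", paste(extra, collapse = ", "))
    colData(x)$class_label <- as.character(meta$class_label[hit])
    colData(x)$library_size <- as.numeric(meta$library_size[hit])
    validObject(x)
    x
}

#' @rdname attachSampleMetadata
#' @param annotation a `data.frame`/`DataFrame` with columns `gene_id`,
#'   `categories` (semicolon-delimited), `specificity` (as read by
#'   [readGeneAnnotation()]). Genes without a row default to empty categories
#'   and `inconclusive` specificity.
#' @export
attachGeneAnnotation <- function(x, annotation) {
    stopifnot(is(x, "MarkerExperiment"))
    annotation <- as.data.frame(annotation)
    need <- c("gene_id", "categories", "specificity")
    if (!all(need %in% colnames(annotation)))
        stop("annotation must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(tolower(annotation$gene_id)))
        stop("duplicated gene_id in annotation")
    hit <- match(tolower(rownames(x)), tolower(annotation$gene_id))
    cats <- ifelse(is.na(hit), "", as.character(annotation$categories[hit]))
    spec <- ifelse(is.na(hit), "inconclusive",
                   as.character(annotation$specificity[hit]))
    spec[is.na(spec) | spec == ""] <- "inconclusive"
    .checkSpecificity(spec)
    rowData(x)$categories <- cats
    rowData(x)$specificity <- spec
    validObject(x)
    x
}

setMethod("show", "MarkerExperiment", function(object) {
    cat("MarkerExperiment with", nrow(object), "genes and",
        ncol(object), "samples [unit:", object@unit, "]\n")
    cl <- classLabels(object)
    if (!all(is.na(cl))) {
        tab <- table(cl, useNA = "no")
        cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                                collapse = ", "), "\n")
    }
    callNextMethod()
})

## mean expression per (gene, class); requires class labels
.classMeans <- function(x, classes = NULL) {
    cl <- classLabels(x)
    if (all(is.na(cl)))
        stop("no class labels attached; see attachSampleMetadata()")
    if (is.null(classes)) classes <- unique(cl[!is.na(cl)])
    missing <- setdiff(classes, cl)
    if (length(missing))
        stop("class(es) missing from the experiment: ",
             paste(missing, collapse = ", "))
    v <- exprValues(x)
    out <- vapply(classes, function(k)
        rowMeans(v[, which(cl == k), drop = FALSE]), numeric(nrow(x)))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(x),
                                         dimnames = list(rownames(x), classes))
    colnames(out) <- classes
    out
}

#' Per-class mean expression
#'
#' Averages expression over the samples of each class (with the study design
#' of one library per class this is the per-sample value itself).
#'
#' @param x a [MarkerExperiment-class] with class labels attached.
#' @param classes character vector of class labels to extract; defaults to
#'   all labelled classes. Missing classes are an error naming them.
#' @return numeric matrix, genes x classes.
#' @export
classRpm <- function(x, classes = NULL) .classMeans(x, classes)
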