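#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData colData<- rowData rowData<-
NULL

setOldClass("hclust")

#' Core classes of the CEC marker-discovery workflow
#'
#' `MarkerExperiment` is a [SummarizedExperiment::SummarizedExperiment]
#' holding one gene x sample assay of non-negative expression values whose
#' unit is either raw uniquely-mapped read counts (`"counts"`) or reads per
#' million (`"rpm"`). Sample class labels (`cec_young`, `cec_old`,
#' `cec_culture`, `stroma`, or `tissue_panel:<name>`) and library sizes (total
#' uniquely mapping reads) live in `colData`; per-gene functional categories
#' and an external tissue-specificity verdict live in `rowData`.
#'
#' @slot unit character(1), `"counts"` or `"rpm"`.
#'
#' @section Validity:
#' All assay values must be finite and >= 0 with no missing cells; gene
#' identifiers must be unique after case-folding; when the unit is
#' `"counts"`, any declared library sizes must be positive.
#'
#' @aliases MarkerExperiment-class
#' @seealso [MarkerExperiment()], [readExpressionTable()], [rpmNormalize()]
#' @exportClass MarkerExperiment
setClass("MarkerExperiment",
    contains = "SummarizedExperiment",
    representation(unit = "character"),
    prototype(unit = "counts"))

.coreClasses <- c("cec_young", "cec_old", "cec_culture", "stroma")

setValidity("MarkerExperiment", function(object) {
    msg <- character()
    if (length(object@unit) != 1L || !object@unit %in% c("counts", "rpm"))
        msg <- c(msg, "'unit' must be one of \"counts\", \"rpm\"")
    if (!"values" %in% assayNames(object))
        msg <- c(msg, "assay 'values' is missing")
    else {
        v <- assay(object, "values")
        if (anyNA(v) || any(!is.finite(v)))
            msg <- c(msg, "expression values must be finite and non-missing")
        else if (any(v < 0))
            msg <- c(msg, "expression values must be non-negative")
    }
    g <- rownames(object)
    if (is.null(g) || anyDuplicated(tolower(g)))
        msg <- c(msg, "gene identifiers must be present and unique (case-insensitively)")
    cd <- colData(object)
    if ("library_size" %in% colnames(cd) && object@unit == "counts") {
        ls <- cd$library_size
        if (any(!is.na(ls) & ls <= 0))
            msg <- c(msg, "library sizes must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' Filter thresholds of the marker selection cascade
#'
#' Holds the four thresholds that drive marker selection: the minimum RPM for
#' a gene to count as expressed in each CEC class (default 10, strict `>`),
#' the minimum young-CEC/stroma fold contrast (default 2, evaluated on the
#' half-up one-decimal rounded fold, inclusive), the maximum tolerated
#' young/old age fold (default 2, two-sided: the rounded young/old fold must
#' lie in `[1/max, max]`), and the stroma RPM ceiling below which a gene
#' counts as absent from stroma (default 1, strict `<`).
#'
#' @slot minRpmExpressed numeric(1) RPM floor for the three CEC classes.
#' @slot minFoldVsStroma numeric(1) young/stroma contrast floor.
#' @slot maxAgeFold numeric(1) two-sided young/old fold ceiling.
#' @slot maxStromaRpmAbsent numeric(1) stroma RPM ceiling for "absent".
#'
#' @aliases FilterCriteria-class
#' @seealso [filterCriteria()], [stableCecFilter()], [stromaAbsentFilter()]
#' @exportClass FilterCriteria
setClass("FilterCriteria",
    representation(minRpmExpressed = "numeric", minFoldVsStroma = "numeric",
                   maxAgeFold = "numeric", maxStromaRpmAbsent = "numeric"))

setValidity("FilterCriteria", function(object) {
    vals <- c(object@minRpmExpressed, object@minFoldVsStroma,
              object@maxAgeFold, object@maxStromaRpmAbsent)
    if (length(vals) != 4L || anyNA(vals) || any(vals <= 0))
        "all thresholds must be single positive numbers"
    else TRUE
})

#' qPCR threshold-cycle table
#'
#' Long-format container of qPCR threshold cycles: one row per
#' (assay, sample, replicate) with the measured Ct, `NA` meaning undetected,
#' plus the designation of the housekeeping assays used for normalization.
#'
#' @slot data data.frame with columns `assay_id`, `sample_id`, `replicate`,
#'   `ct` (numeric cycles, `NA` = undetected).
#' @slot housekeeping character, non-empty set of housekeeping assay ids;
#'   each must be measured (detected) in every sample.
#'
#' @aliases CtTable-class
#' @seealso [ctTable()], [readCtTable()], [deltaCt()]
#' @exportClass CtTable
setClass("CtTable",
    representation(data = "data.frame", housekeeping = "character"))

setValidity("CtTable", function(object) {
    d <- object@data
    msg <- character()
    need <- c("assay_id", "sample_id", "replicate", "ct")
    if (!all(need %in% colnames(d)))
        return(paste("data must have columns", paste(need, collapse = ", ")))
    if (!length(object@housekeeping))
        msg <- c(msg, "at least one housekeeping assay is required")
    if (!all(object@housekeeping %in% d$assay_id))
        msg <- c(msg, "every housekeeping assay must appear in the data")
    if (any(!is.na(d$ct) & d$ct <= 0))
        msg <- c(msg, "detected Ct values must be > 0")
    hk <- d[d$assay_id %in% object@housekeeping, , drop = FALSE]
    if (nrow(hk)) {
        have <- unique(hk$sample_id)
        alls <- unique(d$sample_id)
        if (!all(alls %in% have))
            msg <- c(msg, "housekeeping assays must be measured in every sample")
    }
    if (length(msg)) msg else TRUE
})

#' Hierarchical clustering of expression samples
#'
#' Wraps the binary merge tree produced by [clusterSamples()] together with
#' the pairwise sample distances and the parameters that produced it. Merge
#' heights are non-decreasing from leaves to root (guaranteed for average and
#' complete linkage on a metric or correlation distance).
#'
#' @slot hclust the underlying [stats::hclust] tree.
#' @slot dist the sample-by-sample distance matrix.
#' @slot transform,distance,linkage character(1) parameters used.
#'
#' @aliases SampleDendrogram-class
#' @seealso [clusterSamples()], [exportNewick()]
#' @exportClass SampleDendrogram
setClass("SampleDendrogram",
    representation(hclust = "hclust", dist = "matrix",
                   transform = "character", distance = "character",
                   linkage = "character"))
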