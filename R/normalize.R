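#' Round half-up
#'
#' Decimal rounding with ties going away from zero (`25.65 -> 25.7`), the
#' convention used when printing RPM and fold-change tables. Base R's
#' [round()] rounds half to even and is not used for display.
#'
#' @param x non-negative numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    ## nudge compensates for binary representation of values like 2.5*1e-1
    floor(x * p + 0.5 + 1e-9) / p
}

#' Convert raw counts to reads per million
#'
#' Scales each sample's counts by its library size (total uniquely mapping
#' reads, from the sample metadata — not the column sum, since the table may
#' cover a subset of genes): `rpm(g, s) = count(g, s) / library_size(s) * 1e6`.
#'
#' @param x a [MarkerExperiment-class] with unit `"counts"` and a library
#'   size for every sample.
#' @return the same object with unit `"rpm"`.
#' @details Normalizing an already-RPM object is an error (no double
#'   normalization); a missing library size is an error naming the sample.
#'   No pseudocount is added anywhere in the workflow.
#' @export
rpmNormalize <- function(x) {
    stopifnot(is(x, "MarkerExperiment"))
    if (exprUnit(x) == "rpm")
        stop("matrix is already in RPM; refusing to normalize twice")
    ls <- librarySizes(x)
    if (anyNA(ls))
        stop("missing library size for sample(s): ",
             paste(names(ls)[is.na(ls)], collapse = ", "))
    if (any(ls <= 0))
        stop("library sizes must be positive")
    v <- sweep(exprValues(x), 2L, ls, "/") * 1e6
    out <- x
    SummarizedExperiment::assay(out, "values") <- v
    out@unit <- "rpm"
    validObject(out)
    out
}

#' Fold change with an explicit undefined sentinel
#'
#' Computes `a / b` for non-negative expression values. The fold is
#' *undefined* exactly when the denominator is 0 (even if `a` is 0too);
#' undefined folds are returned as `NA` and rendered `"n/a"` by
#' [formatFold()]. No pseudocount is ever substituted.
#'
#' @param a,b non-negative numeric vectors (recycled to common length).
#' @return numeric vector of folds, `NA` where `b == 0`.
#' @examples
#' foldChange(2312, 90)              # 25.68889
#' formatFold(foldChange(2312, 90))  # "25.7"
#' formatFold(foldChange(13, 0))     # "n/a"
#' @export
foldChange <- function(a, b) {
    if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
        stop("fold change requires non-negative inputs")
    out <- ifelse(b == 0, NA_real_, a / b)
    out
}

#' @rdname foldChange
#' @param x numeric vector of folds (possibly `NA` = undefined).
#' @return `formatFold()`: character vector, one-decimal half-up rendering,
#'   `"n/a"` for undefined.
#' @export
formatFold <- function(x) {
    ifelse(is.na(x), "n/a", sprintf("%.1f", roundHalfUp(x, 1)))
}
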