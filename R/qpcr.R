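#' Construct a CtTable
#'
#' @param data data.frame with columns `assay_id`, `sample_id`, `replicate`,
#'   `ct` (numeric threshold cycles; `NA` = undetected).
#' @param housekeeping non-empty character vector of housekeeping assay ids
#'   (e.g. `c("GAPDH", "ATP6V0E1", "H2AFY")`, or just `"GAPDH"` for
#'   single-gene normalization).
#' @return a [CtTable-class].
#' @export
ctTable <- function(data, housekeeping) {
    data <- as.data.frame(data)
    data$assay_id <- as.character(data$assay_id)
    data$sample_id <- as.character(data$sample_id)
    data$ct <- as.numeric(data$ct)
    new("CtTable", data = data, housekeeping = as.character(housekeeping))
}

#' Read qPCR Ct tables
#'
#' `readCtTable()` reads a long-format TSV with columns `assay_id`,
#' `sample_id`, `replicate`, `ct`; `readCtWide()` reads a wide plate export
#' with assays in rows and one column per sample measurement, replicates
#' appearing as repeated sample columns. In both formats an empty cell,
#' `NA`, `ND` or `Undetermined` means undetected.
#'
#' @param path path to the TSV file.
#' @param housekeeping the housekeeping assay ids.
#' @return a [CtTable-class].
#' @export
readCtTable <- function(path, housekeeping) {
    d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
    need <- c("assay_id", "sample_id", "replicate", "ct")
    if (!all(need %in% colnames(d)))
        stop("Ct table must have columns ", paste(need, collapse = ", "))
    d$ct <- .parseCt(d$ct)
    d$replicate <- as.integer(d$replicate)
    ctTable(d, housekeeping)
}

#' @rdname readCtTable
#' @export
readCtWide <- function(path, housekeeping) {
    raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character", fileEncoding = "UTF-8")
    assays <- raw[[1L]]
    samples <- colnames(raw)[-1L]
    long <- do.call(rbind, lapply(seq_along(samples), function(j) {
        data.frame(assay_id = assays, sample_id = samples[j],
                   ct = .parseCt(raw[[j + 1L]]), stringsAsFactors = FALSE)
    }))
    ## repeated sample columns are replicates
    long$replicate <- stats::ave(seq_len(nrow(long)),
                                 long$assay_id, long$sample_id,
                                 FUN = seq_along)
    ctTable(long[, c("assay_id", "sample_id", "replicate", "ct")],
            housekeeping)
}

.parseCt <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "NA", "ND", "Undetermined")] <- NA
    as.numeric(x)
}

#' @describeIn ctTable the housekeeping assay ids.
#' @param x a `CtTable`.
#' @export
housekeepingAssays <- function(x) {
    stopifnot(is(x, "CtTable"))
    x@housekeeping
}

#' @describeIn ctTable the long-format measurement data.frame.
#' @export
ctValues <- function(x) {
    stopifnot(is(x, "CtTable"))
    x@data
}

setMethod("show", "CtTable", function(object) {
    d <- object@data
    cat("CtTable:", length(unique(d$assay_id)), "assays x",
        length(unique(d$sample_id)), "samples,",
        max(d$replicate), "replicate(s)\n")
    cat("  housekeeping:", paste(object@housekeeping, collapse = ", "), "\n")
})

## replicate-mean Ct and replicate SD, assay x sample matrices
.ctSummaries <- function(x) {
    d <- x@data
    assays <- unique(d$assay_id)
    samples <- unique(d$sample_id)
    mean_ <- sd_ <- matrix(NA_real_, length(assays), length(samples),
                           dimnames = list(assays, samples))
    key <- paste(d$assay_id, d$sample_id, sep = "\r")
    det <- !is.na(d$ct)
    mlist <- tapply(d$ct[det], key[det], mean)
    slist <- tapply(d$ct[det], key[det], stats::sd)
    grid <- expand.grid(assay = assays, sample = samples,
                        stringsAsFactors = FALSE)
    k <- paste(grid$assay, grid$sample, sep = "\r")
    mean_[cbind(grid$assay, grid$sample)] <- mlist[k]
    sd_[cbind(grid$assay, grid$sample)] <- slist[k]
    list(mean = mean_, sd = sd_)
}

#' Housekeeping-normalized delta-Ct
#'
#' Averages Ct across replicates, then subtracts, per sample, the arithmetic
#' mean of the housekeeping assays' replicate-mean Ct:
#' `dCt(a, s) = meanCt(a, s) - mean over housekeeping h of meanCt(h, s)`.
#' Averaging Ct arithmetically corresponds to the geometric mean on the
#' expression scale. With a single housekeeping gene this reduces to
#' pairwise subtraction.
#'
#' @param x a [CtTable-class].
#' @return numeric matrix (assays x samples) of dCt values; `NA` marks an
#'   assay undetected in that sample. The replicate SD of each (assay,
#'   sample) mean Ct is attached as attribute `"replicate_sd"`.
#' @details A housekeeping assay undetected in some sample is an error
#'   naming the sample (normalization is impossible there).
#' @export
deltaCt <- function(x) {
    stopifnot(is(x, "CtTable"))
    s <- .ctSummaries(x)
    hk <- s$mean[x@housekeeping, , drop = FALSE]
    bad <- colnames(hk)[apply(hk, 2L, anyNA)]
    if (length(bad))
        stop("housekeeping assay undetected in sample(s): ",
             paste(bad, collapse = ", "))
    ref <- colMeans(hk)
    out <- sweep(s$mean, 2L, ref, "-")
    attr(out, "replicate_sd") <- s$sd
    out
}

#' Relative expression on the reference-sample = 100 scale
#'
#' Converts dCt values to relative expression with the reference sample set
#' to exactly 100 for every assay:
#' `value(a, s) = 100 * 2^-(dCt(a, s) - dCt(a, ref))` (amplification
#' efficiency fixed at 2; TaqMan-style assays without efficiency
#' calibration). An assay undetected in a sample gets relative expression 0
#' and is flagged; undetected in the *reference* sample is an error for that
#' assay.
#'
#' @param dct dCt matrix from [deltaCt()] (assays x samples).
#' @param referenceSample the sample id fixed at 100.
#' @return numeric matrix of relative expressions with attributes
#'   `"undetected"` (logical matrix) and, when `dct` carries replicate SDs,
#'   `"sd"`: the replicate SD propagated to the linear scale by the delta
#'   method, `sd_linear = ln(2) * value * sd_ct`.
#' @export
relativeExpression <- function(dct, referenceSample) {
    if (!referenceSample %in% colnames(dct))
        stop("reference sample ", sQuote(referenceSample), " not in the table")
    refCol <- dct[, referenceSample]
    bad <- rownames(dct)[is.na(refCol)]
    if (length(bad))
        stop("assay(s) undetected in the reference sample: ",
             paste(bad, collapse = ", "))
    rel <- matrix(100 * 2^(-sweep(unclass(dct), 1L, refCol, "-")),
                  nrow(dct), ncol(dct), dimnames = dimnames(dct))
    rel[, referenceSample] <- 100   # exact by construction
    undet <- is.na(rel)
    rel[undet] <- 0
    attr(rel, "undetected") <- undet
    repSd <- attr(dct, "replicate_sd")
    if (!is.null(repSd))
        attr(rel, "sd") <- log(2) * rel * repSd[rownames(dct), colnames(dct)]
    attr(rel, "reference") <- referenceSample
    rel
}

#' Two-group comparison of relative expressions
#'
#' Welch two-sample, two-tailed t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom) between two groups of per-donor
#' relative expression values, with group means, SDs, the a/b fold and
#' significance stars (`"*"` for p < 0.05, `"**"` for p < 0.01).
#'
#' @param a,b numeric vectors of per-donor values (>= 2 each for the test;
#'   means and SDs are reported from 1).
#' @return a list with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `fold`
#'   (`mean_a / mean_b`, `NA` when `mean_b` is 0), `p_value`, `stars`,
#'   `degenerate` (TRUE when both groups have zero variance, where the
#'   t-statistic is undefined: p is 1 for equal means, 0 otherwise).
#' @examples
#' groupStats(c(441, 549, 495), c(1, 2, 3))
#' @export
groupStats <- function(a, b) {
    stopifnot(is.numeric(a), is.numeric(b), length(a) >= 1, length(b) >= 1)
    out <- list(mean_a = mean(a), sd_a = stats::sd(a),
                mean_b = mean(b), sd_b = stats::sd(b))
    out$fold <- if (out$mean_b == 0) NA_real_ else out$mean_a / out$mean_b
    degenerate <- length(a) >= 2 && length(b) >= 2 &&
        stats::sd(a) == 0 && stats::sd(b) == 0
    if (degenerate) {
        out$p_value <- if (isTRUE(all.equal(out$mean_a, out$mean_b))) 1 else 0
    } else if (length(a) >= 2 && length(b) >= 2) {
        out$p_value <- stats::t.test(a, b, alternative = "two.sided",
                                     var.equal = FALSE)$p.value
    } else {
        out$p_value <- NA_real_
    }
    out$degenerate <- degenerate
    out$stars <- if (is.na(out$p_value)) "" else
        if (out$p_value < 0.01) "**" else if (out$p_value < 0.05) "*" else ""
    out
}
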