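#' Construct filter criteria
#'
#' The defaults are the published selection thresholds: RPM > 10 in young
#' CEC, old CEC and CEC culture; young/stroma fold >= 2; less than 2-fold
#' young/old difference (two-sided, on the one-decimal rounded fold,
#' inclusive bounds); stroma RPM < 1 for the stroma-absent screen.
#'
#' @param minRpmExpressed RPM floor for the three CEC classes (strict `>`).
#' @param minFoldVsStroma young/stroma contrast floor (on the rounded fold,
#'   inclusive; an undefined fold from stroma RPM = 0 counts as passing —
#'   zero stroma expression is maximal contrast).
#' @param maxAgeFold two-sided young/old ceiling: the rounded fold must lie
#'   in `[roundHalfUp(1/maxAgeFold, 1), maxAgeFold]`.
#' @param maxStromaRpmAbsent stroma ceiling for "absent in stroma" (strict `<`).
#' @return a [FilterCriteria-class].
#' @export
filterCriteria <- function(minRpmExpressed = 10, minFoldVsStroma = 2,
                           maxAgeFold = 2, maxStromaRpmAbsent = 1) {
    new("FilterCriteria", minRpmExpressed = minRpmExpressed,
        minFoldVsStroma = minFoldVsStroma, maxAgeFold = maxAgeFold,
        maxStromaRpmAbsent = maxStromaRpmAbsent)
}

setMethod("show", "FilterCriteria", function(object) {
    cat("FilterCriteria:",
        sprintf("RPM > %g in CEC classes;", object@minRpmExpressed),
        sprintf("young/stroma fold >= %g;", object@minFoldVsStroma),
        sprintf("young/old rounded fold in [%.1f, %g];",
                roundHalfUp(1 / object@maxAgeFold, 1), object@maxAgeFold),
        sprintf("stroma RPM < %g for absence\n", object@maxStromaRpmAbsent))
})

#' Per-gene marker records
#'
#' Assembles one record per gene: the four class RPMs, the three fold
#' changes (young/old, young/culture, young/stroma; `NA` = undefined), and —
#' when annotation is attached — the flaw flags of [classifyFlaws()].
#'
#' @param x a [MarkerExperiment-class] in RPM with the four core classes
#'   (`cec_young`, `cec_old`, `cec_culture`, `stroma`) labelled.
#' @param withFlaws logical, add the flaw columns (default TRUE).
#' @return a [S4Vectors::DataFrame] with columns `gene_id`,
#'   `rpm_cec_young`, `rpm_cec_old`, `rpm_cec_culture`, `rpm_stroma`,
#'   `fold_young_old`, `fold_young_culture`, `fold_young_stroma`, and flaw
#'   columns.
#' @export
markerTable <- function(x, withFlaws = TRUE) {
    stopifnot(is(x, "MarkerExperiment"))
    if (exprUnit(x) != "rpm")
        stop("marker records are computed on RPM; run rpmNormalize() first")
    m <- .classMeans(x, .coreClasses)
    rec <- DataFrame(gene_id = rownames(x),
                     rpm_cec_young = unname(m[, "cec_young"]),
                     rpm_cec_old = unname(m[, "cec_old"]),
                     rpm_cec_culture = unname(m[, "cec_culture"]),
                     rpm_stroma = unname(m[, "stroma"]),
                     row.names = rownames(x))
    rec$fold_young_old <- foldChange(rec$rpm_cec_young, rec$rpm_cec_old)
    rec$fold_young_culture <- foldChange(rec$rpm_cec_young, rec$rpm_cec_culture)
    rec$fold_young_stroma <- foldChange(rec$rpm_cec_young, rec$rpm_stroma)
    if (withFlaws)
        rec <- classifyFlaws(rec, geneSpecificity(x))
    rec
}

#' Rank the most highly expressed genes of a class
#'
#' @param x a [MarkerExperiment-class] in RPM.
#' @param classLabel the class to rank by (e.g. `"cec_young"`).
#' @param n number of genes to return. If `n` exceeds the gene count, all
#'   genes are returned with a warning.
#' @return character vector of gene ids, descending RPM, ties broken
#'   lexicographically by gene id.
#' @export
rankTopExpressed <- function(x, classLabel = "cec_young", n = 20) {
    stopifnot(is(x, "MarkerExperiment"), n >= 1)
    rpm <- .classMeans(x, classLabel)[, 1L]
    ord <- order(-rpm, rownames(x), method = "radix")
    if (n > nrow(x)) {
        warning("n = ", n, " exceeds the ", nrow(x),
                " genes in the table; returning all")
        n <- nrow(x)
    }
    rownames(x)[ord[seq_len(n)]]
}

## rounded-fold comparison used by both selection criteria: printed tables
## are only self-consistent when folds are compared at the printed precision
.roundedFold <- function(fold) roundHalfUp(fold, 1)

.passesStable <- function(rec, criteria) {
    cecOk <- rec$rpm_cec_young > criteria@minRpmExpressed &
        rec$rpm_cec_old > criteria@minRpmExpressed &
        rec$rpm_cec_culture > criteria@minRpmExpressed
    fs <- rec$fold_young_stroma
    stromaOk <- is.na(fs) | .roundedFold(fs) >= criteria@minFoldVsStroma
    fa <- .roundedFold(rec$fold_young_old)
    lo <- roundHalfUp(1 / criteria@maxAgeFold, 1)
    ageOk <- !is.na(fa) & fa >= lo & fa <= criteria@maxAgeFold
    cecOk & stromaOk & ageOk
}

#' The stable-CEC marker filter
#'
#' Keeps genes expressed in all three CEC classes (RPM strictly above
#' `minRpmExpressed`), at least `minFoldVsStroma`-fold higher in young CEC
#' than in corneal stroma (evaluated on the one-decimal rounded fold; an
#' undefined fold from stroma RPM = 0 passes), and with less than
#' `maxAgeFold` difference between young and old CEC (two-sided, rounded
#' fold, inclusive bounds). Output is ranked by descending young-CEC RPM.
#'
#' @param x a [MarkerExperiment-class] in RPM containing all four core
#'   classes (a missing class is an error naming it).
#' @param criteria a [FilterCriteria-class].
#' @return a marker-record [S4Vectors::DataFrame] (see [markerTable()]) of
#'   the retained genes.
#' @seealso [stromaAbsentFilter()], [selectCategory()]
#' @export
stableCecFilter <- function(x, criteria = filterCriteria()) {
    rec <- markerTable(x)
    rec <- rec[.passesStable(rec, criteria), , drop = FALSE]
    .rankRecords(rec)
}

#' The stroma-absent marker filter
#'
#' Keeps genes with RPM strictly above `minRpmExpressed` in the three CEC
#' classes and strictly below `maxStromaRpmAbsent` in corneal stroma (raw
#' values, no rounding), ranked by descending young-CEC RPM.
#'
#' @inheritParams stableCecFilter
#' @return a marker-record [S4Vectors::DataFrame] of the retained genes.
#' @export
stromaAbsentFilter <- function(x, criteria = filterCriteria()) {
    rec <- markerTable(x)
    keep <- rec$rpm_cec_young > criteria@minRpmExpressed &
        rec$rpm_cec_old > criteria@minRpmExpressed &
        rec$rpm_cec_culture > criteria@minRpmExpressed &
        rec$rpm_stroma < criteria@maxStromaRpmAbsent
    .rankRecords(rec[keep, , drop = FALSE])
}

.rankRecords <- function(rec) {
    rec[order(-rec$rpm_cec_young, rec$gene_id, method = "radix"), ,
        drop = FALSE]
}

#' Classify marker-adequacy flaws
#'
#' Applies the four disqualification rules to per-gene records:
#' \describe{
#'   \item{low_in_young}{not high in young CEC: young RPM < 100.}
#'   \item{absent_in_culture}{not expressed in culture: culture RPM < 10.}
#'   \item{no_stroma_contrast}{does not differentiate CEC from stroma:
#'     young/stroma fold defined and < 5. An undefined fold (stroma RPM = 0)
#'     is maximal contrast and never sets the flag.}
#'   \item{nonspecific}{the external cross-tissue verdict is `ubiquitous`.
#'     `restricted:<site>` and `inconclusive` populate `specificity_note`
#'     without setting the flag.}
#' }
#' The flags are fully determined by the RPMs, folds and annotation, so
#' recomputation is idempotent.
#'
#' @param records a marker-record table (from [markerTable()] or a filter).
#' @param specificity named character vector of per-gene verdicts (e.g. from
#'   [geneSpecificity()]); genes without a verdict default to `inconclusive`.
#' @return `records` with logical columns `flaw_low_in_young`,
#'   `flaw_absent_in_culture`, `flaw_no_stroma_contrast`, `flaw_nonspecific`,
#'   a comma-joined `flaws` summary and `specificity_note`.
#' @export
classifyFlaws <- function(records, specificity = NULL) {
    rec <- records
    spec <- .alignMeta(specificity, rec$gene_id, "inconclusive")
    spec[is.na(spec)] <- "inconclusive"
    rec$flaw_low_in_young <- rec$rpm_cec_young < 100
    rec$flaw_absent_in_culture <- rec$rpm_cec_culture < 10
    fs <- rec$fold_young_stroma
    rec$flaw_no_stroma_contrast <- !is.na(fs) & fs < 5
    rec$flaw_nonspecific <- spec == "ubiquitous"
    flagMat <- cbind(low_in_young = rec$flaw_low_in_young,
                     absent_in_culture = rec$flaw_absent_in_culture,
                     no_stroma_contrast = rec$flaw_no_stroma_contrast,
                     nonspecific = rec$flaw_nonspecific)
    rec$flaws <- apply(flagMat, 1L, function(on)
        paste(colnames(flagMat)[on], collapse = ","))
    note <- rep("", nrow(rec))
    note[spec == "inconclusive"] <- "inconclusive"
    restr <- grepl("^restricted:", spec)
    note[restr] <- sub("^restricted:", "", spec[restr])
    rec$specificity_note <- note
    rec
}

#' @describeIn classifyFlaws the flaw sets as a named list of character
#'   vectors.
#' @export
flawSets <- function(records) {
    stats::setNames(strsplit(records$flaws, ",", fixed = TRUE),
                    records$gene_id)
}

#' Category-restricted marker screen
#'
#' Restricts [stableCecFilter()] to the genes annotated with one functional
#' category (e.g. `transporter`, `cytokine_receptor`,
#' `transcription_factor`), ranked by descending young-CEC RPM.
#'
#' @inheritParams stableCecFilter
#' @param category a single category label; an unknown label is an error
#'   listing the known categories.
#' @return a marker-record [S4Vectors::DataFrame]; zero rows when no
#'   annotated gene passes.
#' @export
selectCategory <- function(x, category, criteria = filterCriteria()) {
    stopifnot(is(x, "MarkerExperiment"), length(category) == 1L)
    cats <- geneCategories(x)
    known <- sort(unique(unlist(cats)))
    if (!category %in% known)
        stop("unknown category ", sQuote(category), "; known categories: ",
             if (length(known)) paste(known, collapse = ", ") else "(none)")
    inCat <- vapply(cats, function(v) category %in% v, logical(1L))
    rec <- stableCecFilter(x, criteria)
    rec[rec$gene_id %in% rownames(x)[inCat], , drop = FALSE]
}

#' Extract an explicit gene set
#'
#' Pulls the records of a listed gene set (e.g. the SMAD family), ranked by
#' descending young-CEC RPM. Genes absent from the matrix are reported in
#' the `missing` metadata entry, not an error.
#'
#' @inheritParams stableCecFilter
#' @param genes non-empty character vector of gene ids (matched
#'   case-insensitively, identifiers preserved as stored).
#' @return a marker-record [S4Vectors::DataFrame];
#'   `S4Vectors::metadata(.)$missing` lists requested ids not found.
#' @export
extractGeneSet <- function(x, genes) {
    stopifnot(is(x, "MarkerExperiment"), length(genes) >= 1L)
    hit <- match(tolower(genes), tolower(rownames(x)))
    rec <- markerTable(x)
    out <- .rankRecords(rec[hit[!is.na(hit)], , drop = FALSE])
    metadata(out)$missing <- genes[is.na(hit)]
    out
}
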