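.exampleFiles <- c(
    prior_markers = "cec_prior_markers.tsv",
    top50 = "cec_top50.tsv",
    stroma_absent = "cec_stroma_absent.tsv",
    transporters = "cec_transporters.tsv",
    cytokine_receptors = "cec_cytokine_receptors_synthetic.tsv",
    transcription_factors = "cec_transcription_factors.tsv",
    smads = "cec_smads.tsv",
    go_terms = "cec_go_terms.tsv",
    prior_annotation = "cec_prior_annotation.tsv")

#' Bundled corneal-endothelium reference tables
#'
#' Small published summary tables of the human corneal endothelium RNA-seq
#' screen this workflow implements, shipped as plain TSV for examples and
#' regression tests:
#' \describe{
#'   \item{prior_markers}{RPMs, printed fold changes and the four-column
#'     flaw grid for 14 previously used CEC markers (young, old, culture,
#'     stroma classes).}
#'   \item{top50}{the 50 top-expressed stable-CEC genes with young/stroma
#'     and young/old folds. Two cells reproduce values reconstructed from
#'     the row's own fold columns where the printed RPM digit was corrupt
#'     (see the package vignette).}
#'   \item{stroma_absent}{the stroma-absent screen (2-decimal RPMs); kept
#'     verbatim including a duplicated UPRT row, so reading it with
#'     [readExpressionTable()] demonstrates the duplicate-gene error.}
#'   \item{transporters, transcription_factors}{category screens (the
#'     transcription-factor table deduplicated of an identical repeated
#'     row).}
#'   \item{cytokine_receptors}{the three published cytokine receptors
#'     passing the screen plus *synthetic* failing receptor rows standing in
#'     for the full receptor list, which is not redistributable here.}
#'   \item{smads}{SMAD-family expression.}
#'   \item{go_terms}{over-represented gene-ontology terms of the top-200
#'     young-CEC genes with their member lists and percentages.}
#'   \item{prior_annotation}{specificity verdicts encoded from the
#'     prior-marker flaw grid (`ubiquitous` / `specific` /
#'     `restricted:retina`).}
#' }
#'
#' @param name one of the table names above.
#' @return `cecExampleTable()`: a `data.frame`; `cecExampleExperiment()`: a
#'   [MarkerExperiment-class] in RPM with the four core classes labelled
#'   (duplicate rows resolved to their first occurrence, as noted above).
#' @export
cecExampleTable <- function(name = names(.exampleFiles)) {
    name <- match.arg(name)
    path <- system.file("extdata", .exampleFiles[[name]],
                        package = "cecmarker", mustWork = TRUE)
    utils::read.delim(path, header = TRUE, check.names = FALSE,
                      colClasses = "character", fileEncoding = "UTF-8")
}

#' @rdname cecExampleTable
#' @export
cecExampleExperiment <- function(name = c("prior_markers", "top50",
                                          "stroma_absent", "transporters",
                                          "cytokine_receptors",
                                          "transcription_factors", "smads")) {
    name <- match.arg(name)
    df <- cecExampleTable(name)
    classCols <- c(cec_young = "cec_young", cec_old = "cec_old",
                   cec_culture = "cec_culture", stroma = "stroma")
    keep <- !duplicated(tolower(df$gene_id))
    df <- df[keep, , drop = FALSE]
    m <- vapply(classCols, function(cc)
        as.numeric(gsub(",", "", df[[cc]])), numeric(nrow(df)))
    rownames(m) <- df$gene_id
    me <- MarkerExperiment(m, unit = "rpm", classLabels = unname(classCols))
    if (name == "prior_markers") {
        ann <- cecExampleTable("prior_annotation")
        me <- attachGeneAnnotation(me, ann)
    }
    me
}
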