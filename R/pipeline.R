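#' Assemble or read a pipeline configuration
#'
#' `pipelineConfig()` builds the configuration driving [runPipeline()];
#' `readPipelineConfig()` reads the same fields from a YAML or JSON file
#' (keys mirror the argument names; `criteria` sub-keys mirror
#' [filterCriteria()] arguments).
#'
#' @param expression path to the counts/RPM expression TSV.
#' @param metadata path to the sample metadata TSV (required when
#'   `unit = "counts"`).
#' @param annotation optional path to the gene annotation TSV.
#' @param ct optional path to a long-format Ct TSV; enables the qPCR stage.
#' @param outputDir directory for the report bundle.
#' @param unit unit of the expression table.
#' @param criteria a [FilterCriteria-class] or a named list of its arguments.
#' @param transform,distance,linkage clustering options, see
#'   [clusterSamples()].
#' @param topN size of the top-expressed ranking.
#' @param categories category labels to screen (skipped when absent from the
#'   annotation-free run).
#' @param housekeeping housekeeping assay ids for the qPCR stage.
#' @param referenceSample reference sample for [relativeExpression()].
#' @param seed integer seed recorded in the run log.
#' @return a named list (class `pipeline_config`).
#' @export
pipelineConfig <- function(expression, metadata = NULL, annotation = NULL,
                           ct = NULL, outputDir = "cecmarker_out",
                           unit = c("counts", "rpm"), criteria = filterCriteria(),
                           transform = "log2p1", distance = "euclidean",
                           linkage = "average", topN = 20,
                           categories = character(),
                           housekeeping = c("GAPDH", "ATP6V0E1", "H2AFY"),
                           referenceSample = NULL, seed = 1) {
    unit <- match.arg(unit)
    if (is.list(criteria)) criteria <- do.call(filterCriteria, criteria)
    stopifnot(is(criteria, "FilterCriteria"))
    structure(list(expression = expression, metadata = metadata,
                   annotation = annotation, ct = ct, outputDir = outputDir,
                   unit = unit, criteria = criteria, transform = transform,
                   distance = distance, linkage = linkage, topN = topN,
                   categories = categories, housekeeping = housekeeping,
                   referenceSample = referenceSample, seed = seed),
              class = "pipeline_config")
}

#' @rdname pipelineConfig
#' @param path a `.yaml`/`.yml` or `.json` configuration file.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
        else jsonlite::fromJSON(path, simplifyVector = TRUE)
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(cfg), known)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    do.call(pipelineConfig, cfg)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

## small deterministic config fingerprint for the run log (polynomial hash)
.configHash <- function(cfg) {
    bytes <- utf8ToInt(paste(utils::capture.output(utils::str(cfg)),
                             collapse = "\n"))
    h <- 0
    for (b in bytes) h <- (h * 131 + b) %% 2147483647
    sprintf("%08x", h)
}

#' Run the end-to-end marker-discovery pipeline
#'
#' Executes normalize, cluster, top-expressed ranking, stable-CEC filter,
#' stroma-absent filter, flaw classification, category screens, enrichment
#' and (when Ct data are configured) qPCR relative quantification, writing
#' every table (TSV + JSON for marker reports), a newick dendrogram and a
#' run log with package version, seed and a configuration fingerprint. Any
#' stage error aborts with the failing stage named. Outputs are
#' deterministic: two runs from the same configuration and seed produce
#' byte-identical tables.
#'
#' @param config a [pipelineConfig()] (or a path accepted by
#'   [readPipelineConfig()]).
#' @return invisibly, a named list of the artifact paths.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readPipelineConfig(config)
    stopifnot(inherits(config, "pipeline_config"))
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    art <- list()
    p <- function(f) file.path(config$outputDir, f)

    me <- .stage("read_expression", {
        x <- readExpressionTable(config$expression, unit = config$unit)
        if (!is.null(config$metadata))
            x <- attachSampleMetadata(x, readSampleMetadata(config$metadata))
        else if (config$unit == "rpm")
            colData(x)$class_label <- colnames(x)
        if (!is.null(config$annotation))
            x <- attachGeneAnnotation(x, readGeneAnnotation(config$annotation))
        x
    })
    rpm <- .stage("normalize",
                  if (exprUnit(me) == "counts") rpmNormalize(me) else me)
    .stage("write_rpm", {
        utils::write.table(
            data.frame(gene_id = rownames(rpm), exprValues(rpm),
                       check.names = FALSE),
            p("rpm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        art$rpm <- p("rpm.tsv")
    })
    .stage("cluster", {
        dendro <- clusterSamples(rpm, transform = config$transform,
                                 distance = config$distance,
                                 linkage = config$linkage)
        exportNewick(dendro, p("dendrogram.nwk"))
        exportDistances(dendro, p("distances.tsv"))
        art$dendrogram <- p("dendrogram.nwk")
        art$distances <- p("distances.tsv")
    })
    .stage("top_expressed", {
        top <- rankTopExpressed(rpm, "cec_young", min(config$topN, nrow(rpm)))
        writeLines(top, p("top_expressed.txt"))
        art$top_expressed <- p("top_expressed.txt")
    })
    stable <- .stage("stable_filter", stableCecFilter(rpm, config$criteria))
    .stage("write_stable", {
        writeMarkerReport(stable, p("stable_markers.tsv"))
        art$stable <- p("stable_markers.tsv")
    })
    .stage("stroma_absent_filter", {
        sa <- stromaAbsentFilter(rpm, config$criteria)
        writeMarkerReport(sa, p("stroma_absent_markers.tsv"), rpmDigits = 2)
        art$stroma_absent <- p("stroma_absent_markers.tsv")
    })
    .stage("classify_flaws", {
        writeMarkerReport(markerTable(rpm), p("flaw_report.tsv"))
        art$flaws <- p("flaw_report.tsv")
    })
    .stage("category_screens", {
        known <- unique(unlist(geneCategories(rpm)))
        for (cc in intersect(config$categories, known)) {
            sel <- selectCategory(rpm, cc, config$criteria)
            writeMarkerReport(sel, p(paste0("category_", cc, ".tsv")))
            art[[paste0("category_", cc)]] <- p(paste0("category_", cc, ".tsv"))
        }
    })
    .stage("enrichment", {
        if (!is.null(config$annotation)) {
            ann <- readGeneAnnotation(config$annotation)
            top <- rankTopExpressed(rpm, "cec_young",
                                    min(config$topN * 10, nrow(rpm)))
            enr <- as.data.frame(categoryPercentages(top, ann))
            utils::write.table(enr, p("enrichment.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            art$enrichment <- p("enrichment.tsv")
        }
    })
    .stage("qpcr", {
        if (!is.null(config$ct)) {
            ct <- readCtTable(config$ct, config$housekeeping)
            dct <- deltaCt(ct)
            ref <- config$referenceSample
            if (is.null(ref)) ref <- colnames(dct)[1L]
            rel <- relativeExpression(dct, ref)
            utils::write.table(
                data.frame(assay_id = rownames(rel), rel, check.names = FALSE),
                p("qpcr_relative_expression.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
            art$qpcr <- p("qpcr_relative_expression.tsv")
        }
    })
    .stage("run_log", {
        log <- c(sprintf("cecmarker %s",
                         as.character(utils::packageVersion("cecmarker"))),
                 sprintf("R %s", getRversion()),
                 sprintf("seed: %d", config$seed),
                 sprintf("config hash: %s", .configHash(config)),
                 "resolved configuration:",
                 utils::capture.output(utils::str(unclass(config))))
        writeLines(log, p("run_log.txt"))
        art$log <- p("run_log.txt")
    })
    invisible(art)
}
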