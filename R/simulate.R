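## Archetype templates: per-class mean RPM patterns the generator plants.
## Patterns mirror the marker classes seen in corneal endothelium profiling:
## pan-CEC (expressed in vivo and in culture, absent from stroma, CYYR1-like),
## in-vivo-only (lost in culture, CA3-like), culture-induced (far higher in
## culture, MGP-like), stroma-restricted, ubiquitous housekeeping, and an
## ocular-but-non-CEC class carrying a restricted:<site> verdict (COL8A2-like).
.archetypeTemplates <- list(
    pan_cec        = c(cec_young = 600, cec_old = 600, cec_culture = 250, stroma = 0),
    in_vivo_only   = c(cec_young = 800, cec_old = 600, cec_culture = 2,   stroma = 30),
    culture_induced= c(cec_young = 40,  cec_old = 40,  cec_culture = 2000, stroma = 80),
    stroma_marker  = c(cec_young = 3,   cec_old = 3,   cec_culture = 3,   stroma = 1000),
    ubiquitous     = c(cec_young = 1000, cec_old = 1000, cec_culture = 1000, stroma = 1000),
    ocular_non_cec = c(cec_young = 300, cec_old = 300, cec_culture = 150, stroma = 20)
)

.defaultQuotas <- c(pan_cec = 20, in_vivo_only = 15, culture_induced = 15,
                    stroma_marker = 15, ubiquitous = 10, ocular_non_cec = 10)

## evaluate expr with a temporary RNG seed, restoring global state after
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Configuration of the count simulator
#'
#' Defaults emulate the study design the workflow targets: the four core
#' sample classes with one pooled library each, sequencing depths drawn
#' uniformly from 1.8-4.6 million uniquely mapped reads, negative-binomial
#' counts with a single shared dispersion of 0.1 (bulk RNA-seq scale
#' overdispersion), and planted marker archetypes alongside a low-expression
#' background. Per-donor biological variance is unidentifiable in a pooled
#' one-library-per-class design and is fixed at 0 (see the vignette).
#'
#' @param nGenes total genes to simulate.
#' @param classes sample class labels.
#' @param samplesPerClass libraries per class (default 1, the pooled design).
#' @param librarySizeRange depth range (uniform draw), in reads.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives the noise-free limit where counts
#'   equal the rounded expected means.
#' @param quotas named integer vector of archetype gene counts (names from
#'   `pan_cec`, `in_vivo_only`, `culture_induced`, `stroma_marker`,
#'   `ubiquitous`, `ocular_non_cec`); remaining genes are low-expression
#'   background. Quotas summing past `nGenes` are an error.
#' @param seed integer seed; all randomness of [generateCounts()] flows from
#'   it.
#' @return a named list (class `simulation_config`).
#' @export
simulationConfig <- function(nGenes = 200, classes = .coreClasses,
                             samplesPerClass = 1,
                             librarySizeRange = c(1.8e6, 4.6e6),
                             dispersion = 0.1, quotas = .defaultQuotas,
                             seed = 1) {
    stopifnot(nGenes >= 1, samplesPerClass >= 1,
              length(librarySizeRange) == 2L,
              librarySizeRange[1] > 0,
              librarySizeRange[2] >= librarySizeRange[1],
              dispersion >= 0)
    bad <- setdiff(names(quotas), names(.archetypeTemplates))
    if (length(bad))
        stop("unknown archetype(s): ", paste(bad, collapse = ", "))
    if (sum(quotas) > nGenes)
        stop("archetype quotas (", sum(quotas), ") exceed nGenes (", nGenes, ")")
    structure(list(nGenes = nGenes, classes = classes,
                   samplesPerClass = samplesPerClass,
                   librarySizeRange = librarySizeRange,
                   dispersion = dispersion, quotas = quotas, seed = seed),
              class = "simulation_config")
}

#' Simulate a count matrix with planted marker archetypes
#'
#' Draws gene counts from a negative-binomial law with mean
#' `template RPM * depth / 1e6` and the configured dispersion, for a design
#' of one (by default) library per class at depths drawn from the configured
#' range. Planted archetypes are recoverable by the marker filters by
#' construction at default noise; background genes get a low constant
#' expression across classes (log-normal base level, median 3 RPM).
#'
#' @param config a [simulationConfig()].
#' @return a list with
#' \describe{
#'   \item{experiment}{a counts [MarkerExperiment-class] with class labels,
#'     library sizes and generated annotation attached.}
#'   \item{truth}{a [S4Vectors::DataFrame]: per gene the archetype, the
#'     per-class mean RPM used for generation, and the filter outcomes
#'     expected from the noiseless template (`expected_stable`,
#'     `expected_stroma_absent`).}
#' }
#' Fully reproducible from `config$seed`.
#' @export
generateCounts <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "simulation_config"))
    .withSeed(config$seed, {
        quotas <- config$quotas
        arch <- rep(names(quotas), quotas)
        nBg <- config$nGenes - length(arch)
        arch <- c(arch, rep("background", nBg))
        geneIds <- sprintf("G%04d", seq_len(config$nGenes))
        classes <- config$classes
        tmpl <- matrix(0, config$nGenes, length(classes),
                       dimnames = list(geneIds, classes))
        for (i in seq_along(arch)) {
            tmpl[i, ] <- if (arch[i] == "background") {
                rep(stats::rlnorm(1, meanlog = log(3), sdlog = 1),
                    length(classes))
            } else {
                .archetypeTemplates[[arch[i]]][classes]
            }
        }
        samples <- unlist(lapply(classes, function(k)
            paste0(k, if (config$samplesPerClass > 1)
                paste0("_", seq_len(config$samplesPerClass)) else "")))
        sampleClass <- rep(classes, each = config$samplesPerClass)
        depth <- round(stats::runif(length(samples),
                                    config$librarySizeRange[1],
                                    config$librarySizeRange[2]))
        counts <- matrix(0, config$nGenes, length(samples),
                         dimnames = list(geneIds, samples))
        for (j in seq_along(samples)) {
            mu <- tmpl[, sampleClass[j]] * depth[j] / 1e6
            counts[, j] <- if (config$dispersion == 0) round(mu)
                else stats::rnbinom(config$nGenes, mu = mu,
                                    size = 1 / config$dispersion)
        }
        spec <- c(pan_cec = "specific", in_vivo_only = "specific",
                  culture_induced = "specific", stroma_marker = "specific",
                  ubiquitous = "ubiquitous",
                  ocular_non_cec = "restricted:retina",
                  background = "inconclusive")[arch]
        cats <- vapply(seq_along(arch), function(i) {
            pool <- c("transporter", "transcription_factor",
                      "cytokine_receptor")
            got <- pool[stats::runif(3) < c(0.25, 0.15, 0.05)]
            paste(got, collapse = ";")
        }, character(1L))
        me <- MarkerExperiment(counts, unit = "counts",
                               classLabels = sampleClass,
                               librarySizes = depth,
                               categories = cats, specificity = unname(spec))
        truth <- DataFrame(gene_id = geneIds, archetype = arch,
                           row.names = geneIds)
        for (k in classes) truth[[paste0("mean_rpm_", k)]] <- tmpl[, k]
        if (all(.coreClasses %in% classes)) {
            noiseless <- MarkerExperiment(tmpl, unit = "rpm",
                                          classLabels = classes,
                                          specificity = unname(spec))
            truth$expected_stable <-
                geneIds %in% stableCecFilter(noiseless)$gene_id
            truth$expected_stroma_absent <-
                geneIds %in% stromaAbsentFilter(noiseless)$gene_id
        }
        list(experiment = me, truth = truth)
    })
}

#' Simulate a qPCR Ct plate from known relative abundances
#'
#' Generates replicate Ct values from the exponential amplification model:
#' `Ct = baseCycle - log2(abundance) + N(0, noiseSd)` per replicate, so a
#' doubling of abundance lowers Ct by one cycle. Housekeeping assays are
#' generated at a constant abundance in every sample, making them exact
#' normalizers up to the Gaussian cycle noise.
#'
#' @param relAbundances positive numeric matrix, assays x samples, of true
#'   relative abundances (non-positive values are an error).
#' @param noiseSd Gaussian Ct noise per replicate, in cycles.
#' @param nReplicates replicates per (assay, sample).
#' @param seed integer seed.
#' @param baseCycle Ct of a unit-abundance target.
#' @param housekeeping housekeeping assay ids to append.
#' @param hkAbundance constant abundance of the housekeeping assays.
#' @return a [CtTable-class].
#' @export
generateCt <- function(relAbundances, noiseSd = 0.2, nReplicates = 3,
                       seed = 1, baseCycle = 30,
                       housekeeping = c("GAPDH", "ATP6V0E1", "H2AFY"),
                       hkAbundance = 1) {
    relAbundances <- as.matrix(relAbundances)
    if (any(relAbundances <= 0) || anyNA(relAbundances))
        stop("relative abundances must be strictly positive")
    if (is.null(rownames(relAbundances)))
        rownames(relAbundances) <- sprintf("assay%02d",
                                           seq_len(nrow(relAbundances)))
    if (is.null(colnames(relAbundances)))
        colnames(relAbundances) <- sprintf("sample%02d",
                                           seq_len(ncol(relAbundances)))
    hk <- matrix(hkAbundance, length(housekeeping), ncol(relAbundances),
                 dimnames = list(housekeeping, colnames(relAbundances)))
    ab <- rbind(relAbundances, hk)
    .withSeed(seed, {
        rows <- expand.grid(replicate = seq_len(nReplicates),
                            sample_id = colnames(ab),
                            assay_id = rownames(ab),
                            stringsAsFactors = FALSE)
        mu <- baseCycle - log2(ab[cbind(rows$assay_id, rows$sample_id)])
        rows$ct <- mu + stats::rnorm(nrow(rows), 0, noiseSd)
        ctTable(rows[, c("assay_id", "sample_id", "replicate", "ct")],
                housekeeping)
    })
}
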