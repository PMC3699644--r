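# Independent oracles and tiny fixture builders used across the suite.

## Build a small RPM MarkerExperiment for the four core classes from a
## named list gene -> c(young, old, culture, stroma).
coreExperiment <- function(rows, specificity = NULL) {
    m <- do.call(rbind, rows)
    dimnames(m) <- list(names(rows),
                        c("cec_young", "cec_old", "cec_culture", "stroma"))
    MarkerExperiment(m, unit = "rpm",
                     classLabels = colnames(m), specificity = specificity)
}

## Brute-force UPGMA: repeatedly merge the pair of clusters with the
## smallest mean pairwise distance; heights are those means. Independent of
## stats::hclust.
upgmaOracle <- function(d) {
    clusters <- as.list(rownames(d))
    heights <- numeric(0)
    merges <- list()
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestv <- Inf
        for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
            v <- mean(d[clusters[[i]], clusters[[j]]])
            if (v < bestv - 1e-12) { bestv <- v; best <- c(j, i) }
        }
        merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
        merges[[length(merges) + 1L]] <- merged
        heights <- c(heights, bestv)
        clusters[[best[1]]] <- merged
        clusters[[best[2]]] <- NULL
    }
    list(merges = merges, heights = heights)
}

## All rooted binary topologies over 4 labelled leaves, each as a sequence
## of merges (left children, right children). Scores every topology by
## least-squares cophenetic fit, estimating each merge height as the mean
## distance between the two merged subclusters (the average-linkage
## estimate), and returns topologies sorted by fit.
topologyFits4 <- function(d) {
    leaves <- rownames(d)
    stopifnot(length(leaves) == 4L)
    tops <- list()
    addTop <- function(merges) tops[[length(tops) + 1L]] <<- merges
    for (p in utils::combn(4, 2, simplify = FALSE)) {
        ab <- leaves[p]; cd <- leaves[-p]
        ## balanced ((a,b),(c,d)) — generated once per unordered split
        if (p[1] == 1L)
            addTop(list(list(ab[1], ab[2]), list(cd[1], cd[2]),
                        list(ab, cd)))
        ## caterpillars (((a,b),c),d) and (((a,b),d),c)
        for (k in 1:2)
            addTop(list(list(ab[1], ab[2]), list(ab, cd[k]),
                        list(c(ab, cd[k]), cd[3 - k])))
    }
    score <- vapply(tops, function(merges) {
        coph <- matrix(NA_real_, 4, 4, dimnames = list(leaves, leaves))
        for (m in merges) {
            h <- mean(d[m[[1]], m[[2]]])
            for (a in m[[1]]) for (b in m[[2]])
                coph[a, b] <- coph[b, a] <- h
        }
        sum((coph[upper.tri(coph)] - d[upper.tri(d)])^2)
    }, numeric(1))
    ord <- order(score)
    ## report each topology as its nested cluster sets, smallest first
    tops <- lapply(tops[ord], function(merges)
        lapply(merges, function(m) sort(c(m[[1]], m[[2]]))))
    list(tops = tops, score = score[ord])
}

## Independent ddCt recomputation, cell by cell.
ddctOracle <- function(ct, reference) {
    d <- ctValues(ct)
    hk <- housekeepingAssays(ct)
    assays <- unique(d$assay_id); samples <- unique(d$sample_id)
    meanCt <- function(a, s) mean(d$ct[d$assay_id == a & d$sample_id == s])
    dct <- function(a, s) meanCt(a, s) -
        mean(vapply(hk, meanCt, numeric(1), s = s))
    out <- matrix(NA_real_, length(assays), length(samples),
                  dimnames = list(assays, samples))
    for (a in assays) for (s in samples)
        out[a, s] <- 100 * 2^(-(dct(a, s) - dct(a, reference)))
    out
}

## Exhaustive hypergeometric upper tail by enumerating all draws.
hyperEnumOracle <- function(k, nList, K, N) {
    marked <- seq_len(K)
    draws <- utils::combn(N, nList, simplify = FALSE)
    mean(vapply(draws, function(dr) sum(dr %in% marked) >= k, logical(1)))
}
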