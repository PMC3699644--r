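#' Category percentages for a gene list
#'
#' For every functional category represented in a gene list, computes the
#' percentage of list members carrying the category. The denominator `N` is
#' the number of input genes carrying at least one annotation — not the list
#' length — mirroring how annotation tools report "recognized" genes; genes
#' may belong to several categories, so member counts across categories can
#' exceed `N` (no normalization across categories is applied).
#'
#' A one-sided hypergeometric over-representation p-value against the
#' universe is attached per category, with Benjamini-Hochberg adjustment
#' across categories reported (the ranking itself is by percentage, ties
#' broken lexicographically by category label).
#'
#' @param genes character vector, the input gene list.
#' @param annotation a gene-annotation `data.frame` (columns `gene_id`,
#'   `categories` semicolon-delimited, `specificity`; see
#'   [readGeneAnnotation()]).
#' @param universe character vector of background gene ids; defaults to all
#'   annotated genes of `annotation`. Must contain the annotated input genes.
#' @return a [S4Vectors::DataFrame] with columns `category`, `k` (member
#'   count), `N` (annotated-input denominator), `percent`
#'   (`100 * k / N`, half-up rounded to 1 decimal), `p_value`, `p_adjust`
#'   and `genes` (comma-joined members), sorted by descending percent.
#'   Empty input gives an empty result.
#' @export
categoryPercentages <- function(genes, annotation, universe = NULL) {
    annotation <- as.data.frame(annotation)
    catList <- strsplit(ifelse(is.na(annotation$categories), "",
                               annotation$categories), ";", fixed = TRUE)
    catList <- lapply(catList, function(v) trimws(v[nzchar(trimws(v))]))
    names(catList) <- annotation$gene_id
    annotated <- names(catList)[lengths(catList) > 0L]
    if (is.null(universe)) universe <- annotated
    genes <- unique(genes)
    inAnn <- genes[tolower(genes) %in% tolower(annotated)]
    if (!all(tolower(inAnn) %in% tolower(universe)))
        stop("universe must contain every annotated input gene")
    emptyOut <- DataFrame(category = character(0), k = integer(0),
                          N = integer(0), percent = numeric(0),
                          p_value = numeric(0), p_adjust = numeric(0),
                          genes = character(0))
    if (!length(inAnn)) return(emptyOut)
    N <- length(inAnn)
    memb <- catList[match(tolower(inAnn), tolower(names(catList)))]
    cats <- sort(unique(unlist(memb)))
    uniAnn <- catList[tolower(names(catList)) %in% tolower(universe)]
    Nuniverse <- length(universe)
    rows <- lapply(cats, function(cc) {
        members <- inAnn[vapply(memb, function(v) cc %in% v, logical(1L))]
        k <- length(members)
        K <- sum(vapply(uniAnn, function(v) cc %in% v, logical(1L)))
        p <- overrepresentationTest(k, N, max(K, k), Nuniverse)
        DataFrame(category = cc, k = k, N = N,
                  percent = roundHalfUp(100 * k / N, 1), p_value = p,
                  genes = paste(sort(members), collapse = ","))
    })
    out <- do.call(rbind, rows)
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
    out <- out[order(-out$percent, out$category, method = "radix"), ,
               drop = FALSE]
    out[, c("category", "k", "N", "percent", "p_value", "p_adjust", "genes")]
}

#' One-sided hypergeometric over-representation test
#'
#' Probability of observing `k` or more category members in a draw of
#' `nList` genes from a universe of `NUniverse` genes of which `KUniverse`
#' carry the category: `P(X >= k)` for
#' `X ~ Hypergeometric(NUniverse, KUniverse, nList)`.
#'
#' @param k observed member count in the list.
#' @param nList list size (number of annotated input genes).
#' @param KUniverse category size in the universe.
#' @param NUniverse universe size.
#' @return the upper-tail probability; `1` when `k == 0`.
#' @examples
#' overrepresentationTest(2, 2, 2, 4)  # 1/6
#' @export
overrepresentationTest <- function(k, nList, KUniverse, NUniverse) {
    vals <- c(k, nList, KUniverse, NUniverse)
    if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals)))
        stop("counts must be non-negative integers")
    if (KUniverse > NUniverse || nList > NUniverse ||
        k > min(nList, KUniverse))
        stop("inconsistent counts: need k <= min(nList, KUniverse) and ",
             "KUniverse, nList <= NUniverse")
    stats::phyper(k - 1, KUniverse, NUniverse - KUniverse, nList,
                  lower.tail = FALSE)
}
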