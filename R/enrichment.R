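#' @include AllClasses.R
NULL

.checkHyperArgs <- function(k, K, n, N) {
    if (N < 1) stop("'N' must be >= 1")
    if (K < 0 || K > N) stop("'K' must satisfy 0 <= K <= N")
    if (n < 0 || n > N) stop("'n' must satisfy 0 <= n <= N")
    if (k < 0) stop("'k' must be >= 0")
    if (k > min(n, K))
        stop("'k' must satisfy k <= min(n, K)")
}

# log hypergeometric pmf at i draws of the K marked among n from N
.lhyper <- function(i, K, n, N)
    lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)

#' Hypergeometric point mass
#'
#' P(X = k) for X ~ hypergeometric(N, K, n): the probability that a
#' uniformly random size-n subset of an N-gene universe contains exactly k
#' of the K genes carrying a given annotation. Computed via log binomial
#' coefficients, stable for N up to at least 1e5.
#'
#' @param k Number of annotated genes drawn.
#' @param K Annotated genes in the universe.
#' @param n Draw (query) size.
#' @param N Universe size.
#' @return Probability in [0, 1].
#' @export
hypergeomPmf <- function(k, K, n, N) {
    .checkHyperArgs(k, K, n, N)
    if (k < max(0, n + K - N)) return(0)
    exp(.lhyper(k, K, n, N))
}

#' Hypergeometric upper tail (over-representation p-value)
#'
#' P(X >= k) for X ~ hypergeometric(N, K, n): the probability that a
#' random query of size n drawn from an N-gene universe contains at least
#' k of the K genes annotated to a term. This is the standard
#' over-representation (one-sided Fisher) test statistic. Summation runs
#' over the log-scale pmf from k to min(n, K), so it is numerically safe
#' for universes up to at least 1e5 genes.
#'
#' @inheritParams hypergeomPmf
#' @return p-value in (0, 1].
#' @examples
#' hypergeomUpperTail(4, K = 5, n = 4, N = 10)  # 5/210
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
    .checkHyperArgs(k, K, n, N)
    if (k <= max(0, n + K - N)) return(1)
    i <- k:min(n, K)
    # sum on the log scale anchored at the largest term
    lp <- .lhyper(i, K, n, N)
    m <- max(lp)
    min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort raw p-values ascending, multiply the i-th by
#' m/i, enforce monotonicity from the largest down, cap at 1. Input order
#' is preserved and the result is invariant under permutation of the
#' input. Adjusted values never fall below the raw p-value.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA not allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric())
    if (anyNA(p) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Bonferroni adjustment
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return `pmin(1, p * length(p))`.
#' @export
bonferroniAdjust <- function(p) {
    if (!length(p)) return(numeric())
    if (anyNA(p) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    pmin(1, p * length(p))
}

#' Read a term-to-gene annotation table
#'
#' @param path TSV with header columns `term_id`, `term_name`, `gene_id`.
#' @return `data.frame` with those three character columns.
#' @export
readAnnotations <- function(path) {
    if (!file.exists(path))
        stop("annotation table not found: ", path)
    ann <- utils::read.table(path, sep = "\t", header = TRUE,
        colClasses = "character", quote = "")
    need <- c("term_id", "term_name", "gene_id")
    if (!all(need %in% colnames(ann)))
        stop("annotation table needs columns: ", paste(need, collapse = ", "))
    ann[, need]
}

#' Over-representation analysis of a gene set
#'
#' Tests every annotation term for over-representation in a query gene set
#' relative to a gene universe, with the hypergeometric upper tail
#' ([hypergeomUpperTail()]) and multiple-testing correction across all
#' tested terms. Terms with no annotated gene in the universe are skipped
#' (they carry no information and would only inflate the testing burden).
#' Query genes outside the universe are dropped with a warning.
#'
#' @param querySet Character vector of query gene ids.
#' @param annotations Annotation `data.frame` (`term_id`, `term_name`,
#'   `gene_id`), e.g. from [readAnnotations()].
#' @param universe Character vector of universe gene ids (for a
#'   transcriptome study, typically all orthologs of the presence matrix).
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return `data.frame`, one row per tested term, sorted by adjusted
#'   p-value then term id, with columns `term_id`, `term_name`, `k`
#'   (query genes annotated), `K` (universe genes annotated), `n` (query
#'   size in universe), `N` (universe size), `enrichment_ratio`
#'   (`(k/n)/(K/N)`), `p_value`, `adjusted_p`, `significant`.
#' @export
enrichTerms <- function(querySet, annotations, universe, alpha = 0.05,
        method = c("BH", "bonferroni")) {
    method <- match.arg(method)
    universe <- unique(universe)
    if (!length(universe)) stop("'universe' must be non-empty")
    querySet <- unique(querySet)
    outside <- setdiff(querySet, universe)
    if (length(outside))
        warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(querySet, universe)
    N <- length(universe)
    n <- length(query)
    ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
    if (!nrow(ann))
        return(.emptyEnrichment())
    genesByTerm <- split(ann$gene_id, ann$term_id)
    genesByTerm <- lapply(genesByTerm, unique)
    termName <- ann$term_name[match(names(genesByTerm), ann$term_id)]
    K <- lengths(genesByTerm)
    k <- vapply(genesByTerm, function(g) length(intersect(g, query)), 0L)
    p <- vapply(seq_along(K), function(i)
        hypergeomUpperTail(k[i], K[i], n, N), 0)
    adj <- if (method == "BH") bhAdjust(p) else bonferroniAdjust(p)
    res <- data.frame(
        term_id = names(genesByTerm),
        term_name = termName,
        k = as.integer(k), K = as.integer(K),
        n = as.integer(n), N = as.integer(N),
        enrichment_ratio = ifelse(n > 0, (k / n) / (K / N), NA_real_),
        p_value = p,
        adjusted_p = adj,
        significant = adj <= alpha,
        stringsAsFactors = FALSE)
    res <- res[order(res$adjusted_p, res$term_id), , drop = FALSE]
    rownames(res) <- NULL
    res
}

.emptyEnrichment <- function() data.frame(term_id = character(),
    term_name = character(), k = integer(), K = integer(), n = integer(),
    N = integer(), enrichment_ratio = numeric(), p_value = numeric(),
    adjusted_p = numeric(), significant = logical(),
    stringsAsFactors = FALSE)

#' Terms significantly enriched in both of two analyses
#'
#' @param resultsA,resultsB Enrichment tables from [enrichTerms()],
#'   computed against comparable universes.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Sorted character vector of shared significant term ids (empty
#'   when the significant sets do not overlap).
#' @export
sharedTerms <- function(resultsA, resultsB, alpha = 0.05) {
    sa <- resultsA$term_id[resultsA$adjusted_p <= alpha]
    sb <- resultsB$term_id[resultsB$adjusted_p <= alpha]
    sort(intersect(sa, sb))
}
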