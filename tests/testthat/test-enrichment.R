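# exhaustive enumeration oracle: upper tail by counting all size-n subsets
enumUpperTail <- function(k, K, n, N) {
    marked <- seq_len(K)
    subsets <- utils::combn(N, n)
    mean(colSums(matrix(subsets %in% marked, nrow = n)) >= k)
}

test_that("hypergeometric upper tail matches exhaustive enumeration", {
    # all C(10,4) = 210 draws; 5 of them contain all 4 available marked genes
    expect_equal(enumUpperTail(4, 5, 4, 10), 5 / 210)
    expect_equal(hypergeomUpperTail(4, K = 5, n = 4, N = 10), 5 / 210)
    for (case in list(c(2, 5, 4, 10), c(1, 3, 6, 12), c(3, 7, 5, 14))) {
        expect_equal(
            hypergeomUpperTail(case[1], case[2], case[3], case[4]),
            enumUpperTail(case[1], case[2], case[3], case[4]),
            tolerance = 1e-12)
    }
})

test_that("upper tail boundary cases and argument checks behave", {
    expect_equal(hypergeomUpperTail(0, 5, 4, 10), 1)
    expect_equal(hypergeomUpperTail(4, 4, 4, 4), 1)  # forced draw
    expect_error(hypergeomUpperTail(5, 4, 10, 10), "k")
    expect_error(hypergeomUpperTail(1, 11, 4, 10), "K")
    expect_error(hypergeomUpperTail(1, 4, 11, 10), "n")
})

test_that("upper tail agrees with stats::phyper and is numerically safe at N = 1e5", {
    set.seed(31)
    for (i in 1:30) {
        N <- sample(c(100L, 5000L, 100000L), 1L)
        K <- sample.int(N %/% 2L, 1L)
        n <- sample.int(N %/% 2L, 1L)
        k <- sample(0:min(n, K), 1L)
        expect_equal(hypergeomUpperTail(k, K, n, N),
            stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
            tolerance = 1e-10)
    }
})

test_that("pmf sums to one and the upper tail is monotone in k", {
    for (N in c(10L, 57L, 200L)) {
        for (K in unique(c(0L, 3L, N %/% 2L, N))) {
            for (n in unique(c(1L, N %/% 3L + 1L, N))) {
                ks <- max(0L, n + K - N):min(n, K)
                expect_equal(sum(vapply(ks, hypergeomPmf, 0, K = K,
                    n = n, N = N)), 1, tolerance = 1e-12)
                p <- vapply(ks, hypergeomUpperTail, 0, K = K, n = n, N = N)
                expect_true(all(diff(p) <= 1e-12))
            }
        }
    }
})

test_that("BH step-up matches the hand-derived example and p.adjust", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.5), 0.5)
    set.seed(17)
    for (i in 1:10) {
        p <- stats::runif(sample(1:40, 1L))
        adj <- bhAdjust(p)
        expect_equal(adj, stats::p.adjust(p, "BH"))
        expect_true(all(adj >= p))
        # permutation invariance
        perm <- sample(length(p))
        expect_equal(bhAdjust(p[perm])[order(perm)], adj)
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    expect_equal(bonferroniAdjust(c(0.01, 0.4)), c(0.02, 0.8))
})

test_that("enrichment table has coherent counts, ordering and flags", {
    genes <- sprintf("G%03d", 1:100)
    ann <- data.frame(
        term_id = rep(c("T1", "T2"), c(20L, 30L)),
        term_name = rep(c("alpha", "beta"), c(20L, 30L)),
        gene_id = c(genes[1:20], genes[41:70]),
        stringsAsFactors = FALSE)
    res <- enrichTerms(genes[1:15], ann, genes)
    expect_equal(res$term_id[1L], "T1")
    expect_equal(res$k[res$term_id == "T1"], 15L)
    expect_equal(res$K[res$term_id == "T1"], 20L)
    expect_equal(res$N, rep(100L, 2L))
    expect_true(res$significant[1L])
    expect_equal(res$enrichment_ratio[res$term_id == "T1"],
        (15 / 15) / (20 / 100))
    # query = universe: every term has k = K and p = 1
    full <- enrichTerms(genes, ann, genes)
    expect_equal(full$k, full$K)
    expect_true(all(full$p_value == 1))
    # genes outside the universe are dropped with a warning
    expect_warning(enrichTerms(c(genes[1:5], "NOPE"), ann, genes),
        "outside the universe")
    # terms with no universe gene are skipped
    ann2 <- rbind(ann, data.frame(term_id = "T3", term_name = "ghost",
        gene_id = "ELSEWHERE"))
    expect_equal(nrow(enrichTerms(genes[1:5], ann2, genes)), 2L)
    expect_error(enrichTerms(genes[1:5], ann, character()), "non-empty")
})

test_that("the planted enriched term is recovered from synthetic annotations", {
    ids <- sprintf("VIT_%04d", 1:2000)
    target <- ids[1:30]
    # deterministic construction: target set exactly annotated
    annExact <- generateAnnotations(ids, target, insideRate = 1,
        backgroundRate = 0, nOtherTerms = 0L, seed = 4L)
    expect_equal(sort(unique(annExact$term_id)), "TERM:0000001")
    expect_setequal(annExact$gene_id, target)
    res <- enrichTerms(target, annExact, ids)
    expect_equal(res$term_id[1L], "TERM:0000001")
    expect_lt(res$adjusted_p[1L], 1e-20)
})

test_that("analytic p-values sit inside the Monte-Carlo band of a permutation null", {
    set.seed(61)
    for (i in 1:20) {
        N <- sample(100:800, 1L)
        K <- sample(5:(N %/% 4L), 1L)
        n <- sample(5:(N %/% 4L), 1L)
        k <- stats::rhyper(1L, K, N - K, n)  # a typical observed overlap
        p <- hypergeomUpperTail(k, K, n, N)
        draws <- stats::rhyper(20000L, K, N - K, n)
        phat <- mean(draws >= k)
        se <- sqrt(max(p * (1 - p), 1 / 20000) / 20000)
        expect_lt(abs(p - phat), 3 * se + 1e-12)
    }
})

test_that("shared significant terms intersect correctly", {
    mk <- function(ids, adj) data.frame(term_id = ids, adjusted_p = adj,
        stringsAsFactors = FALSE)
    a <- mk(c("t1", "t2", "t3"), c(0.01, 0.02, 0.2))
    b <- mk(c("t2", "t3", "t4"), c(0.01, 0.03, 0.9))
    # significant sets are {t1, t2} and {t2, t3}: the intersection is {t2}
    expect_equal(sharedTerms(a, b, 0.05), "t2")
    expect_equal(sharedTerms(a, mk("t9", 0.001), 0.05), character())
    expect_equal(sharedTerms(a, a, 0.05), c("t1", "t2"))
})
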