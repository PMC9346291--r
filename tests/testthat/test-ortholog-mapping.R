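test_that("hit tables parse with coverage arithmetic and coordinate normalisation", {
    path <- withr::local_tempfile(lines = c(
        "t1\tVIT_X\t98.0\t450\t2\t0\t1\t450\t1\t450\t1e-50\t800",
        "t2\tVIT_Y\t90.0\t200\t5\t1\t300\t101\t1\t200\t1e-20\t300"))
    hits <- readHitTable(path)
    expect_equal(nrow(hits), 2L)
    expect_equal(hits$subject_id, c("VIT_X", "VIT_Y"))
    # reversed query coordinates are normalised to qstart <= qend
    expect_equal(hits$qstart[2], 101L)
    expect_equal(hits$qend[2], 300L)
    cov <- queryCoverage(hits, c(t1 = 500L, t2 = 400L))
    expect_equal(cov, c(450 / 500, 200 / 400))
})

test_that("empty and malformed hit tables follow the parsing contract", {
    empty <- withr::local_tempfile(lines = character())
    expect_equal(nrow(readHitTable(empty)), 0L)

    mixed <- withr::local_tempfile(lines = c(
        "t1\tVIT_X\t98.0\t450\t2\t0\t1\t450\t1\t450\t1e-50\t800",
        "t2\tVIT_Y\tnot_a_number\t450\t2\t0\t1\t450\t1\t450\t1e-50\t800",
        "t3\ttoo\tfew\tcolumns"))
    expect_warning(hits <- readHitTable(mixed), "2 malformed")
    expect_equal(hits$query_id, "t1")
    expect_error(readHitTable(mixed, strict = TRUE), "malformed")
    expect_error(readHitTable("/nonexistent/file.tsv"), "not found")
})

test_that("full-length flag column drops partial transcripts when present", {
    path <- withr::local_tempfile(lines = c(
        "t1\tVIT_X\t98.0\t450\t2\t0\t1\t450\t1\t450\t1e-50\t800\t1",
        "t2\tVIT_Y\t98.0\t450\t2\t0\t1\t450\t1\t450\t1e-50\t800\t0"))
    expect_equal(readHitTable(path)$query_id, "t1")
    expect_equal(readHitTable(path, dropPartial = FALSE)$query_id,
        c("t1", "t2"))
})

test_that("coverage requires a length for every query and a sane qend", {
    h <- data.frame(query_id = "t1", qstart = 1L, qend = 450L)
    expect_error(queryCoverage(h, c(other = 500L)), "t1")
    expect_error(queryCoverage(h, c(t1 = 400L)), "shorter")
    expect_equal(queryCoverage(h, c(t1 = 500L)), 0.9)
})

test_that("filterHits keeps exactly the hits inside both inclusive boundaries", {
    qlen <- c(a = 100L, b = 100L, c = 100L, d = 100L)
    hits <- data.frame(
        query_id = c("a", "b", "c", "d"),
        subject_id = paste0("VIT_", 1:4),
        percent_identity = 95, align_length = 90L, mismatches = 0L,
        gap_opens = 0L, qstart = 1L,
        qend = c(95L, 95L, 90L, 89L),   # cov 0.95, 0.95, 0.90, 0.89
        sstart = 1L, send = 90L,
        evalue = c(1e-12, 1e-6, 1e-9, 1e-50),
        bitscore = 500,
        stringsAsFactors = FALSE)
    kept <- filterHits(hits, filterThresholds(1e-9, 0.9), qlen)
    # passes; fails e-value; exactly on both boundaries (kept); fails coverage
    expect_equal(kept$query_id, c("a", "c"))
    # idempotence
    expect_identical(filterHits(kept, filterThresholds(1e-9, 0.9), qlen), kept)
    # brute-force predicate agreement
    cov <- (hits$qend - hits$qstart + 1) / qlen[hits$query_id]
    expect_equal(kept$query_id,
        hits$query_id[hits$evalue <= 1e-9 & cov >= 0.9])
})

test_that("relaxing thresholds never removes a presence (monotonicity)", {
    set.seed(11)
    com <- generateCommunity(communityConfig(nFocal = 3L, nBackground = 4L,
        nOrthologs = 120L, nCore = 20L, plantedExclusive = c("2" = 5L),
        nAbsent = 10L, dropout = 0.1, spuriousRate = 3, seed = 11L))
    strict <- classifyCommunity(com, filterThresholds(1e-9, 0.9))
    loose <- classifyCommunity(com, filterThresholds(1e-6, 0.8))
    # every ortholog detected under the strict filter stays detected
    expect_true(all(strict@universe %in% loose@universe))
})

test_that("best hit selection is deterministic: bitscore, e-value, subject id", {
    hits <- data.frame(
        query_id = "t1", subject_id = c("A", "B"),
        percent_identity = 95, align_length = 90L, mismatches = 0L,
        gap_opens = 0L, qstart = 1L, qend = 95L, sstart = 1L, send = 90L,
        evalue = 1e-40, bitscore = c(200, 150), stringsAsFactors = FALSE)
    expect_equal(bestHitPerTranscript(hits), c(t1 = "A"))
    hits$bitscore <- 200; hits$evalue <- c(1e-40, 1e-50)
    expect_equal(bestHitPerTranscript(hits), c(t1 = "B"))
    hits$evalue <- 1e-50
    hits$subject_id <- c("B", "A")
    expect_equal(bestHitPerTranscript(hits), c(t1 = "A"))
})

test_that("best hit selection is permutation-invariant", {
    set.seed(5)
    hits <- data.frame(
        query_id = sample(paste0("t", 1:8), 40, replace = TRUE),
        subject_id = sample(paste0("VIT_", 1:12), 40, replace = TRUE),
        evalue = 10^-sample(10:60, 40, replace = TRUE),
        bitscore = sample(100:900, 40, replace = TRUE),
        stringsAsFactors = FALSE)
    ref <- bestHitPerTranscript(hits)
    for (i in 1:10) {
        sh <- hits[sample(nrow(hits)), ]
        got <- bestHitPerTranscript(sh)
        expect_identical(got[sort(names(got))], ref[sort(names(ref))])
    }
})

test_that("presence matrix collapses many transcripts to one ortholog cell", {
    md <- data.frame(species_id = c("S1", "S2"),
        growth_form = c("focal", "background"),
        collapse_group = c("S1", "S2"), stringsAsFactors = FALSE)
    best <- list(S1 = c(t1 = "A", t2 = "A", t3 = "B"), S2 = c(t1 = "B"))
    pm <- buildPresenceMatrix(best, md)
    expect_equal(dim(pm), c(2L, 2L))
    expect_equal(presence(pm)["A", ], c(S1 = TRUE, S2 = FALSE))
    expect_equal(presence(pm)["B", ], c(S1 = TRUE, S2 = TRUE))
    expect_error(buildPresenceMatrix(list(S3 = c(t1 = "A")), md), "S3")
})

test_that("species metadata reader normalises liana/non_liana labels", {
    path <- withr::local_tempfile(lines = c(
        "species_id\tgrowth_form\tcollapse_group",
        "LIA01\tliana\tLIA01",
        "TRE01\tnon_liana\tTRE01"))
    md <- readSpeciesMetadata(path)
    expect_equal(md$growth_form, c("focal", "background"))
    bad <- withr::local_tempfile(lines = c(
        "species_id\tgrowth_form", "X\tshrubbery"))
    expect_error(readSpeciesMetadata(bad), "shrubbery")
})
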