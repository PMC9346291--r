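test_that("edge loading dedupes reversed pairs, drops loops, inclusive cutoff", {
    path <- withr::local_tempfile(lines = c(
        "protein1\tprotein2\tcombined_score",
        "A\tB\t900", "B\tA\t700",   # reversed duplicate, keep max
        "A\tA\t950",                # self-loop
        "C\tD\t400", "D\tE\t300"))  # boundary inclusive at 400
    expect_warning(net <- readStringEdges(path, minScore = 400L),
        "self-loop")
    ed <- networkEdges(net)
    expect_equal(nrow(ed), 2L)
    expect_equal(ed$combined_score[ed$protein1 == "A"], 900L)
    expect_true(all(c("C", "D") %in% orthologIds(net)))
    expect_false("E" %in% ed$protein2)
    # brute-force predicate on the scores {300, 400, 500}
    p2 <- withr::local_tempfile(lines = c("A\tB\t300", "B\tC\t400",
        "C\tD\t500"))
    expect_equal(numEdges(readStringEdges(p2, 400L)), 2L)
    bad <- withr::local_tempfile(lines = c("A\tB\t900", "B\tC\toops"))
    expect_error(readStringEdges(bad), "line 2")
})

test_that("shell extraction follows BFS layers on a path graph", {
    net <- interactionNetwork(data.frame(
        protein1 = c("A", "B", "C"), protein2 = c("B", "C", "D"),
        combined_score = 500L, stringsAsFactors = FALSE))
    sub <- extractSubnetwork(net, "A", nShells = 2L)
    nd <- networkNodes(sub)
    expect_equal(stats::setNames(nd$shell, nd$node)[c("A", "B", "C")],
        c(A = 0L, B = 1L, C = 2L))
    expect_false("D" %in% nd$node)
    ed <- networkEdges(sub)
    expect_equal(nrow(ed), 2L)
    # isolated seed and seed missing from the network
    iso <- interactionNetwork(data.frame(protein1 = "X", protein2 = "Y",
        combined_score = 500L), nodes = "A")
    subIso <- extractSubnetwork(iso, "A", 2L)
    expect_equal(numNodes(subIso), 1L)
    expect_equal(numEdges(subIso), 0L)
    expect_warning(subMiss <- extractSubnetwork(net, c("A", "ZZ"), 1L),
        "absent")
    ndm <- networkNodes(subMiss)
    expect_equal(ndm$shell[ndm$node == "ZZ"], 0L)
})

test_that("tree shell edges keep only consecutive-shell links", {
    # triangle A-B-C plus spur C-D, seed A: edge B-C joins two shell-1 nodes
    net <- interactionNetwork(data.frame(
        protein1 = c("A", "A", "B", "C"), protein2 = c("B", "C", "C", "D"),
        combined_score = 500L, stringsAsFactors = FALSE))
    ind <- extractSubnetwork(net, "A", 2L, shellEdges = "induced")
    tre <- extractSubnetwork(net, "A", 2L, shellEdges = "tree")
    expect_equal(numEdges(ind), 4L)
    expect_equal(numEdges(tre), 3L)
    trEd <- networkEdges(tre)
    expect_false(any(trEd$protein1 == "B" & trEd$protein2 == "C"))
})

test_that("shell labels equal all-pairs shortest distances on random graphs", {
    set.seed(21)
    for (i in 1:25) {
        net <- randomNetwork(sample(10:50, 1L), pEdge = 0.08)
        seeds <- sample(orthologIds(net), sample(1:3, 1L))
        k <- sample(0:3, 1L)
        sub <- extractSubnetwork(net, seeds, nShells = k)
        oracle <- oracleShells(net, seeds, k)
        nd <- networkNodes(sub)
        got <- stats::setNames(nd$shell, nd$node)
        got <- got[order(names(got))]
        expect_identical(got, oracle$shells)
        expect_identical(networkEdges(sub), oracle$edges)
    }
})

test_that("subnetwork of all nodes with zero shells is the identity", {
    set.seed(3)
    net <- randomNetwork(30L, 0.1)
    sub <- extractSubnetwork(net, orthologIds(net), nShells = 0L)
    expect_identical(networkEdges(sub), networkEdges(net))
    expect_setequal(orthologIds(sub), orthologIds(net))
    expect_error(extractSubnetwork(net, character()), "non-empty")
    expect_error(extractSubnetwork(net, "N01", nShells = -1L), ">= 0")
})

test_that("sector annotation labels mapped nodes, defaults the rest", {
    net <- interactionNetwork(data.frame(protein1 = c("A", "B"),
        protein2 = c("B", "C"), combined_score = 500L))
    ann <- annotateSectors(net, c(A = "L5"))
    nd <- networkNodes(ann)
    expect_equal(nd$category[nd$node == "A"], "L5")
    expect_equal(nd$category[nd$node != "A"],
        rep("shell_interactor", 2L))
    all_default <- networkNodes(annotateSectors(net, character()))
    expect_true(all(all_default$category == "shell_interactor"))
})

test_that("network merging is a union keeping max scores and joint labels", {
    e1 <- data.frame(protein1 = "A", protein2 = "B", combined_score = 500L)
    e2 <- data.frame(protein1 = "A", protein2 = "B", combined_score = 700L)
    n1 <- annotateSectors(interactionNetwork(e1), c(A = "L2"))
    n2 <- annotateSectors(interactionNetwork(e2), c(A = "co_downregulated"))
    m <- mergeNetworks(n1, n2)
    expect_equal(networkEdges(m)$combined_score, 700L)
    nd <- networkNodes(m)
    expect_equal(nd$category[nd$node == "A"], "L2+co_downregulated")
    # disjoint networks add up
    d1 <- interactionNetwork(data.frame(protein1 = "A", protein2 = "B",
        combined_score = 400L))
    d2 <- interactionNetwork(data.frame(protein1 = "C", protein2 = "D",
        combined_score = 400L))
    md <- mergeNetworks(d1, d2)
    expect_equal(numNodes(md), 4L)
    expect_equal(numEdges(md), 2L)
    # idempotence and commutativity
    expect_identical(networkEdges(mergeNetworks(n1, n1)), networkEdges(n1))
    expect_identical(networkNodes(mergeNetworks(n1, n2)),
        networkNodes(mergeNetworks(n2, n1)))
})

test_that("degree ranking sorts by degree then id; degree sum is twice edges", {
    star <- interactionNetwork(data.frame(
        protein1 = "HUB", protein2 = sprintf("L%d", 1:6),
        combined_score = 500L))
    rk <- degreeRanking(star)
    expect_equal(rk$node[1L], "HUB")
    expect_equal(rk$degree[1L], 6L)
    tri <- interactionNetwork(data.frame(
        protein1 = c("C", "A", "B"), protein2 = c("A", "B", "C"),
        combined_score = 500L))
    rkt <- degreeRanking(tri)
    expect_equal(rkt$node, c("A", "B", "C"))
    expect_equal(rkt$degree, rep(2L, 3L))
    set.seed(8)
    net <- randomNetwork(40L, 0.1)
    expect_equal(sum(degreeRanking(net)$degree), 2L * numEdges(net))
    expect_equal(nrow(degreeRanking(net, topN = 5L)), 5L)
})

test_that("coverage fraction reproduces the in-study gene-space figure", {
    expect_equal(coverageFraction(3835, 33568), 100 * 3835 / 33568)
    expect_gt(coverageFraction(3835, 33568), 11)
    expect_equal(coverageFraction(0, 100), 0)
    expect_equal(coverageFraction(100, 100), 100)
    expect_error(coverageFraction(10, 0), "positive")
    net <- interactionNetwork(data.frame(protein1 = "A", protein2 = "B",
        combined_score = 500L))
    expect_equal(coverageFraction(net, 20), 10)
})

test_that("graph export round-trips through GraphML and honours SIF/node-table contracts", {
    net <- interactionNetwork(data.frame(
        protein1 = c("A", "B"), protein2 = c("B", "C"),
        combined_score = c(500L, 900L)), nodes = "D")
    net <- annotateSectors(net, c(A = "L3", D = "co_downregulated"))
    net <- suppressWarnings(extractSubnetwork(net, c("A", "D"), 2L))
    gml <- withr::local_tempfile(fileext = ".graphml")
    exportGraph(net, gml, "graphml")
    back <- importGraph(gml, "graphml")
    expect_identical(networkEdges(back), networkEdges(net))
    ndA <- networkNodes(net); ndB <- networkNodes(back)
    expect_equal(ndB[order(ndB$node), ], ndA[order(ndA$node), ],
        ignore_attr = TRUE)
    sif <- withr::local_tempfile(fileext = ".sif")
    exportGraph(net, sif, "sif")
    lines <- readLines(sif)
    expect_true("A pp B" %in% lines)
    expect_true("D" %in% lines)  # isolated node kept
    tab <- withr::local_tempfile(fileext = ".tsv")
    exportGraph(net, tab, "node_table")
    nd <- utils::read.table(tab, header = TRUE, sep = "\t")
    expect_setequal(colnames(nd), c("node", "category", "shell"))
    expect_equal(nrow(nd), numNodes(net))
    expect_error(exportGraph(net, tab, "dot"), "arg")
})
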