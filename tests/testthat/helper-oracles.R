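# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. Oracles deliberately avoid the package's own
# code paths: classification is re-derived per ortholog with scalar
# predicates, shells with igraph's all-pairs distances.

# random ortholog x unit presence matrix with at least one focal and one
# background unit
randomPresenceMatrix <- function(nUnits, nOrth, pPresent = 0.4) {
    m <- matrix(stats::runif(nOrth * nUnits) < pPresent, nrow = nOrth,
        dimnames = list(sprintf("VIT_%04d", seq_len(nOrth)),
            sprintf("U%02d", seq_len(nUnits))))
    nFocal <- sample(seq_len(nUnits - 1L), 1L)
    PresenceMatrix(m, growthForm = c(rep("focal", nFocal),
        rep("background", nUnits - nFocal)))
}

# per-ortholog scalar predicate evaluation of the three classifiers
oracleClassify <- function(pm, minSupport = 1L, excludeCore = TRUE) {
    m <- presence(pm)
    foc <- growthForm(pm) == "focal"
    core <- character(); absent <- character()
    exclusive <- stats::setNames(
        rep(list(character()), sum(foc)), as.character(seq_len(sum(foc))))
    for (o in rownames(m)) {
        pres <- m[o, ]
        nf <- sum(pres[foc]); nb <- sum(pres[!foc])
        isCore <- all(pres)
        if (isCore) core <- c(core, o)
        if (nf >= 1L && nb == 0L && !(excludeCore && isCore))
            exclusive[[as.character(nf)]] <-
                c(exclusive[[as.character(nf)]], o)
        if (nf == 0L && nb >= minSupport) absent <- c(absent, o)
    }
    list(core = sort(core), exclusive = lapply(exclusive, sort),
        absent = sort(absent))
}

# all-pairs-distance shell oracle on an InteractionNetwork
oracleShells <- function(net, seeds, nShells) {
    g <- net@graph
    seeds <- intersect(seeds, igraph::V(g)$name)
    d <- igraph::distances(g, v = seeds)
    dmin <- apply(d, 2L, min)
    dmin[is.infinite(dmin)] <- NA
    keep <- !is.na(dmin) & dmin <= nShells
    shells <- stats::setNames(as.integer(dmin[keep]),
        colnames(d)[keep])
    ed <- networkEdges(net)
    ed <- ed[ed$protein1 %in% names(shells) &
        ed$protein2 %in% names(shells), , drop = FALSE]
    ed <- ed[order(ed$protein1, ed$protein2), , drop = FALSE]
    rownames(ed) <- NULL
    list(shells = shells[order(names(shells))], edges = ed)
}

# random simple named graph as an InteractionNetwork
randomNetwork <- function(nNodes, pEdge = 0.1) {
    g <- igraph::sample_gnp(nNodes, pEdge)
    el <- igraph::as_edgelist(g)
    ids <- sprintf("N%02d", seq_len(nNodes))
    edges <- data.frame(protein1 = ids[el[, 1L]], protein2 = ids[el[, 2L]],
        combined_score = sample(400:1000, nrow(el), replace = TRUE),
        stringsAsFactors = FALSE)
    interactionNetwork(edges, nodes = ids)
}

# classification straight from in-memory hit tables (no disk round trip)
classifyCommunity <- function(com, thresholds = filterThresholds(),
        minBackgroundSupport = 1L) {
    best <- lapply(com$hitTables, function(h)
        bestHitPerTranscript(filterHits(h, thresholds, com$queryLengths)))
    pm <- buildPresenceMatrix(best, com$speciesMetadata)
    classifyConvergence(pm, minBackgroundSupport = minBackgroundSupport)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# minimal hand-built presence fixture: 4 orthologs x 4 units
tinyPresence <- function() {
    m <- matrix(c(
        TRUE,  TRUE,  TRUE,  TRUE,   # core
        TRUE,  TRUE,  FALSE, FALSE,  # exclusive L2
        FALSE, FALSE, TRUE,  TRUE,   # absent in focal
        TRUE,  FALSE, TRUE,  FALSE), # mixed
        nrow = 4L, byrow = TRUE,
        dimnames = list(c("CORE", "EXC2", "ABS", "MIX"),
            c("F1", "F2", "B1", "B2")))
    PresenceMatrix(m, growthForm = c("focal", "focal",
        "background", "background"))
}
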