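#' @include AllClasses.R
NULL

#' Configuration of a synthetic species community
#'
#' Describes a community of `nFocal` focal-group species (the study's ten
#' lianas) and `nBackground` background species (37 trees and shrubs)
#' detected against a universe of `nOrthologs` reference orthologs. The
#' universe is partitioned into planted compartments: `nCore` orthologs
#' present in every species, `plantedExclusive[k]` orthologs present in
#' exactly k focal species and no background species (the convergence
#' levels, k >= 2 in the study's L2-L5 analysis), `nAbsent` orthologs
#' present in at least one background species and no focal species, and
#' random filler ("mixed") genes. Detection noise is independent Bernoulli
#' dropout per (species, expressed ortholog) plus Poisson-distributed
#' decoy hits per species that must fail the quality filter.
#'
#' @param nFocal,nBackground Species counts (defaults 10 and 37, the
#'   study's community shape).
#' @param nOrthologs Reference universe size (default 2000; the real
#'   grapevine reference has 33,568 protein-coding genes).
#' @param nCore Planted core orthologs (default 100).
#' @param plantedExclusive Named integer vector, level k (as name) ->
#'   count of level-k exclusive orthologs; default 10 each at levels 2-5.
#' @param nAbsent Planted group-absent orthologs (default 200).
#' @param dropout Per-(species, expressed ortholog) probability of
#'   non-detection, in [0, 1). Default 0.05.
#' @param spuriousRate Expected decoy (filter-failing) hits per species,
#'   >= 0. Default 2.
#' @param mixedRate Per-species presence probability of filler genes
#'   (default 0.3); every filler gene is additionally guaranteed one focal
#'   and one background presence so fillers never mimic a planted pattern.
#' @param seed Integer random seed.
#' @return A validated list of class `CommunityConfig`.
#' @export
communityConfig <- function(nFocal = 10L, nBackground = 37L,
        nOrthologs = 2000L, nCore = 100L,
        plantedExclusive = c("2" = 10L, "3" = 10L, "4" = 10L, "5" = 10L),
        nAbsent = 200L, dropout = 0.05, spuriousRate = 2,
        mixedRate = 0.3, seed = 1L) {
    cfg <- list(nFocal = as.integer(nFocal),
        nBackground = as.integer(nBackground),
        nOrthologs = as.integer(nOrthologs), nCore = as.integer(nCore),
        plantedExclusive = stats::setNames(as.integer(plantedExclusive),
            names(plantedExclusive)),
        nAbsent = as.integer(nAbsent), dropout = dropout,
        spuriousRate = spuriousRate, mixedRate = mixedRate,
        seed = as.integer(seed))
    for (f in c("nFocal", "nBackground", "nOrthologs", "nCore", "nAbsent"))
        if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
            stop("configuration error: '", f, "' must be a non-negative count")
    if (cfg$nFocal < 1L)
        stop("configuration error: 'nFocal' must be >= 1")
    if (length(cfg$plantedExclusive)) {
        lv <- suppressWarnings(as.integer(names(cfg$plantedExclusive)))
        if (anyNA(lv) || any(lv < 2L) || any(lv > cfg$nFocal))
            stop("configuration error: 'plantedExclusive' levels must lie in 2..nFocal")
        if (any(cfg$plantedExclusive < 0L))
            stop("configuration error: 'plantedExclusive' counts must be >= 0")
        if (anyDuplicated(lv))
            stop("configuration error: duplicate 'plantedExclusive' level")
    }
    if (cfg$nCore + sum(cfg$plantedExclusive) + cfg$nAbsent > cfg$nOrthologs)
        stop("configuration error: 'nOrthologs' too small for the planted compartments")
    if (!is.numeric(cfg$dropout) || cfg$dropout < 0 || cfg$dropout >= 1)
        stop("configuration error: 'dropout' must lie in [0, 1)")
    if (!is.numeric(cfg$spuriousRate) || cfg$spuriousRate < 0)
        stop("configuration error: 'spuriousRate' must be >= 0")
    if (cfg$mixedRate < 0 || cfg$mixedRate > 1)
        stop("configuration error: 'mixedRate' must lie in [0, 1]")
    structure(cfg, class = "CommunityConfig")
}

.orthId <- function(i) sprintf("VIT_%05dg", i)

#' Generate a synthetic community with planted ground truth
#'
#' Emulates the input of a multi-species ortholog-mapping study at the
#' hit-table level: for each species, each truly present ortholog that
#' survives dropout yields exactly one filter-passing hit (e-value <=
#' 1e-12, query coverage >= 0.95, comfortably inside the 1e-9/0.9 filter),
#' plus Poisson(`spuriousRate`) decoy hits each failing the filter by
#' construction (e-value drawn in (1e-8, 1e-3) or coverage in (0.3, 0.85),
#' straddling neither boundary). Identical `(config, seed)` give
#' byte-identical outputs.
#'
#' @param config A [communityConfig()].
#' @return List with elements `hitTables` (named list of per-species
#'   12-column hit `data.frame`s), `queryLengths` (named integer vector
#'   over all query ids), `speciesMetadata` (`data.frame`:
#'   `species_id`, `growth_form`, `collapse_group`), and `groundTruth`
#'   (list: `truePresence` logical ortholog x species matrix before
#'   dropout, `coreIds`, `exclusiveIdsByLevel`, `absentIds`, `mixedIds`,
#'   `hubId`, `enrichedTermId`).
#' @export
generateCommunity <- function(config = communityConfig()) {
    stopifnot(inherits(config, "CommunityConfig"))
    set.seed(config$seed)
    nSp <- config$nFocal + config$nBackground
    species <- c(sprintf("LIA%02d", seq_len(config$nFocal)),
        sprintf("TRE%02d", seq_len(config$nBackground)))
    focal <- seq_len(config$nFocal)
    background <- config$nFocal + seq_len(config$nBackground)
    orth <- .orthId(seq_len(config$nOrthologs))

    nEx <- sum(config$plantedExclusive)
    idx <- seq_len(config$nCore)
    coreIds <- orth[idx]
    exclusiveIdsByLevel <- list()
    at <- config$nCore
    for (k in names(config$plantedExclusive)) {
        cnt <- config$plantedExclusive[[k]]
        exclusiveIdsByLevel[[k]] <- orth[at + seq_len(cnt)]
        at <- at + cnt
    }
    absentIds <- orth[at + seq_len(config$nAbsent)]
    at <- at + config$nAbsent
    mixedIds <- if (at < config$nOrthologs)
        orth[(at + 1L):config$nOrthologs] else character()

    true <- matrix(FALSE, nrow = config$nOrthologs, ncol = nSp,
        dimnames = list(orth, species))
    true[coreIds, ] <- TRUE
    for (k in names(exclusiveIdsByLevel)) {
        kk <- as.integer(k)
        for (id in exclusiveIdsByLevel[[k]])
            true[id, sample(focal, kk)] <- TRUE
    }
    for (id in absentIds) {
        carriers <- background[stats::runif(length(background)) < 0.5]
        if (!length(carriers)) carriers <- sample(background, 1L)
        true[id, carriers] <- TRUE
    }
    if (length(mixedIds) && nSp >= 2L) {
        rnd <- matrix(stats::runif(length(mixedIds) * nSp) < config$mixedRate,
            nrow = length(mixedIds))
        true[mixedIds, ] <- rnd
        # anchor one focal and one background presence so fillers are
        # always "mixed", never exclusive or group-absent
        if (length(background)) {
            fAnchor <- sample(focal, length(mixedIds), replace = TRUE)
            bAnchor <- sample(background, length(mixedIds), replace = TRUE)
            true[cbind(match(mixedIds, orth), fAnchor)] <- TRUE
            true[cbind(match(mixedIds, orth), bAnchor)] <- TRUE
        }
    }

    hitTables <- vector("list", nSp)
    names(hitTables) <- species
    queryLengths <- list()
    for (s in seq_len(nSp)) {
        expressed <- orth[true[, s]]
        detected <- expressed[stats::runif(length(expressed)) >= config$dropout]
        nDecoy <- stats::rpois(1L, config$spuriousRate)
        nHit <- length(detected) + nDecoy
        qid <- sprintf("%s_t%06d", species[s], seq_len(nHit))
        qlen <- sample(300:1500, nHit, replace = TRUE)
        hits <- .emptyHits()
        if (nHit > 0L) {
            pass <- seq_len(length(detected))
            qend <- integer(nHit); ev <- numeric(nHit)
            subj <- character(nHit)
            subj[pass] <- detected
            # passing hits: coverage >= 0.95, evalue <= 1e-12
            qend[pass] <- ceiling(stats::runif(length(pass), 0.95, 1) *
                qlen[pass])
            ev[pass] <- 10^stats::runif(length(pass), -50, -12)
            if (nDecoy > 0L) {
                dec <- length(detected) + seq_len(nDecoy)
                subj[dec] <- sample(orth, nDecoy, replace = TRUE)
                badEv <- stats::runif(nDecoy) < 0.5
                ev[dec] <- ifelse(badEv,
                    10^stats::runif(nDecoy, -8, -3),       # fails e-value
                    10^stats::runif(nDecoy, -50, -12))
                covDec <- ifelse(badEv,
                    stats::runif(nDecoy, 0.95, 1),
                    stats::runif(nDecoy, 0.3, 0.85))       # fails coverage
                qend[dec] <- pmax(1L, floor(covDec * qlen[dec]))
            }
            hits <- data.frame(query_id = qid, subject_id = subj,
                percent_identity = round(stats::runif(nHit, 80, 100), 1),
                align_length = qend, mismatches = 0L, gap_opens = 0L,
                qstart = 1L, qend = qend, sstart = 1L, send = qend,
                evalue = signif(ev, 3), bitscore = round(
                    stats::runif(nHit, 200, 900), 1),
                stringsAsFactors = FALSE)
        }
        hitTables[[s]] <- hits
        queryLengths[[s]] <- stats::setNames(qlen, qid)
    }

    hubPool <- c(unlist(exclusiveIdsByLevel, use.names = FALSE), coreIds, orth)
    hubId <- hubPool[1L]
    list(hitTables = hitTables,
        queryLengths = unlist(unname(queryLengths)),
        speciesMetadata = data.frame(species_id = species,
            growth_form = c(rep("focal", config$nFocal),
                rep("background", config$nBackground)),
            collapse_group = species, stringsAsFactors = FALSE),
        groundTruth = list(truePresence = true, coreIds = coreIds,
            exclusiveIdsByLevel = exclusiveIdsByLevel,
            absentIds = absentIds, mixedIds = mixedIds,
            hubId = hubId, enrichedTermId = "TERM:0000001"))
}

#' Generate a STRING-style network with a planted hub and module
#'
#' Builds a simple undirected weighted edge list over `orthologIds` where
#' `hubId` is guaranteed the unique maximum-degree node (degree
#' `hubDegree`, plus clique edges when the hub belongs to the module),
#' `moduleIds` form a clique, and `extraEdges` random edges
#' are added subject to keeping every other node's degree strictly below
#' `hubDegree`. Scores are drawn uniformly in [400, 1000].
#'
#' @param orthologIds Character vector of node ids.
#' @param hubDegree Planted hub degree; must be < `length(orthologIds)`
#'   and > `length(moduleIds)` so the hub is uniquely maximal.
#' @param moduleIds Ids to connect as a clique (subset of `orthologIds`).
#' @param extraEdges Number of additional random edges.
#' @param seed Integer random seed.
#' @param hubId Hub node id; default the first of `orthologIds`.
#' @return Edge `data.frame` (`protein1`, `protein2`, `combined_score`).
#' @export
generateNetwork <- function(orthologIds, hubDegree, moduleIds = character(),
        extraEdges = 0L, seed = 1L, hubId = orthologIds[[1L]]) {
    n <- length(orthologIds)
    if (hubDegree >= n)
        stop("configuration error: 'hubDegree' must be < number of ortholog ids")
    if (!all(moduleIds %in% orthologIds))
        stop("configuration error: 'moduleIds' must be a subset of 'orthologIds'")
    if (!hubId %in% orthologIds)
        stop("configuration error: 'hubId' must be one of 'orthologIds'")
    if (length(moduleIds) && hubDegree <= length(moduleIds))
        stop("configuration error: 'hubDegree' must exceed the module size")
    set.seed(seed)
    others <- setdiff(orthologIds, hubId)
    nbr <- sample(others, hubDegree)
    edges <- data.frame(protein1 = hubId, protein2 = nbr,
        stringsAsFactors = FALSE)
    if (length(moduleIds) >= 2L) {
        cmb <- utils::combn(sort(moduleIds), 2L)
        edges <- rbind(edges, data.frame(protein1 = cmb[1L, ],
            protein2 = cmb[2L, ], stringsAsFactors = FALSE))
    }
    deg <- function(e) {
        d <- table(c(e$protein1, e$protein2))
        stats::setNames(as.integer(d), names(d))
    }
    nAdded <- 0L
    guard <- 0L
    while (nAdded < extraEdges && guard < 50L * extraEdges + 100L) {
        guard <- guard + 1L
        pair <- sample(others, 2L)
        a <- min(pair); b <- max(pair)
        if (any(edges$protein1 == a & edges$protein2 == b) ||
            any(edges$protein1 == b & edges$protein2 == a))
            next
        d <- deg(edges)
        da <- if (a %in% names(d)) d[[a]] else 0L
        db <- if (b %in% names(d)) d[[b]] else 0L
        if (da + 1L >= hubDegree || db + 1L >= hubDegree)
            next  # keep the hub uniquely maximal
        edges <- rbind(edges, data.frame(protein1 = a, protein2 = b,
            stringsAsFactors = FALSE))
        nAdded <- nAdded + 1L
    }
    a <- pmin(edges$protein1, edges$protein2)
    b <- pmax(edges$protein1, edges$protein2)
    edges <- data.frame(protein1 = a, protein2 = b,
        stringsAsFactors = FALSE)
    edges <- edges[!duplicated(edges), , drop = FALSE]
    edges$combined_score <- as.integer(round(stats::runif(nrow(edges),
        400, 1000)))
    rownames(edges) <- NULL
    edges
}

#' Generate a term-to-gene annotation table with one planted enriched term
#'
#' The planted term annotates each gene of `targetSet` with probability
#' `insideRate` and every other gene with probability `backgroundRate`;
#' `nOtherTerms` decoy terms each annotate a uniformly random gene subset.
#'
#' @param orthologIds Gene universe.
#' @param termId,termName Planted term identity.
#' @param targetSet Genes the planted term should be enriched in (subset
#'   of `orthologIds`).
#' @param insideRate,backgroundRate Annotation probabilities in [0, 1]
#'   (defaults 0.9 and 0.05).
#' @param nOtherTerms Number of decoy terms (default 20).
#' @param seed Integer random seed.
#' @return Annotation `data.frame` (`term_id`, `term_name`, `gene_id`).
#' @export
generateAnnotations <- function(orthologIds, targetSet,
        termId = "TERM:0000001", termName = "planted process",
        insideRate = 0.9, backgroundRate = 0.05, nOtherTerms = 20L,
        seed = 1L) {
    if (!all(targetSet %in% orthologIds))
        stop("configuration error: 'targetSet' must be a subset of 'orthologIds'")
    if (insideRate < 0 || insideRate > 1 || backgroundRate < 0 ||
        backgroundRate > 1)
        stop("configuration error: rates must lie in [0, 1]")
    set.seed(seed)
    inTarget <- orthologIds %in% targetSet
    pr <- ifelse(inTarget, insideRate, backgroundRate)
    hit <- stats::runif(length(orthologIds)) < pr
    out <- data.frame(term_id = character(), term_name = character(),
        gene_id = character(), stringsAsFactors = FALSE)
    if (any(hit))
        out <- data.frame(term_id = termId, term_name = termName,
            gene_id = orthologIds[hit], stringsAsFactors = FALSE)
    if (nOtherTerms > 0L) {
        for (j in seq_len(nOtherTerms)) {
            size <- sample(5:50, 1L)
            size <- min(size, length(orthologIds))
            out <- rbind(out, data.frame(
                term_id = sprintf("TERM:%07d", j + 1L),
                term_name = sprintf("random process %d", j),
                gene_id = sample(orthologIds, size),
                stringsAsFactors = FALSE))
        }
    }
    rownames(out) <- NULL
    out
}

#' Write a synthetic community workspace to disk
#'
#' Writes per-species hit tables (`hits/<species>.tsv`, 12-column
#' tab-separated), `query_lengths.tsv`, `species_metadata.tsv`, a
#' STRING-style `edges.tsv` (header `protein1 protein2 combined_score`)
#' and `annotations.tsv`, ready for [runPipeline()].
#'
#' @param dir Output directory (created if needed).
#' @param config A [communityConfig()].
#' @param hubDegree,extraEdges Network shape (defaults 30 and 400).
#' @param nOtherTerms Decoy annotation terms (default 20).
#' @return Invisibly, the `generateCommunity()` result plus elements
#'   `edges`, `annotations` and `dir`.
#' @export
writeCommunity <- function(dir, config = communityConfig(),
        hubDegree = 30L, extraEdges = 400L, nOtherTerms = 20L) {
    com <- generateCommunity(config)
    gt <- com$groundTruth
    planted <- unlist(gt$exclusiveIdsByLevel, use.names = FALSE)
    moduleIds <- utils::head(planted, 8L)
    edges <- generateNetwork(rownames(gt$truePresence), hubDegree,
        moduleIds = moduleIds, extraEdges = extraEdges,
        seed = config$seed + 1L, hubId = gt$hubId)
    target <- utils::head(c(planted, gt$absentIds), 30L)
    ann <- generateAnnotations(rownames(gt$truePresence), target,
        termId = gt$enrichedTermId, nOtherTerms = nOtherTerms,
        seed = config$seed + 2L)
    dir.create(file.path(dir, "hits"), recursive = TRUE,
        showWarnings = FALSE)
    for (s in names(com$hitTables))
        utils::write.table(com$hitTables[[s]],
            file.path(dir, "hits", paste0(s, ".tsv")), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(
        data.frame(query_id = names(com$queryLengths),
            length = unname(com$queryLengths)),
        file.path(dir, "query_lengths.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    md <- com$speciesMetadata
    md$growth_form <- ifelse(md$growth_form == "focal", "liana", "non_liana")
    utils::write.table(md, file.path(dir, "species_metadata.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(c(com, list(edges = edges, annotations = ann, dir = dir)))
}
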