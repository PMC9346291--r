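#' @include AllClasses.R
NULL

.CONFIG_DEFAULTS <- list(
    evalue_max = 1e-9, query_cov_min = 0.9, min_score = 400L,
    n_shells = 2L, min_background_support = 1L, alpha = 0.05,
    exclude_core = TRUE, min_level = 2L, seed = 1L)

#' Validate a pipeline run configuration
#'
#' Reads a YAML run configuration, fills in documented defaults
#' (e-value ceiling 1e-9, query coverage 0.9, STRING score cutoff 400,
#' two interaction shells, background support 1, alpha 0.05) and checks
#' every constraint, reporting the complete list of violations rather
#' than only the first.
#'
#' Expected layout:
#' \preformatted{
#' paths:
#'   hits_dir: hits/            # one <species_id>.tsv per species
#'   query_lengths: query_lengths.tsv
#'   species_metadata: species_metadata.tsv
#'   edge_list: edges.tsv
#'   annotations: annotations.tsv
#'   output_dir: results/
#'   collapse_map: collapse.tsv # optional, species_id -> unit_id
#' thresholds:
#'   evalue_max: 1e-9
#'   query_cov_min: 0.9
#'   min_score: 400
#'   n_shells: 2
#'   min_background_support: 1
#'   alpha: 0.05
#' seed: 1
#' }
#'
#' @param path Path to the YAML configuration file, or a list with the
#'   same structure.
#' @return A validated configuration list of class `RunConfig`; on any
#'   violation an error is thrown whose message lists all of them.
#' @export
validateConfig <- function(path) {
    cfg <- if (is.list(path)) path
        else if (!file.exists(path)) stop("config file not found: ", path)
        else yaml::read_yaml(path)
    base <- if (is.list(path)) getwd() else dirname(normalizePath(path))
    errs <- character()
    paths <- cfg$paths
    if (is.null(paths)) {
        errs <- c(errs, "missing 'paths' section")
        paths <- list()
    }
    resolve <- function(p) if (is.null(p) || grepl("^/", p)) p
        else file.path(base, p)
    need <- c("hits_dir", "query_lengths", "species_metadata", "edge_list",
        "annotations", "output_dir")
    for (f in need)
        if (is.null(paths[[f]]))
            errs <- c(errs, sprintf("missing path '%s'", f))
    for (f in setdiff(need, "output_dir")) {
        p <- resolve(paths[[f]])
        if (!is.null(p) && !file.exists(p))
            errs <- c(errs, sprintf("path '%s' does not exist: %s", f, p))
        paths[[f]] <- p
    }
    if (!is.null(paths$collapse_map)) {
        paths$collapse_map <- resolve(paths$collapse_map)
        if (!file.exists(paths$collapse_map))
            errs <- c(errs, sprintf("path 'collapse_map' does not exist: %s",
                paths$collapse_map))
    }
    paths$output_dir <- resolve(paths$output_dir)
    th <- utils::modifyList(.CONFIG_DEFAULTS,
        c(cfg$thresholds, cfg["seed"][!vapply(cfg["seed"], is.null, TRUE)]))
    if (th$evalue_max <= 0)
        errs <- c(errs, "'evalue_max' must be > 0")
    if (th$query_cov_min <= 0 || th$query_cov_min > 1)
        errs <- c(errs, "'query_cov_min' must lie in (0, 1]")
    if (th$min_score < 0 || th$min_score > 1000)
        errs <- c(errs, "'min_score' must lie in [0, 1000]")
    if (th$n_shells < 0)
        errs <- c(errs, "'n_shells' must be >= 0")
    if (th$min_background_support < 1)
        errs <- c(errs, "'min_background_support' must be >= 1")
    if (th$alpha <= 0 || th$alpha > 1)
        errs <- c(errs, "'alpha' must lie in (0, 1]")
    if (th$min_level < 1)
        errs <- c(errs, "'min_level' must be >= 1")
    if (length(errs))
        stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
    structure(list(paths = paths, thresholds = th,
        seed = as.integer(th$seed)), class = "RunConfig")
}

.stageLog <- function(level, stage, fmt, ...) {
    if (identical(level, "quiet")) return(invisible())
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full convergence-analysis pipeline
#'
#' Executes the stages in order: ortholog mapping (parse, filter, best
#' hit, presence matrix), species collapsing and convergence
#' classification, seed-based subnetwork extraction for the exclusive
#' (level >= `min_level`) and group-absent compartments with merging,
#' sector annotation, hub ranking, and over-representation analysis of
#' both compartments. All outputs are written under
#' `config$paths$output_dir` and a JSON run manifest (timestamp, config
#' hash, package version, per-file record counts) is written last.
#' The pipeline is deterministic: identical configuration gives
#' byte-identical data outputs.
#'
#' Output files: `presence_matrix.tsv`, `classification.tsv`,
#' `membership_summary.tsv`, `network_merged.graphml`,
#' `network_merged.sif`, `network_nodes.tsv`, `degree_ranking.tsv`,
#' `enrichment_exclusive.tsv`, `enrichment_absent.tsv`,
#' `manifest.json`.
#'
#' @param config A `RunConfig` from [validateConfig()] (or a path/list
#'   accepted by it).
#' @param logLevel `"info"` (default) or `"quiet"`.
#' @return Invisibly, a list with `presence` ([PresenceMatrix-class]),
#'   `classification` ([ConvergenceClassification-class]), `network`
#'   (merged [InteractionNetwork-class]), `degreeRanking`,
#'   `enrichmentExclusive`, `enrichmentAbsent`, and `manifest`.
#' @export
runPipeline <- function(config, logLevel = c("info", "quiet")) {
    logLevel <- match.arg(logLevel)
    if (!inherits(config, "RunConfig"))
        config <- validateConfig(config)
    p <- config$paths; th <- config$thresholds
    dir.create(p$output_dir, recursive = TRUE, showWarnings = FALSE)
    outputs <- character()

    ## stage 1: ortholog mapping
    md <- readSpeciesMetadata(p$species_metadata)
    qlen <- readQueryLengths(p$query_lengths)
    files <- sort(list.files(p$hits_dir, pattern = "\\.tsv$",
        full.names = TRUE))
    if (!length(files))
        stop("stage mapping: no hit tables (*.tsv) in ", p$hits_dir)
    thr <- filterThresholds(th$evalue_max, th$query_cov_min)
    best <- list()
    for (f in files) {
        sp <- sub("\\.tsv$", "", basename(f))
        hits <- readHitTable(f)
        kept <- filterHits(hits, thr, qlen)
        best[[sp]] <- bestHitPerTranscript(kept)
        .stageLog(logLevel, "map", "%s: %d hits, %d pass filter, %d transcripts mapped",
            sp, nrow(hits), nrow(kept), length(best[[sp]]))
    }
    pm <- buildPresenceMatrix(best, md)
    .stageLog(logLevel, "map", "presence matrix: %d orthologs x %d species",
        nrow(pm), ncol(pm))

    ## stage 2: collapse + classification
    collapseMap <- NULL
    if (!is.null(p$collapse_map)) {
        cm <- utils::read.table(p$collapse_map, sep = "\t", header = TRUE,
            colClasses = "character")
        collapseMap <- stats::setNames(cm[[2L]], cm[[1L]])
    }
    pmU <- collapseSpecies(pm, collapseMap)
    cls <- classifyConvergence(pmU, excludeCore = th$exclude_core,
        minBackgroundSupport = th$min_background_support)
    summ <- membershipSummary(cls)
    .stageLog(logLevel, "classify",
        "core %d, exclusive L>=%d %d, absent %d",
        length(coreSet(cls)), th$min_level,
        sum(lengths(exclusiveSets(cls)[
            as.integer(names(exclusiveSets(cls))) >= th$min_level])),
        length(absentInGroup(cls)))

    ## stage 3: interactome
    net <- readStringEdges(p$edge_list, minScore = th$min_score)
    ex <- exclusiveSets(cls)
    exSeeds <- sort(unlist(ex[as.integer(names(ex)) >= th$min_level],
        use.names = FALSE))
    abSeeds <- absentInGroup(cls)
    catMap <- c(
        stats::setNames(rep(names(ex), lengths(ex)),
            unlist(ex, use.names = FALSE)),
        stats::setNames(rep("co_downregulated", length(abSeeds)), abSeeds))
    catMap[names(catMap) %in% unlist(ex, use.names = FALSE)] <-
        paste0("L", catMap[names(catMap) %in%
            unlist(ex, use.names = FALSE)])
    subs <- list()
    if (length(exSeeds))
        subs$exclusive <- suppressWarnings(extractSubnetwork(net, exSeeds,
            nShells = th$n_shells))
    if (length(abSeeds))
        subs$absent <- suppressWarnings(extractSubnetwork(net, abSeeds,
            nShells = th$n_shells))
    merged <- if (length(subs) == 2L)
        mergeNetworks(subs[[1L]], subs[[2L]])
        else if (length(subs) == 1L) subs[[1L]]
        else interactionNetwork(.emptyEdges())
    merged <- annotateSectors(merged, catMap)
    rank <- degreeRanking(merged)
    .stageLog(logLevel, "network", "merged subnetwork: %d nodes, %d edges",
        numNodes(merged), numEdges(merged))

    ## stage 4: enrichment
    ann <- readAnnotations(p$annotations)
    universe <- orthologIds(pmU)
    enrEx <- suppressWarnings(enrichTerms(exSeeds, ann, universe,
        alpha = th$alpha))
    enrAb <- suppressWarnings(enrichTerms(abSeeds, ann, universe,
        alpha = th$alpha))
    .stageLog(logLevel, "enrich",
        "exclusive: %d/%d terms significant; absent: %d/%d",
        sum(enrEx$significant), nrow(enrEx),
        sum(enrAb$significant), nrow(enrAb))

    ## outputs
    wr <- function(x, name) {
        path <- file.path(p$output_dir, name)
        utils::write.table(x, path, sep = "\t", quote = FALSE,
            row.names = FALSE)
        outputs <<- c(outputs, name)
        path
    }
    pmOut <- data.frame(ortholog_id = rownames(pmU),
        ifelse(presence(pmU), 1L, 0L), check.names = FALSE)
    wr(pmOut, "presence_matrix.tsv")
    clsTab <- .classificationTable(cls)
    wr(clsTab, "classification.tsv")
    wr(summ, "membership_summary.tsv")
    exportGraph(merged, file.path(p$output_dir, "network_merged.graphml"),
        "graphml")
    exportGraph(merged, file.path(p$output_dir, "network_merged.sif"),
        "sif")
    exportGraph(merged, file.path(p$output_dir, "network_nodes.tsv"),
        "node_table")
    outputs <- c(outputs, "network_merged.graphml", "network_merged.sif",
        "network_nodes.tsv")
    wr(rank, "degree_ranking.tsv")
    wr(enrEx, "enrichment_exclusive.tsv")
    wr(enrAb, "enrichment_absent.tsv")

    manifest <- .writeManifest(config, p$output_dir, outputs)
    .stageLog(logLevel, "done", "outputs in %s", p$output_dir)
    invisible(list(presence = pmU, classification = cls, network = merged,
        degreeRanking = rank, enrichmentExclusive = enrEx,
        enrichmentAbsent = enrAb, manifest = manifest))
}

.classificationTable <- function(cls) {
    ex <- exclusiveSets(cls)
    rows <- rbind(
        if (length(coreSet(cls))) data.frame(ortholog_id = coreSet(cls),
            category = "core", level = NA_integer_,
            stringsAsFactors = FALSE),
        do.call(rbind, lapply(names(ex), function(k)
            if (length(ex[[k]])) data.frame(ortholog_id = ex[[k]],
                category = "exclusive", level = as.integer(k),
                stringsAsFactors = FALSE))),
        if (length(absentInGroup(cls)))
            data.frame(ortholog_id = absentInGroup(cls),
                category = "absent_in_focal", level = NA_integer_,
                stringsAsFactors = FALSE))
    if (is.null(rows))
        rows <- data.frame(ortholog_id = character(),
            category = character(), level = integer(),
            stringsAsFactors = FALSE)
    rownames(rows) <- NULL
    rows
}

# manifest: timestamp, config hash, version, per-file record counts
.writeManifest <- function(config, outDir, outputs) {
    cfgFile <- tempfile()
    on.exit(unlink(cfgFile))
    writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE),
        cfgFile)
    counts <- vapply(outputs, function(f) {
        path <- file.path(outDir, f)
        if (grepl("\\.(tsv|sif)$", f))
            length(readLines(path)) -
                as.integer(grepl("\\.tsv$", f) & !grepl("^hits", f))
        else file.size(path)
    }, 0)
    manifest <- list(
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config_hash = unname(tools::md5sum(cfgFile)),
        package_version = as.character(utils::packageVersion("orthoconv")),
        seed = config$seed,
        outputs = as.list(counts))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE)
    manifest
}
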