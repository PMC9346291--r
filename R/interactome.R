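#' @include AllClasses.R
NULL

#' Load a STRING-style weighted edge list
#'
#' Reads a 3-column tab-separated edge list (`protein1`, `protein2`,
#' `combined_score` on the 0-1000 STRING confidence scale; a header line is
#' detected and skipped). Edges below `minScore` are discarded (boundary
#' inclusive: a score equal to `minScore` is kept), duplicate and reversed
#' pairs are collapsed keeping the maximum score, and self-loops are
#' dropped with a warning giving their count.
#'
#' @param path Path to the edge-list TSV.
#' @param minScore Minimum combined score to retain an edge; the default
#'   400 is the conventional STRING "medium confidence" cutoff.
#' @return An [InteractionNetwork-class].
#' @export
readStringEdges <- function(path, minScore = 400L) {
    if (!file.exists(path))
        stop("edge list not found: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!length(lines))
        return(interactionNetwork(.emptyEdges()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 3L))
        stop("edge list rows must have 3 tab-separated columns; first bad line: ",
            which(lengths(fields) < 3L)[1L])
    start <- 1L
    if (is.na(suppressWarnings(as.numeric(fields[[1L]][3L]))))
        start <- 2L  # header
    if (start > length(fields))
        return(interactionNetwork(.emptyEdges()))
    fields <- fields[start:length(fields)]
    score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (anyNA(score))
        stop("malformed combined_score at line ",
            which(is.na(score))[1L] + start - 1L, " of ", path)
    edges <- data.frame(
        protein1 = vapply(fields, `[`, "", 1L),
        protein2 = vapply(fields, `[`, "", 2L),
        combined_score = as.integer(score),
        stringsAsFactors = FALSE)
    nloop <- sum(edges$protein1 == edges$protein2)
    if (nloop > 0L)
        warning(nloop, " self-loop(s) dropped from ", path)
    edges <- edges[edges$combined_score >= minScore, , drop = FALSE]
    interactionNetwork(edges)
}

.emptyEdges <- function() data.frame(protein1 = character(),
    protein2 = character(), combined_score = integer(),
    stringsAsFactors = FALSE)

# breadth-first shell labelling from a seed set; returns a named integer
# vector of shells for all reached nodes within nShells
.bfsShells <- function(g, seeds, nShells) {
    adj <- igraph::as_adj_list(g, mode = "all")
    adj <- lapply(adj, function(v) igraph::V(g)$name[as.integer(v)])
    names(adj) <- igraph::V(g)$name
    shell <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
    frontier <- intersect(seeds, names(adj))
    shell[frontier] <- 0L
    d <- 0L
    while (length(frontier) && d < nShells) {
        nxt <- unique(unlist(adj[frontier], use.names = FALSE))
        nxt <- nxt[is.na(shell[nxt])]
        d <- d + 1L
        shell[nxt] <- d
        frontier <- nxt
    }
    shell[!is.na(shell)]
}

#' Extract a seed-based subnetwork with shell expansion
#'
#' Starting from a set of seed nodes (shell 0), includes every node within
#' `nShells` unweighted shortest-path steps of the seed set — the first
#' and second interaction shells for the default `nShells = 2`.
#' Each retained node is annotated with its shell index (its BFS distance
#' to the seed set). Seeds absent from the network are retained as
#' isolated shell-0 nodes with a warning, so that classified orthologs
#' without interaction evidence remain visible in exports.
#'
#' @param net An [InteractionNetwork-class].
#' @param seeds Non-empty character vector of seed node ids.
#' @param nShells Number of expansion shells (>= 0); default 2.
#' @param shellEdges `"induced"` (default) keeps every network edge whose
#'   two endpoints are retained, including edges internal to the outermost
#'   shell; `"tree"` keeps only edges linking consecutive shells.
#' @return An [InteractionNetwork-class]; node attribute `shell` holds the
#'   shell index, node categories are carried over.
#' @export
extractSubnetwork <- function(net, seeds, nShells = 2L,
        shellEdges = c("induced", "tree")) {
    shellEdges <- match.arg(shellEdges)
    if (length(seeds) == 0L)
        stop("'seeds' must be non-empty")
    if (nShells < 0L)
        stop("'nShells' must be >= 0")
    seeds <- unique(seeds)
    g <- net@graph
    known <- if (igraph::vcount(g)) igraph::V(g)$name else character()
    orphan <- setdiff(seeds, known)
    if (length(orphan))
        warning(length(orphan),
            " seed(s) absent from the network kept as isolated nodes")
    shell <- .bfsShells(g, seeds, nShells)
    sub <- igraph::induced_subgraph(g, names(shell))
    igraph::V(sub)$shell <- unname(shell[igraph::V(sub)$name])
    if (shellEdges == "tree" && igraph::ecount(sub) > 0L) {
        el <- igraph::as_edgelist(sub)
        lvl <- stats::setNames(igraph::V(sub)$shell, igraph::V(sub)$name)
        keep <- abs(lvl[el[, 1L]] - lvl[el[, 2L]]) == 1L
        sub <- igraph::delete_edges(sub, igraph::E(sub)[!keep])
    }
    if (length(orphan)) {
        sub <- igraph::add_vertices(sub, length(orphan), name = orphan,
            category = "shell_interactor", shell = 0L)
    }
    .asInteractionNetwork(sub)
}

#' Annotate network nodes with sector categories
#'
#' Assigns category labels (for instance `"L2"` ... `"L5"` for
#' liana-exclusive convergence levels or `"co_downregulated"` for the
#' group-absent compartment) to network nodes; unlabeled nodes default to
#' `"shell_interactor"`.
#'
#' @param net An [InteractionNetwork-class].
#' @param categoryMap Named character vector: node id -> category label.
#'   Ids absent from the network are ignored.
#' @return The annotated [InteractionNetwork-class].
#' @export
annotateSectors <- function(net, categoryMap) {
    g <- net@graph
    if (igraph::vcount(g) == 0L) return(net)
    cat <- rep("shell_interactor", igraph::vcount(g))
    if (length(categoryMap)) {
        idx <- match(igraph::V(g)$name, names(categoryMap))
        cat[!is.na(idx)] <- unname(categoryMap[idx[!is.na(idx)]])
    }
    igraph::V(g)$category <- cat
    methods::new("InteractionNetwork", graph = g)
}

# join two category labels into a sorted multi-label
.joinCategories <- function(a, b) {
    vapply(seq_along(a), function(i) {
        parts <- unique(c(strsplit(a[i], "+", fixed = TRUE)[[1L]],
            strsplit(b[i], "+", fixed = TRUE)[[1L]]))
        parts <- setdiff(parts, "shell_interactor")
        if (!length(parts)) "shell_interactor"
        else paste(sort(parts), collapse = "+")
    }, "")
}

#' Merge two interaction networks
#'
#' Graph union: the node set is the union of both node sets and the edge
#' set the union of both edge sets, keeping the maximum combined score for
#' edges present in both. Conflicting node categories are joined into a
#' sorted multi-label (`"L2+co_downregulated"`); shells take the minimum
#' of the two (the distance to the union of the seed sets is at most the
#' smaller of the two distances). Merging is commutative and idempotent.
#'
#' @param a,b [InteractionNetwork-class] objects.
#' @return The merged [InteractionNetwork-class].
#' @export
mergeNetworks <- function(a, b) {
    na <- networkNodes(a); nb <- networkNodes(b)
    ea <- networkEdges(a); eb <- networkEdges(b)
    edges <- rbind(ea, eb)
    ids <- sort(unique(c(na$node, nb$node)))
    net <- interactionNetwork(edges, nodes = ids)
    g <- net@graph
    ia <- match(igraph::V(g)$name, na$node)
    ib <- match(igraph::V(g)$name, nb$node)
    ca <- ifelse(is.na(ia), "shell_interactor", na$category[ia])
    cb <- ifelse(is.na(ib), "shell_interactor", nb$category[ib])
    igraph::V(g)$category <- .joinCategories(ca, cb)
    sa <- ifelse(is.na(ia), NA_integer_, na$shell[ia])
    sb <- ifelse(is.na(ib), NA_integer_, nb$shell[ib])
    igraph::V(g)$shell <- pmin(sa, sb, na.rm = TRUE)
    methods::new("InteractionNetwork", graph = g)
}

#' Rank network nodes by degree
#'
#' Degree counts distinct neighbours (the graph is simple). Ties are
#' broken by node id, ascending, so the ranking is deterministic.
#'
#' @param net An [InteractionNetwork-class].
#' @param topN Number of top nodes to report (default: all).
#' @return `data.frame` with columns `node`, `degree`, sorted by degree
#'   descending then node id; empty for an empty network.
#' @export
degreeRanking <- function(net, topN = Inf) {
    if (topN < 1)
        stop("'topN' must be >= 1")
    g <- net@graph
    if (igraph::vcount(g) == 0L)
        return(data.frame(node = character(), degree = integer(),
            stringsAsFactors = FALSE))
    d <- igraph::degree(g)
    out <- data.frame(node = names(d), degree = as.integer(d),
        stringsAsFactors = FALSE)
    out <- out[order(-out$degree, out$node), , drop = FALSE]
    rownames(out) <- NULL
    utils::head(out, topN)
}

#' Fraction of the reference gene space covered by a network
#'
#' `100 * nodes / proteome size`, the statistic behind the observation
#' that a 3835-node interactome occupies a little over 11% of the
#' grapevine gene space (33,568 protein-coding genes).
#'
#' @param net An [InteractionNetwork-class], or directly a node count.
#' @param proteomeSize Number of protein-coding genes in the reference
#'   (> 0).
#' @return Percentage in [0, 100] (can exceed 100 if the network holds
#'   ids outside the reference).
#' @examples
#' coverageFraction(3835, 33568)  # 11.42
#' @export
coverageFraction <- function(net, proteomeSize) {
    if (!is.numeric(proteomeSize) || length(proteomeSize) != 1L ||
        proteomeSize <= 0)
        stop("'proteomeSize' must be a single positive number")
    n <- if (methods::is(net, "InteractionNetwork")) numNodes(net)
        else as.numeric(net)
    100 * n / proteomeSize
}

#' Export a network to file
#'
#' Formats: `graphml` (full round trip of nodes, edges, scores, categories
#' and shells; readable by Cytoscape and igraph), `sif` (Cytoscape simple
#' interaction format, `A pp B` per edge, bare node id per isolated node),
#' `node_table` (TSV of node, category, shell).
#'
#' @param net An [InteractionNetwork-class].
#' @param path Output file path.
#' @param format One of `"graphml"`, `"sif"`, `"node_table"`.
#' @return `path`, invisibly.
#' @export
exportGraph <- function(net, path, format = c("graphml", "sif", "node_table")) {
    format <- match.arg(format)
    if (format == "graphml") {
        g <- net@graph
        # GraphML booleans/NA round-trip poorly; encode shell NA as -1
        sh <- igraph::V(g)$shell
        sh[is.na(sh)] <- -1L
        igraph::V(g)$shell <- as.numeric(sh)
        igraph::write_graph(g, path, format = "graphml")
    } else if (format == "sif") {
        ed <- networkEdges(net)
        nd <- networkNodes(net)
        iso <- setdiff(nd$node, c(ed$protein1, ed$protein2))
        writeLines(c(sprintf("%s pp %s", ed$protein1, ed$protein2), iso),
            path)
    } else {
        utils::write.table(networkNodes(net), path, sep = "\t",
            quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Import a network written by [exportGraph()]
#'
#' Only the `graphml` format is lossless; `sif` recovers topology with
#' unit scores.
#'
#' @param path File path.
#' @param format `"graphml"` or `"sif"`.
#' @return An [InteractionNetwork-class].
#' @export
importGraph <- function(path, format = c("graphml", "sif")) {
    format <- match.arg(format)
    if (format == "graphml") {
        g <- igraph::read_graph(path, format = "graphml")
        if (igraph::vcount(g) > 0 && !is.null(igraph::V(g)$shell)) {
            sh <- as.integer(igraph::V(g)$shell)
            sh[sh < 0L] <- NA_integer_
            igraph::V(g)$shell <- sh
        }
        if (igraph::ecount(g) > 0)
            igraph::E(g)$combined_score <-
                as.integer(igraph::E(g)$combined_score)
        if (!is.null(igraph::graph_attr(g, "id")))
            g <- igraph::delete_graph_attr(g, "id")
        .asInteractionNetwork(g)
    } else {
        lines <- readLines(path)
        lines <- lines[nzchar(lines)]
        parts <- strsplit(lines, " ", fixed = TRUE)
        isEdge <- lengths(parts) >= 3L
        edges <- data.frame(
            protein1 = vapply(parts[isEdge], `[`, "", 1L),
            protein2 = vapply(parts[isEdge], `[`, "", 3L),
            combined_score = 1000L, stringsAsFactors = FALSE)
        interactionNetwork(edges,
            nodes = vapply(parts[!isEdge], `[`, "", 1L))
    }
}
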