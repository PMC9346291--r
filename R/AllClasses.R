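#' @include AllGenerics.R
NULL

#' PresenceMatrix: species-by-ortholog detection matrix
#'
#' A `SummarizedExperiment` subclass holding a single logical assay
#' `"presence"` with reference orthologs as rows and species analysis units
#' as columns. `colData` carries the per-unit `growth_form` label
#' (`"focal"` = the convergent growth form under study, e.g. lianas;
#' `"background"` = free-standing comparators) and an optional
#' `collapse_group` used by [collapseSpecies()].
#'
#' @seealso [buildPresenceMatrix()], [classifyConvergence()]
#' @export
setClass("PresenceMatrix", contains = "SummarizedExperiment")

setValidity("PresenceMatrix", function(object) {
    msg <- character()
    if (!"presence" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'presence' is missing")
    else {
        a <- SummarizedExperiment::assay(object, "presence")
        if (!is.logical(a))
            msg <- c(msg, "assay 'presence' must be a logical matrix")
        if (anyNA(a))
            msg <- c(msg, "assay 'presence' must not contain NA")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"growth_form" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'growth_form' column")
    else if (!all(cd$growth_form %in% c("focal", "background")))
        msg <- c(msg, "growth_form labels must be 'focal' or 'background'")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "unit ids (column names) must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "ortholog ids (row names) must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a PresenceMatrix
#'
#' @param present Logical matrix, orthologs in rows, species units in
#'   columns; dimnames required.
#' @param growthForm Character vector of `"focal"`/`"background"` labels,
#'   one per column of `present` (recycled from a named vector by column
#'   name if named).
#' @param collapseGroup Optional character vector of collapse-unit ids
#'   (see [collapseSpecies()]); defaults to each unit being its own group.
#' @return A [PresenceMatrix-class].
#' @examples
#' m <- matrix(c(TRUE, FALSE, TRUE, TRUE), nrow = 2,
#'             dimnames = list(c("VIT_01", "VIT_02"), c("spA", "spB")))
#' pm <- PresenceMatrix(m, growthForm = c("focal", "background"))
#' presence(pm)
#' @export
PresenceMatrix <- function(present, growthForm, collapseGroup = NULL) {
    if (!is.matrix(present) || !is.logical(present))
        stop("'present' must be a logical matrix")
    if (is.null(rownames(present)) || is.null(colnames(present)))
        stop("'present' must have ortholog row names and unit column names")
    if (!is.null(names(growthForm)))
        growthForm <- growthForm[colnames(present)]
    if (length(growthForm) != ncol(present))
        stop("'growthForm' must supply one label per unit")
    if (is.null(collapseGroup))
        collapseGroup <- colnames(present)
    cd <- S4Vectors::DataFrame(
        growth_form = as.character(growthForm),
        collapse_group = as.character(collapseGroup),
        row.names = colnames(present))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(presence = present), colData = cd)
    methods::new("PresenceMatrix", se)
}

#' @rdname presence
#' @export
setMethod("presence", "PresenceMatrix", function(x)
    SummarizedExperiment::assay(x, "presence"))

#' @rdname growthForm
#' @export
setMethod("growthForm", "PresenceMatrix", function(x) {
    gf <- SummarizedExperiment::colData(x)$growth_form
    names(gf) <- colnames(x)
    gf
})

#' @rdname orthologIds
#' @export
setMethod("orthologIds", "PresenceMatrix", function(x) rownames(x))

#' @rdname unitIds
#' @export
setMethod("unitIds", "PresenceMatrix", function(x) colnames(x))

setMethod("show", "PresenceMatrix", function(object) {
    gf <- growthForm(object)
    cat(sprintf(
        "PresenceMatrix: %d orthologs x %d units (%d focal, %d background)\n",
        nrow(object), ncol(object),
        sum(gf == "focal"), sum(gf == "background")))
    cat(sprintf("  detections: %d cells TRUE (%.1f%%)\n",
        sum(presence(object)),
        100 * mean(presence(object))))
})

#' ConvergenceClassification: core / exclusive / absent partition
#'
#' Result object of [classifyConvergence()]. Slots hold the common core
#' (present in every unit), the per-convergence-level group-exclusive sets
#' (level k = present in exactly k focal units and no background unit),
#' and the group-absent ("co-downregulated") set (no focal presence,
#' sufficient background support). The three compartments are pairwise
#' disjoint by construction; orthologs in none of them are "mixed".
#'
#' @slot core character: ortholog ids present in all units.
#' @slot exclusiveByLevel named list of character vectors, names `"1"` ...
#'   up to the focal unit count.
#' @slot absentInFocal character: ids absent from all focal units.
#' @slot universe character: all ortholog ids of the classified matrix.
#' @slot focalUnitCount,backgroundUnitCount integer unit counts after any
#'   collapsing.
#' @slot minBackgroundSupport integer support threshold used for the
#'   absent set.
#' @export
setClass("ConvergenceClassification",
    representation(
        core = "character",
        exclusiveByLevel = "list",
        absentInFocal = "character",
        universe = "character",
        focalUnitCount = "integer",
        backgroundUnitCount = "integer",
        minBackgroundSupport = "integer"))

setValidity("ConvergenceClassification", function(object) {
    msg <- character()
    ex <- object@exclusiveByLevel
    if (length(ex)) {
        lv <- suppressWarnings(as.integer(names(ex)))
        if (anyNA(lv) || any(lv < 1L) || any(lv > object@focalUnitCount))
            msg <- c(msg, "exclusive levels must be integers in 1..focalUnitCount")
    }
    sets <- c(list(core = object@core, absent = object@absentInFocal), ex)
    all_ids <- unlist(sets, use.names = FALSE)
    if (anyDuplicated(all_ids))
        msg <- c(msg, "core, exclusive levels and absent sets must be pairwise disjoint")
    if (!all(all_ids %in% object@universe))
        msg <- c(msg, "classified ids must belong to the universe")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ConvergenceClassification", function(object) {
    cat(sprintf(
        "ConvergenceClassification: %d focal + %d background units, universe %d\n",
        object@focalUnitCount, object@backgroundUnitCount,
        length(object@universe)))
    cat(sprintf("  core: %d\n", length(object@core)))
    for (k in names(object@exclusiveByLevel))
        cat(sprintf("  exclusive L%s: %d\n", k,
            length(object@exclusiveByLevel[[k]])))
    cat(sprintf("  absent in focal group: %d (background support >= %d)\n",
        length(object@absentInFocal), object@minBackgroundSupport))
})

#' InteractionNetwork: weighted undirected protein-protein graph
#'
#' Wraps a simple undirected igraph graph. Edges carry an integer
#' `combined_score` on the STRING 0-1000 confidence scale; nodes carry an
#' optional `category` label (sector: `"L2"` ... , `"co_downregulated"`,
#' `"shell_interactor"`) and an optional `shell` index (unweighted
#' shortest-path distance to the seed set of the extraction that produced
#' the node, `NA` if never extracted).
#'
#' @slot graph an igraph object (undirected, simple).
#' @seealso [readStringEdges()], [extractSubnetwork()], [mergeNetworks()]
#' @export
setClass("InteractionNetwork", representation(graph = "ANY"))

setValidity("InteractionNetwork", function(object) {
    g <- object@graph
    msg <- character()
    if (!igraph::is_igraph(g))
        return("slot 'graph' must be an igraph object")
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (!igraph::is_simple(g))
        msg <- c(msg, "graph must be simple (no loops or multi-edges)")
    if (is.null(igraph::V(g)$name))
        msg <- c(msg, "vertices must be named")
    if (igraph::ecount(g) > 0) {
        sc <- igraph::E(g)$combined_score
        if (is.null(sc) || anyNA(sc) || any(sc < 0) || any(sc > 1000))
            msg <- c(msg, "edge attribute 'combined_score' must lie in [0, 1000]")
    }
    if (length(msg)) msg else TRUE
})

# internal constructor from an igraph graph; fills in missing attributes
.asInteractionNetwork <- function(g) {
    if (igraph::vcount(g) > 0) {
        if (is.null(igraph::V(g)$category))
            igraph::V(g)$category <- "shell_interactor"
        if (is.null(igraph::V(g)$shell))
            igraph::V(g)$shell <- NA_integer_
    }
    methods::new("InteractionNetwork", graph = g)
}

#' Construct an InteractionNetwork from tables
#'
#' @param edges `data.frame` with columns `protein1`, `protein2`,
#'   `combined_score` (integer 0-1000). Self-loops are dropped; reversed
#'   duplicates are collapsed keeping the maximum score.
#' @param nodes Optional character vector of node ids to include even when
#'   isolated (edge endpoints are always included).
#' @return An [InteractionNetwork-class].
#' @examples
#' net <- interactionNetwork(data.frame(
#'     protein1 = "VIT_A", protein2 = "VIT_B", combined_score = 900L))
#' networkEdges(net)
#' @export
interactionNetwork <- function(edges, nodes = NULL) {
    if (nrow(edges) > 0) {
        keep <- edges$protein1 != edges$protein2
        edges <- edges[keep, , drop = FALSE]
        a <- pmin(edges$protein1, edges$protein2)
        b <- pmax(edges$protein1, edges$protein2)
        key <- paste(a, b, sep = "\r")
        sc <- tapply(as.integer(edges$combined_score), key, max)
        parts <- strsplit(names(sc), "\r", fixed = TRUE)
        edges <- data.frame(
            protein1 = vapply(parts, `[`, "", 1L),
            protein2 = vapply(parts, `[`, "", 2L),
            combined_score = as.integer(sc),
            stringsAsFactors = FALSE)
        edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
    }
    ids <- sort(unique(c(edges$protein1, edges$protein2, nodes)))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
        vertices = if (length(ids)) data.frame(name = ids) else NULL)
    .asInteractionNetwork(g)
}

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "InteractionNetwork", function(x) {
    g <- x@graph
    if (igraph::vcount(g) == 0)
        return(data.frame(node = character(), category = character(),
            shell = integer(), stringsAsFactors = FALSE))
    data.frame(node = igraph::V(g)$name,
        category = igraph::V(g)$category,
        shell = as.integer(igraph::V(g)$shell),
        stringsAsFactors = FALSE)
})

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x) {
    g <- x@graph
    if (igraph::ecount(g) == 0)
        return(data.frame(protein1 = character(), protein2 = character(),
            combined_score = integer(), stringsAsFactors = FALSE))
    el <- igraph::as_edgelist(g)
    out <- data.frame(
        protein1 = pmin(el[, 1], el[, 2]),
        protein2 = pmax(el[, 1], el[, 2]),
        combined_score = as.integer(igraph::E(g)$combined_score),
        stringsAsFactors = FALSE)
    out <- out[order(out$protein1, out$protein2), , drop = FALSE]
    rownames(out) <- NULL
    out
})

#' @rdname numNodes
#' @export
setMethod("numNodes", "InteractionNetwork", function(x)
    igraph::vcount(x@graph))

#' @rdname numEdges
#' @export
setMethod("numEdges", "InteractionNetwork", function(x)
    igraph::ecount(x@graph))

#' @rdname orthologIds
#' @export
setMethod("orthologIds", "InteractionNetwork", function(x) {
    if (igraph::vcount(x@graph) == 0) character() else igraph::V(x@graph)$name
})

setMethod("show", "InteractionNetwork", function(object) {
    cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
        numNodes(object), numEdges(object)))
    nd <- networkNodes(object)
    if (nrow(nd)) {
        tab <- table(nd$category)
        cat("  categories:",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    }
})
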