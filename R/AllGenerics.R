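#' Extract the logical presence assay
#'
#' @param x A [PresenceMatrix-class].
#' @return Logical matrix, orthologs in rows, species units in columns.
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' Per-unit growth-form labels
#'
#' @param x A [PresenceMatrix-class].
#' @return Character vector, one of `"focal"` or `"background"` per unit.
#' @export
setGeneric("growthForm", function(x) standardGeneric("growthForm"))

#' Ortholog identifiers of an object
#'
#' @param x A [PresenceMatrix-class] or [InteractionNetwork-class].
#' @return Character vector of ortholog ids.
#' @export
setGeneric("orthologIds", function(x) standardGeneric("orthologIds"))

#' Species/unit identifiers
#'
#' @param x A [PresenceMatrix-class].
#' @return Character vector of unit ids.
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' Node table of a network
#'
#' @param x An [InteractionNetwork-class].
#' @return `data.frame` with columns `node`, `category`, `shell`.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge table of a network
#'
#' @param x An [InteractionNetwork-class].
#' @return `data.frame` with columns `protein1`, `protein2`, `combined_score`.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Number of nodes in a network
#' @param x An [InteractionNetwork-class].
#' @return Integer count.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges in a network
#' @param x An [InteractionNetwork-class].
#' @return Integer count.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Core ortholog set
#'
#' Orthologs detected in every analysis unit of the community.
#'
#' @param x A [PresenceMatrix-class] or [ConvergenceClassification-class].
#' @return Character vector of ortholog ids (sorted).
#' @export
setGeneric("coreSet", function(x) standardGeneric("coreSet"))

#' Group-exclusive ortholog sets by convergence level
#'
#' Level-k orthologs are present in exactly k focal units and in no
#' background unit.
#'
#' @param x A [PresenceMatrix-class] or [ConvergenceClassification-class].
#' @param ... Further arguments (`excludeCore` for matrices).
#' @return Named list, one character vector per level `1..nFocalUnits`.
#' @export
setGeneric("exclusiveSets", function(x, ...) standardGeneric("exclusiveSets"))

#' Group-absent (co-downregulated) ortholog set
#'
#' Orthologs with no focal-unit presence and at least
#' `minBackgroundSupport` background presences.
#'
#' @param x A [PresenceMatrix-class] or [ConvergenceClassification-class].
#' @param ... Further arguments (`minBackgroundSupport` for matrices).
#' @return Character vector of ortholog ids (sorted).
#' @export
setGeneric("absentInGroup", function(x, ...) standardGeneric("absentInGroup"))

#' Tabulate a convergence classification
#'
#' @param x A [ConvergenceClassification-class].
#' @return `data.frame` with columns `category`, `level`, `count`.
#' @export
setGeneric("membershipSummary", function(x) standardGeneric("membershipSummary"))
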