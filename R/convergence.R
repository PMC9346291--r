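#' @include AllClasses.R
NULL

.focalMask <- function(pm) growthForm(pm) == "focal"

#' Collapse species into analysis units
#'
#' Congeneric taxa (for instance two Smilax species) can be merged into a
#' single analysis unit before classification: the unit's presence row is
#' the element-wise OR of its members' rows and the growth form is
#' inherited. All members of a unit must share a growth form.
#'
#' @param pm A [PresenceMatrix-class].
#' @param collapseMap Named character vector mapping each species id to its
#'   unit id. If `NULL` (default) the matrix's own `collapse_group` column
#'   is used; an identity map leaves the matrix unchanged (up to column
#'   order, which follows first appearance).
#' @return A [PresenceMatrix-class] with one column per unit.
#' @export
collapseSpecies <- function(pm, collapseMap = NULL) {
    if (is.null(collapseMap)) {
        collapseMap <- SummarizedExperiment::colData(pm)$collapse_group
        names(collapseMap) <- colnames(pm)
    }
    missing <- setdiff(colnames(pm), names(collapseMap))
    if (length(missing))
        stop("collapse map misses species: ", paste(missing, collapse = ", "))
    unit <- unname(collapseMap[colnames(pm)])
    units <- unique(unit)
    gf <- growthForm(pm)
    m <- presence(pm)
    out <- matrix(FALSE, nrow = nrow(m), ncol = length(units),
        dimnames = list(rownames(m), units))
    ugf <- character(length(units))
    for (i in seq_along(units)) {
        members <- which(unit == units[i])
        forms <- unique(gf[members])
        if (length(forms) != 1L)
            stop("unit '", units[i], "' mixes growth forms: ",
                paste(forms, collapse = ", "))
        ugf[i] <- forms
        out[, i] <- rowSums(m[, members, drop = FALSE]) > 0L
    }
    PresenceMatrix(out, growthForm = ugf)
}

#' @describeIn coreSet Orthologs present in every unit of the matrix.
#' @export
setMethod("coreSet", "PresenceMatrix", function(x) {
    if (ncol(x) == 0L) stop("presence matrix has no units")
    m <- presence(x)
    sort(rownames(m)[rowSums(m) == ncol(m)])
})

#' @describeIn exclusiveSets Level-k set = orthologs present in exactly k
#'   focal units and in no background unit, for k = 1 .. number of focal
#'   units. Level 1 (a single focal unit) is reported like any other level
#'   but convergence proper starts at level 2. With `excludeCore = TRUE`
#'   (default) core orthologs are removed first — vacuous whenever a
#'   background unit exists, applied for safety.
#' @param excludeCore Remove the core set before the exclusivity scan.
#' @export
setMethod("exclusiveSets", "PresenceMatrix",
    function(x, excludeCore = TRUE) {
    foc <- .focalMask(x)
    if (!any(foc))
        stop("presence matrix has no focal units")
    if (!any(!foc))
        stop("presence matrix has no background units")
    m <- presence(x)
    if (excludeCore)
        m <- m[!(rownames(m) %in% coreSet(x)), , drop = FALSE]
    nf <- rowSums(m[, foc, drop = FALSE])
    nb <- rowSums(m[, !foc, drop = FALSE])
    levels <- seq_len(sum(foc))
    out <- lapply(levels, function(k)
        sort(rownames(m)[nf == k & nb == 0L]))
    names(out) <- as.character(levels)
    out
})

#' @describeIn absentInGroup Orthologs with zero focal presences and at
#'   least `minBackgroundSupport` background presences — the
#'   "co-downregulated" compartment: genes most likely carried by the focal
#'   genomes but not detectably transcribed.
#' @param minBackgroundSupport Minimum number of background units that must
#'   show the ortholog (default 1: presence in any background unit
#'   suffices).
#' @export
setMethod("absentInGroup", "PresenceMatrix",
    function(x, minBackgroundSupport = 1L) {
    if (minBackgroundSupport < 1L)
        stop("'minBackgroundSupport' must be >= 1")
    foc <- .focalMask(x)
    m <- presence(x)
    nf <- rowSums(m[, foc, drop = FALSE])
    nb <- rowSums(m[, !foc, drop = FALSE])
    sort(rownames(m)[nf == 0L & nb >= minBackgroundSupport])
})

#' Classify orthologs into core, exclusive and absent compartments
#'
#' Runs [coreSet()], [exclusiveSets()] and [absentInGroup()] on a (possibly
#' collapsed) presence matrix and bundles the result. The compartments are
#' pairwise disjoint; orthologs in none of them (present in some units of
#' both groups, but not all) form the residual "mixed" category.
#'
#' @param pm A [PresenceMatrix-class] (collapse species first if desired).
#' @param excludeCore Passed to [exclusiveSets()].
#' @param minBackgroundSupport Passed to [absentInGroup()].
#' @return A [ConvergenceClassification-class].
#' @export
classifyConvergence <- function(pm, excludeCore = TRUE,
        minBackgroundSupport = 1L) {
    gf <- growthForm(pm)
    methods::new("ConvergenceClassification",
        core = coreSet(pm),
        exclusiveByLevel = exclusiveSets(pm, excludeCore = excludeCore),
        absentInFocal = absentInGroup(pm,
            minBackgroundSupport = minBackgroundSupport),
        universe = rownames(pm),
        focalUnitCount = sum(gf == "focal"),
        backgroundUnitCount = sum(gf == "background"),
        minBackgroundSupport = as.integer(minBackgroundSupport))
}

#' @rdname coreSet
#' @export
setMethod("coreSet", "ConvergenceClassification", function(x) x@core)

#' @rdname exclusiveSets
#' @export
setMethod("exclusiveSets", "ConvergenceClassification",
    function(x, ...) x@exclusiveByLevel)

#' @rdname absentInGroup
#' @export
setMethod("absentInGroup", "ConvergenceClassification",
    function(x, ...) x@absentInFocal)

#' @describeIn membershipSummary One row per category/level with its set
#'   size; the `mixed` row counts the residual orthologs in no compartment.
#' @export
setMethod("membershipSummary", "ConvergenceClassification", function(x) {
    ex <- x@exclusiveByLevel
    rows <- data.frame(
        category = c("core",
            rep("exclusive", length(ex)),
            "absent_in_focal", "mixed"),
        level = c(NA_integer_, as.integer(names(ex)), NA_integer_,
            NA_integer_),
        count = c(length(x@core), lengths(ex), length(x@absentInFocal),
            length(x@universe) - length(x@core) -
                sum(lengths(ex)) - length(x@absentInFocal)),
        stringsAsFactors = FALSE)
    rownames(rows) <- NULL
    rows
})

#' Compare one focal unit against one background unit
#'
#' Used for within-family contrasts where a family contributes both a
#' liana and a non-liana member: splits the union of the two units'
#' orthologs into focal-only, background-only and shared sets (a disjoint
#' partition of the union).
#'
#' @param pm A [PresenceMatrix-class].
#' @param focalUnit,backgroundUnit Unit (column) ids.
#' @return List with character vectors `focal_only`, `background_only`,
#'   `shared`.
#' @export
pairwiseFamilyCompare <- function(pm, focalUnit, backgroundUnit) {
    for (u in c(focalUnit, backgroundUnit))
        if (!u %in% colnames(pm))
            stop("unknown unit id: ", u)
    m <- presence(pm)
    a <- rownames(m)[m[, focalUnit]]
    b <- rownames(m)[m[, backgroundUnit]]
    list(focal_only = sort(setdiff(a, b)),
        background_only = sort(setdiff(b, a)),
        shared = sort(intersect(a, b)))
}
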