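#' @include AllClasses.R
NULL

.HIT_COLS <- c("query_id", "subject_id", "percent_identity", "align_length",
    "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
    "evalue", "bitscore")
.HIT_NUMERIC <- .HIT_COLS[3:12]

#' Filter thresholds for hit-table filtering
#'
#' The reference pipeline selects top hits at an expectation-value ceiling
#' of 1e-9 and a minimum query coverage of 0.9; both boundaries are
#' inclusive (`evalue <= evalueMax`, `coverage >= queryCovMin`).
#'
#' @param evalueMax Expectation-value ceiling (> 0). Default `1e-9`.
#' @param queryCovMin Minimum fraction of the query covered by the
#'   alignment, in (0, 1]. Default `0.9`.
#' @return A named list of class `FilterThresholds`.
#' @export
filterThresholds <- function(evalueMax = 1e-9, queryCovMin = 0.9) {
    if (!is.numeric(evalueMax) || length(evalueMax) != 1L || evalueMax <= 0)
        stop("'evalueMax' must be a single positive number")
    if (!is.numeric(queryCovMin) || length(queryCovMin) != 1L ||
        queryCovMin <= 0 || queryCovMin > 1)
        stop("'queryCovMin' must lie in (0, 1]")
    structure(list(evalueMax = evalueMax, queryCovMin = queryCovMin),
        class = "FilterThresholds")
}

#' Read a 12-column tabular sequence-search hit table
#'
#' Parses the standard 12-column tab-separated alignment format
#' (query, subject, % identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, e-value, bit score). Subject-strand hits with
#' reversed query coordinates are normalised so that `qstart <= qend`. An
#' optional 13th column is read as a full-length flag (`1`/`0` or
#' `TRUE`/`FALSE`); when present and `dropPartial = TRUE`, transcripts not
#' flagged full-length are dropped before anything else.
#'
#' @param path Path to the tab-separated hit table (may be empty or
#'   header-less; lines starting with `#` are skipped).
#' @param strict If `TRUE` malformed rows abort with the offending line
#'   number; if `FALSE` (default) they are dropped with one warning per file.
#' @param dropPartial Drop rows whose full-length flag (column 13, if
#'   present) is false. Default `TRUE`.
#' @return `data.frame` of hits, one row per alignment, columns
#'   `query_id`, `subject_id`, `percent_identity`, `align_length`,
#'   `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`; row order preserved.
#' @export
readHitTable <- function(path, strict = FALSE, dropPartial = TRUE) {
    if (!file.exists(path))
        stop("hit table not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines))
        return(.emptyHits())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- nf < 12L
    parsed <- matrix(NA_real_, nrow = length(lines), ncol = 10L)
    if (any(!bad)) {
        raw <- t(vapply(fields[!bad], function(f) f[3:12], character(10L)))
        suppressWarnings(storage.mode(raw) <- "double")
        parsed[!bad, ] <- raw
    }
    bad <- bad | apply(parsed, 1L, anyNA)
    if (any(bad)) {
        where <- paste(utils::head(lineno[bad], 5L), collapse = ", ")
        msg <- sprintf("%d malformed row(s) in %s (lines %s%s)",
            sum(bad), path, where, if (sum(bad) > 5L) ", ..." else "")
        if (strict) stop(msg) else warning(msg)
    }
    fields <- fields[!bad]
    parsed <- parsed[!bad, , drop = FALSE]
    hits <- data.frame(
        query_id = vapply(fields, `[`, "", 1L),
        subject_id = vapply(fields, `[`, "", 2L),
        stringsAsFactors = FALSE)
    colnames(parsed) <- .HIT_NUMERIC
    hits <- cbind(hits, as.data.frame(parsed))
    for (col in c("align_length", "mismatches", "gap_opens",
                  "qstart", "qend", "sstart", "send"))
        hits[[col]] <- as.integer(hits[[col]])
    # orientation normalisation: report coordinates on the plus strand
    flip <- hits$qstart > hits$qend
    if (any(flip)) {
        tmp <- hits$qstart[flip]
        hits$qstart[flip] <- hits$qend[flip]
        hits$qend[flip] <- tmp
    }
    if (dropPartial && any(lengths(fields) >= 13L)) {
        fl <- vapply(fields, function(f)
            if (length(f) >= 13L) f[[13L]] else "1", "")
        hits <- hits[fl %in% c("1", "TRUE", "true", "T"), , drop = FALSE]
    }
    rownames(hits) <- NULL
    hits
}

.emptyHits <- function() {
    out <- data.frame(query_id = character(), subject_id = character(),
        stringsAsFactors = FALSE)
    for (col in .HIT_NUMERIC) out[[col]] <- numeric()
    for (col in c("align_length", "mismatches", "gap_opens",
                  "qstart", "qend", "sstart", "send"))
        out[[col]] <- integer()
    out[.HIT_COLS]
}

#' Read a two-column query-length table
#'
#' @param path TSV with columns query id and length (no header required;
#'   a header line whose second field is non-numeric is skipped).
#' @return Named integer vector of query lengths.
#' @export
readQueryLengths <- function(path) {
    if (!file.exists(path))
        stop("query-length table not found: ", path)
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
        colClasses = "character", col.names = c("query_id", "length"))
    if (nrow(tab) && is.na(suppressWarnings(as.numeric(tab$length[1L]))))
        tab <- tab[-1L, , drop = FALSE]
    len <- as.integer(tab$length)
    if (anyNA(len))
        stop("non-numeric length in query-length table: ", path)
    stats::setNames(len, tab$query_id)
}

#' Query coverage of an alignment
#'
#' The fraction of the query sequence spanned by the aligned region,
#' `(qend - qstart + 1) / query length`, with 1-based inclusive
#' coordinates. This is the coverage criterion of the top-hit filter.
#'
#' @param hits Hit `data.frame` as returned by [readHitTable()].
#' @param queryLengths Named integer vector (query id -> length).
#' @return Numeric vector of coverages in (0, 1], one per hit.
#' @examples
#' h <- data.frame(query_id = "t1", qstart = 1L, qend = 450L)
#' queryCoverage(h, c(t1 = 500L))  # 0.9
#' @export
queryCoverage <- function(hits, queryLengths) {
    missing <- setdiff(unique(hits$query_id), names(queryLengths))
    if (length(missing))
        stop("no length entry for query id(s): ",
            paste(utils::head(missing, 5L), collapse = ", "))
    len <- unname(queryLengths[hits$query_id])
    if (any(len < hits$qend))
        stop("query length shorter than alignment end for: ",
            paste(utils::head(hits$query_id[len < hits$qend], 5L),
                collapse = ", "))
    (hits$qend - hits$qstart + 1L) / len
}

#' Filter hits by e-value and query coverage
#'
#' Keeps exactly the hits with `evalue <= evalueMax` and query coverage
#' `>= queryCovMin` (both boundaries inclusive), preserving input order.
#' The operation is idempotent.
#'
#' @param hits Hit `data.frame` from [readHitTable()].
#' @param thresholds A [filterThresholds()] object.
#' @param queryLengths Named integer vector of query lengths.
#' @return Filtered hit `data.frame`.
#' @export
filterHits <- function(hits, thresholds = filterThresholds(), queryLengths) {
    stopifnot(inherits(thresholds, "FilterThresholds"))
    if (!nrow(hits)) return(hits)
    cov <- queryCoverage(hits, queryLengths)
    keep <- hits$evalue <= thresholds$evalueMax & cov >= thresholds$queryCovMin
    out <- hits[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Resolve one best reference ortholog per transcript
#'
#' Among a transcript's (already filtered) hits, the top hit is the one
#' with maximal bit score; ties are broken by minimal e-value, then by the
#' lexicographically smallest subject id, so the result is deterministic
#' under any permutation of the input.
#'
#' @param hits Filtered hit `data.frame`.
#' @return Named character vector: transcript id -> reference ortholog id.
#' @export
bestHitPerTranscript <- function(hits) {
    if (!nrow(hits)) return(stats::setNames(character(), character()))
    o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id,
        method = "radix")
    h <- hits[o, , drop = FALSE]
    first <- !duplicated(h$query_id)
    stats::setNames(h$subject_id[first], h$query_id[first])
}

#' Read a species metadata table
#'
#' @param path TSV with header columns `species_id`, `growth_form`
#'   (`liana`/`non_liana`, or already `focal`/`background`) and optional
#'   `collapse_group`.
#' @return `data.frame` with columns `species_id`, `growth_form`
#'   (normalised to `focal`/`background`), `collapse_group`.
#' @export
readSpeciesMetadata <- function(path) {
    if (!file.exists(path))
        stop("species metadata not found: ", path)
    md <- utils::read.table(path, sep = "\t", header = TRUE,
        colClasses = "character")
    if (!all(c("species_id", "growth_form") %in% colnames(md)))
        stop("species metadata needs 'species_id' and 'growth_form' columns")
    map <- c(liana = "focal", focal = "focal",
        non_liana = "background", background = "background")
    gf <- map[md$growth_form]
    if (anyNA(gf))
        stop("unknown growth-form label(s): ",
            paste(unique(md$growth_form[is.na(gf)]), collapse = ", "))
    md$growth_form <- unname(gf)
    if (is.null(md$collapse_group) ) md$collapse_group <- md$species_id
    md$collapse_group[is.na(md$collapse_group) | md$collapse_group == ""] <-
        md$species_id[is.na(md$collapse_group) | md$collapse_group == ""]
    md[, c("species_id", "growth_form", "collapse_group")]
}

#' Build the species-by-ortholog presence matrix
#'
#' `present[o, s]` is `TRUE` iff at least one transcript of species `s`
#' maps (best hit) to ortholog `o`. Presence requires a single passing
#' transcript; no abundance threshold is applied.
#'
#' @param bestHits Named list, one element per species (names are species
#'   ids), each a transcript -> ortholog map from [bestHitPerTranscript()].
#' @param speciesMetadata `data.frame` from [readSpeciesMetadata()]; must
#'   cover every species in `bestHits`.
#' @return A [PresenceMatrix-class] with orthologs (the sorted union of
#'   mapped subjects) as rows and species as columns.
#' @export
buildPresenceMatrix <- function(bestHits, speciesMetadata) {
    sp <- names(bestHits)
    if (is.null(sp) || anyDuplicated(sp))
        stop("'bestHits' must be a named list with unique species ids")
    unknown <- setdiff(sp, speciesMetadata$species_id)
    if (length(unknown))
        stop("species missing from metadata: ",
            paste(unknown, collapse = ", "))
    orth <- sort(unique(unlist(lapply(bestHits, unname), use.names = FALSE)))
    m <- matrix(FALSE, nrow = length(orth), ncol = length(sp),
        dimnames = list(orth, sp))
    for (s in sp)
        m[unique(unname(bestHits[[s]])), s] <- TRUE
    md <- speciesMetadata[match(sp, speciesMetadata$species_id), ]
    PresenceMatrix(m, growthForm = md$growth_form,
        collapseGroup = md$collapse_group)
}
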