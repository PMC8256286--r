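#' Select motif-bearing significant candidates
#'
#' Intersects the significant hits of each KO comparison with the
#' motif-positive protein groups (ANY-member semantics; groups whose motif
#' status is unknown because no member sequence resolved are excluded) and
#' reports the per-KO sets and their union.
#'
#' @param diffList named list of [differentialTest()] results, one per KO
#' @param motifAnnotation output of [annotateGroups()] (columns `id`,
#'   `hasConsensus`)
#' @return a list with one character vector of group ids per KO plus
#'   `union`
#' @export
selectCandidates <- function(diffList, motifAnnotation) {
    stopifnot(is.list(diffList), length(diffList) >= 1L,
        all(c("id", "hasConsensus") %in% colnames(motifAnnotation)))
    motifPos <- motifAnnotation$id[motifAnnotation$hasConsensus %in% TRUE]
    out <- lapply(diffList, function(d)
        intersect(d$id[d$significant], motifPos))
    out$union <- Reduce(union, out)
    out
}

# Named list accession -> character vector of terms, from a ";"-joined
# annotation column.
.annotationMap <- function(annotation, column) {
    stopifnot(is.data.frame(annotation),
        all(c("accession", column) %in% colnames(annotation)))
    terms <- strsplit(ifelse(is.na(annotation[[column]]), "",
        annotation[[column]]), ";", fixed = TRUE)
    terms <- lapply(terms, function(t) trimws(t[nzchar(trimws(t))]))
    setNames(terms, annotation$accession)
}

# Domains of a protein group under ANY-member semantics.
.groupDomains <- function(members, pfamMap) {
    lapply(strsplit(members, ";", fixed = TRUE), function(acc)
        unique(unlist(pfamMap[intersect(trimws(acc), names(pfamMap))])))
}

#' Fisher exact test of Pfam-domain enrichment
#'
#' For each domain observed in the foreground, tests whether the foreground
#' is enriched for the domain relative to the background universe using a
#' one-sided (greater) Fisher exact test on the 2x2 table `(k, n - k,
#' K - k, N - n - (K - k))`, where `k`/`K` count foreground/background
#' groups carrying the domain and `n`/`N` are the set sizes. Domain
#' annotation uses ANY-member semantics. Domains absent from the foreground
#' are skipped. No multiple-testing correction is applied by default.
#'
#' @param foreground character vector of candidate group ids (must be a
#'   subset of `background`)
#' @param background character vector of universe group ids (the filtered
#'   secretome)
#' @param groups data.frame with columns `id` and `members` mapping group
#'   ids to member accessions
#' @param annotation annotation table (columns `accession`, `pfam`)
#' @param alpha significance threshold (default 0.05)
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @return a data.frame per domain: `domain`, `k`, `n`, `K`, `N`,
#'   `oddsRatio`, `p`, `significant`, ordered by p
#' @export
fisherDomainEnrichment <- function(foreground, background, groups,
        annotation, alpha = 0.05, alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    if (!all(foreground %in% background))
        stop("foreground must be a subset of the background universe",
            call. = FALSE)
    pfamMap <- .annotationMap(annotation, "pfam")
    idx <- match(background, groups$id)
    if (anyNA(idx))
        stop("background ids missing from the group table", call. = FALSE)
    domainsByGroup <- .groupDomains(groups$members[idx], pfamMap)
    names(domainsByGroup) <- background
    fgDomains <- unique(unlist(domainsByGroup[foreground]))
    n <- length(foreground)
    N <- length(background)
    rows <- lapply(fgDomains, function(d) {
        has <- vapply(domainsByGroup, function(x) d %in% x, logical(1))
        k <- sum(has[foreground])
        K <- sum(has)
        tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2L)
        ft <- fisher.test(tab, alternative = alternative)
        data.frame(domain = d, k = k, n = n, K = K, N = N,
            oddsRatio = unname(ft$estimate), p = ft$p.value,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(domain = character(0), k = integer(0),
            n = integer(0), K = integer(0), N = integer(0),
            oddsRatio = numeric(0), p = numeric(0))
    out$significant <- out$p <= alpha
    out <- out[order(out$p, out$domain), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Rescreen a background set for a protein domain
#'
#' Returns every background group with at least one member annotated with
#' the given Pfam domain — the step that widens a significance-driven
#' candidate list to all domain carriers in the filtered universe (e.g.
#' all TSP_1/TSR-domain proteins among the filtered extracellular set).
#'
#' @inheritParams fisherDomainEnrichment
#' @param domain Pfam domain name (default `"TSP_1"`)
#' @return character vector of group ids (empty, with a warning, if the
#'   domain never occurs in the annotation)
#' @export
rescreenDomain <- function(background, groups, annotation,
        domain = "TSP_1") {
    pfamMap <- .annotationMap(annotation, "pfam")
    if (!domain %in% unlist(pfamMap)) {
        warning("domain '", domain, "' not present in the annotation")
        return(character(0))
    }
    idx <- match(background, groups$id)
    if (anyNA(idx))
        stop("background ids missing from the group table", call. = FALSE)
    domainsByGroup <- .groupDomains(groups$members[idx], pfamMap)
    background[vapply(domainsByGroup, function(x) domain %in% x, logical(1))]
}
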