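#' @importFrom Biostrings readAAStringSet AAStringSet writeXStringSet
NULL

# Residues tolerated inside a scanned window ("x" positions). Windows
# containing gap/stop or other foreign characters never match.
.AA_TOLERATED <- c(names(.AA_MONO), "X", "U", "B", "Z")

#' Scan a protein sequence for C-mannosylation consensus sites
#'
#' Reports every tryptophan in a WxxW or WxxC context: positions `i`
#' (1-based) with W at `i` and W or C at `i + 3`. The two x positions may be
#' any tolerated residue (including W or C); overlapping sites are all
#' reported. Windows containing characters outside the amino-acid alphabet
#' (plus X/U/B/Z) never match.
#'
#' @param sequence upper-case amino-acid string
#' @return a data.frame with columns `position` (1-based index of the
#'   modifiable tryptophan), `kind` (`"WxxW"` or `"WxxC"`), and `context`
#'   (the 4-residue window), sorted by position
#' @examples
#' scanConsensusSites("WSDWSSWSPC")  # three sites: 1, 4 (WxxW), 7 (WxxC)
#' @export
scanConsensusSites <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
    if (nchar(sequence) == 0L)
        stop("empty sequence", call. = FALSE)
    chars <- strsplit(sequence, "")[[1L]]
    n <- length(chars)
    empty <- data.frame(position = integer(0), kind = character(0),
        context = character(0), stringsAsFactors = FALSE)
    if (n < 4L)
        return(empty)
    i <- seq_len(n - 3L)
    anchor <- chars[i] == "W"
    partner <- chars[i + 3L]
    xok <- chars %in% .AA_TOLERATED
    windowOk <- xok[i + 1L] & xok[i + 2L]
    isW <- anchor & windowOk & partner == "W"
    isC <- anchor & windowOk & partner == "C"
    pos <- i[isW | isC]
    if (!length(pos))
        return(empty)
    data.frame(
        position = pos,
        kind = ifelse(chars[pos + 3L] == "W", "WxxW", "WxxC"),
        context = vapply(pos, function(p)
            paste(chars[p:(p + 3L)], collapse = ""), character(1)),
        stringsAsFactors = FALSE
    )
}

#' Find thrombospondin type 1 repeat tryptophan motifs
#'
#' Locates the conserved WxxWxxWxxC motif of TSR domains: a 10-residue
#' window with W at offsets 0, 3 and 6 and C at offset 9. All three
#' tryptophans of such a motif can be C-mannosylated (W1 and W2 lie in WxxW
#' contexts, W3 in a WxxC context), so every reported tryptophan is also a
#' [scanConsensusSites()] hit.
#'
#' @inheritParams scanConsensusSites
#' @return a data.frame with columns `start` (1-based), `w1`, `w2`, `w3`
#'   (positions of the three mannosylatable tryptophans) and `motif` (the
#'   10-residue window)
#' @examples
#' findTsrMotifs("WSDWSSWSPC")  # one hit, tryptophans at 1, 4, 7
#' @export
findTsrMotifs <- function(sequence) {
    sites <- scanConsensusSites(sequence)
    empty <- data.frame(start = integer(0), w1 = integer(0), w2 = integer(0),
        w3 = integer(0), motif = character(0), stringsAsFactors = FALSE)
    if (!nrow(sites))
        return(empty)
    byPos <- split(sites$kind, sites$position)
    isKind <- function(p, k) {
        key <- as.character(p)
        !is.null(byPos[[key]]) && k %in% byPos[[key]]
    }
    starts <- sites$position[sites$kind == "WxxW"]
    hit <- vapply(starts, function(p)
        isKind(p + 3L, "WxxW") && isKind(p + 6L, "WxxC"), logical(1))
    starts <- starts[hit]
    if (!length(starts))
        return(empty)
    chars <- strsplit(sequence, "")[[1L]]
    data.frame(
        start = starts,
        w1 = starts, w2 = starts + 3L, w3 = starts + 6L,
        motif = vapply(starts, function(p)
            paste(chars[p:(p + 9L)], collapse = ""), character(1)),
        stringsAsFactors = FALSE
    )
}

#' Read a protein database from FASTA
#'
#' Wraps [Biostrings::readAAStringSet()] and normalises names: UniProt-style
#' headers `sp|ACC|NAME ...` / `tr|ACC|NAME ...` are reduced to the
#' accession; otherwise the first whitespace-delimited token is used.
#'
#' @param path path to a FASTA file
#' @return a named [Biostrings::AAStringSet]
#' @export
readProteinDb <- function(path) {
    seqs <- Biostrings::readAAStringSet(path)
    nm <- names(seqs)
    tok <- sub("\\s.*$", "", nm)
    uni <- grepl("^(sp|tr)\\|", tok)
    tok[uni] <- vapply(strsplit(tok[uni], "|", fixed = TRUE), `[[`, "", 2L)
    names(seqs) <- tok
    if (anyDuplicated(tok))
        warning("duplicated accessions in ", path)
    seqs
}

#' Annotate protein groups with consensus-site calls
#'
#' Lifts residue-level consensus-site scans to MaxQuant-style protein groups
#' using ANY-member semantics: a group is motif-positive if any member with
#' an available sequence carries at least one WxxW/WxxC site. Members with no
#' sequence in `db` are recorded as unresolved and are never treated as
#' evidence of absence; a group whose members all fail to resolve gets
#' `hasConsensus = NA` and is excluded from the motif-positive set.
#'
#' @param groups a data.frame with columns `id` and `members`
#'   (semicolon-separated accession lists), e.g. `rowData` of a
#'   [SecretomeExperiment]
#' @param db a named [Biostrings::AAStringSet] (or named character vector) of
#'   member sequences
#' @return `groups` with added columns `hasConsensus` (logical, `NA` if no
#'   member resolved), `nSites` (total sites over resolved members),
#'   `unresolved` (semicolon-joined accessions missing from `db`), and a
#'   `sites` list-column of per-member site data.frames
#' @export
annotateGroups <- function(groups, db) {
    stopifnot(is.data.frame(groups) || is(groups, "DataFrame"),
        all(c("id", "members") %in% colnames(groups)))
    seqs <- if (is.character(db)) db else as.character(db)
    if (is.null(names(seqs)))
        stop("db must be named by accession", call. = FALSE)
    groups <- as.data.frame(groups[, c("id", "members")])
    memberList <- strsplit(groups$members, ";", fixed = TRUE)
    res <- lapply(memberList, function(acc) {
        acc <- trimws(acc)
        acc <- acc[nzchar(acc)]
        found <- acc[acc %in% names(seqs)]
        missing <- setdiff(acc, found)
        sites <- lapply(found, function(a) scanConsensusSites(seqs[[a]]))
        names(sites) <- found
        list(
            hasConsensus = if (!length(found)) NA
                else any(vapply(sites, nrow, integer(1)) > 0L),
            nSites = sum(vapply(sites, nrow, integer(1))),
            unresolved = missing,
            sites = sites
        )
    })
    unresolved <- unique(unlist(lapply(res, `[[`, "unresolved")))
    if (length(unresolved))
        warning(length(unresolved), " accession(s) without a sequence: ",
            paste(utils::head(unresolved, 5L), collapse = ", "),
            if (length(unresolved) > 5L) ", ...")
    groups$hasConsensus <- vapply(res, `[[`, logical(1), "hasConsensus")
    groups$nSites <- vapply(res, `[[`, integer(1), "nSites")
    groups$unresolved <- vapply(res, function(r)
        paste(r$unresolved, collapse = ";"), character(1))
    groups$sites <- lapply(res, `[[`, "sites")
    groups
}
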