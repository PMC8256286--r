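#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated "proteinGroups.txt" dialect: protein-group ids
#' from `Majority protein IDs` (semicolon-separated accession lists),
#' distinct-peptide counts from `Peptides`, quality flags marked `"+"` in
#' `Potential contaminant` / `Reverse` / `Only identified by site`, and one
#' `LFQ intensity <sample>` column per sample of the design (zeros denote
#' missing and become `NA`).
#'
#' @param path path to a tab-separated proteinGroups file
#' @param design data.frame with columns `sample`, `group`, `clone`
#'   naming the LFQ columns to ingest (see [defaultDesign()])
#' @return a [SecretomeExperiment]
#' @export
readProteinGroups <- function(path, design) {
    stopifnot(all(c("sample", "group", "clone") %in% colnames(design)))
    tab <- utils::read.delim(path, check.names = FALSE, sep = "\t",
        stringsAsFactors = FALSE, quote = "")
    need <- c("Majority protein IDs", "Peptides",
        paste0("LFQ intensity ", design$sample))
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("malformed proteinGroups file, missing column(s): ",
            paste(miss, collapse = ", "), call. = FALSE)
    flag <- function(col) {
        if (col %in% colnames(tab)) tab[[col]] == "+"
        else rep(FALSE, nrow(tab))
    }
    members <- tab[["Majority protein IDs"]]
    rowData <- data.frame(
        id = vapply(strsplit(members, ";", fixed = TRUE), `[[`, "", 1L),
        members = members,
        peptides = as.integer(tab[["Peptides"]]),
        contaminant = flag("Potential contaminant"),
        reverse = flag("Reverse"),
        onlyBySite = flag("Only identified by site"),
        stringsAsFactors = FALSE)
    lfq <- as.matrix(tab[, paste0("LFQ intensity ", design$sample),
        drop = FALSE])
    colnames(lfq) <- design$sample
    SecretomeExperiment(lfq, rowData, design)
}

#' Write a proteinGroups-dialect table
#'
#' @param table a proteinGroups-dialect data.frame (e.g. from
#'   [simulateLfqExperiment()])
#' @param path output path (tab-separated, UTF-8)
#' @return `path`, invisibly
#' @export
writeProteinGroups <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
        row.names = FALSE, na = "")
    invisible(path)
}

#' Read a Perseus-style annotation table
#'
#' Tab-separated table mapping accessions to GO-CC slim terms and Pfam
#' domains, with multi-valued entries semicolon-joined. Column names are
#' matched case-insensitively against common variants (`Accession` /
#' `Protein IDs` / first column; `GOCC slim name`; `Pfam`).
#'
#' @param path path to a tab-separated annotation file
#' @return data.frame with columns `accession`, `gocc`, `pfam`
#' @export
readAnnotation <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE, sep = "\t",
        stringsAsFactors = FALSE, quote = "")
    pick <- function(cands, default = NULL) {
        hit <- which(tolower(colnames(tab)) %in% tolower(cands))
        if (length(hit)) colnames(tab)[hit[1L]] else default
    }
    accCol <- pick(c("accession", "Protein IDs", "Majority protein IDs"),
        colnames(tab)[1L])
    goCol <- pick(c("gocc", "GOCC slim name", "GOCC name"))
    pfamCol <- pick(c("pfam", "Pfam domains"))
    if (is.null(goCol) && is.null(pfamCol))
        stop("annotation file has neither a GO-CC nor a Pfam column",
            call. = FALSE)
    data.frame(
        accession = tab[[accCol]],
        gocc = if (is.null(goCol)) "" else tab[[goCol]],
        pfam = if (is.null(pfamCol)) "" else tab[[pfamCol]],
        stringsAsFactors = FALSE)
}

#' @rdname readAnnotation
#' @param annotation an annotation data.frame
#' @param path output path
#' @export
writeAnnotation <- function(annotation, path) {
    utils::write.table(annotation, path, sep = "\t", quote = FALSE,
        row.names = FALSE, na = "")
    invisible(path)
}

#' Run the full differential-secretome pipeline
#'
#' Executes, in order: ingestion of the protein-group table, Perseus-style
#' filtering ([filterSecretome()]), log2 transformation and left-shifted
#' normal imputation ([imputeLfq()]), per-KO Student t tests
#' ([differentialTest()]), consensus-motif annotation of the filtered
#' universe ([annotateGroups()]), candidate selection
#' ([selectCandidates()]), Pfam domain enrichment
#' ([fisherDomainEnrichment()]) and a background rescreen for the TSP_1
#' domain ([rescreenDomain()]). Any stage failure aborts with the stage
#' name. When `outDir` is given, writes `results.tsv` (volcano-ready merged
#' differential table), `filter_report.tsv`, `enrichment.tsv`,
#' `candidates.tsv` and `provenance.json` (package version, seed, full
#' configuration and its hash).
#'
#' @param proteinGroups path to a proteinGroups file, or a
#'   [SecretomeExperiment]
#' @param fasta path to the protein FASTA, or a named
#'   [Biostrings::AAStringSet] / character vector of sequences
#' @param annotation path to the annotation TSV, or an annotation
#'   data.frame
#' @param design sample design data.frame (see [defaultDesign()])
#' @param seed integer seed for the imputation
#' @param alpha significance threshold (default 0.05)
#' @param minPeptides minimum distinct peptides (default 2)
#' @param imputeWidth,imputeDownshift imputation parameters (defaults 0.3
#'   and 1.8)
#' @param refGroup reference group label (default `"WT"`)
#' @param rescreen Pfam domain for the background rescreen (default
#'   `"TSP_1"`)
#' @param outDir optional output directory
#' @return a list: `se` (filtered, imputed), `filterReport`, `diff` (one
#'   differential table per KO), `motifs`, `candidates`, `enrichment`,
#'   `rescreen`, `perClone`, `provenance`
#' @export
runPipeline <- function(proteinGroups, fasta, annotation,
        design = defaultDesign(), seed, alpha = 0.05, minPeptides = 2L,
        imputeWidth = 0.3, imputeDownshift = 1.8, refGroup = "WT",
        rescreen = "TSP_1", outDir = NULL) {
    if (missing(seed) || is.null(seed))
        stop("pipeline requires an integer seed", call. = FALSE)
    if (missing(annotation) || is.null(annotation))
        stop("pipeline requires an annotation table (GO-CC and Pfam)",
            call. = FALSE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                conditionMessage(e), call. = FALSE))
    }
    se <- stage("ingest", {
        if (is(proteinGroups, "SecretomeExperiment")) proteinGroups
        else readProteinGroups(proteinGroups, design)
    })
    annot <- stage("ingest", {
        if (is.data.frame(annotation)) annotation
        else readAnnotation(annotation)
    })
    db <- stage("ingest", {
        if (is.character(fasta) && length(fasta) == 1L &&
                file.exists(fasta)) readProteinDb(fasta)
        else fasta
    })
    filt <- stage("filter", filterSecretome(se, annot,
        minPeptides = minPeptides, refGroup = refGroup))
    seImp <- stage("impute", imputeLfq(filt$se, width = imputeWidth,
        downshift = imputeDownshift, seed = seed))
    koGroups <- setdiff(unique(design$group), refGroup)
    diff <- stage("test", setNames(lapply(koGroups, function(g)
        differentialTest(seImp, g, ref = refGroup, alpha = alpha)),
        koGroups))
    motifs <- stage("motif", annotateGroups(
        as.data.frame(rowData(seImp)[, c("id", "members")]), db))
    candidates <- stage("select", selectCandidates(diff, motifs))
    groupsDf <- as.data.frame(rowData(seImp)[, c("id", "members")])
    background <- groupsDf$id
    enrich <- stage("enrich", {
        if (length(candidates$union))
            fisherDomainEnrichment(candidates$union, background, groupsDf,
                annot, alpha = alpha)
        else
            fisherDomainEnrichment(character(0), background, groupsDf,
                annot, alpha = alpha)
    })
    rescreened <- stage("rescreen", rescreenDomain(background, groupsDf,
        annot, domain = rescreen))
    perClone <- stage("fold-changes", perCloneFoldChanges(seImp,
        ref = refGroup))
    config <- list(alpha = alpha, minPeptides = minPeptides,
        imputeWidth = imputeWidth, imputeDownshift = imputeDownshift,
        refGroup = refGroup, rescreen = rescreen, seed = seed,
        design = design)
    provenance <- list(
        package = "CMannoScan",
        version = as.character(utils::packageVersion("CMannoScan")),
        seed = seed,
        config = config,
        configHash = .configHash(config))
    result <- list(se = seImp, filterReport = filt$report, diff = diff,
        motifs = motifs, candidates = candidates, enrichment = enrich,
        rescreen = rescreened, perClone = perClone,
        provenance = provenance)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeResults(result, outDir)
    }
    result
}

#' Write a pipeline result bundle to a directory
#'
#' @param result a [runPipeline()] result list
#' @param outDir output directory
#' @return `outDir`, invisibly
#' @export
writeResults <- function(result, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    merged <- do.call(rbind, lapply(names(result$diff), function(g) {
        d <- result$diff[[g]]
        d$comparison <- g
        d$motifPositive <- d$id %in%
            result$motifs$id[result$motifs$hasConsensus %in% TRUE]
        d$candidate <- d$id %in% result$candidates[[g]]
        d
    }))
    merged$configHash <- result$provenance$configHash
    tsv <- function(x, f) utils::write.table(x, file.path(outDir, f),
        sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    tsv(merged, "results.tsv")
    rep <- result$filterReport
    rep$configHash <- result$provenance$configHash
    tsv(rep, "filter_report.tsv")
    enr <- result$enrichment
    enr$configHash <- rep_len(result$provenance$configHash,
        nrow(enr))
    tsv(enr, "enrichment.tsv")
    cand <- data.frame(
        set = rep(names(result$candidates),
            vapply(result$candidates, length, integer(1))),
        id = unlist(result$candidates, use.names = FALSE),
        configHash = result$provenance$configHash)
    tsv(cand, "candidates.tsv")
    jsonlite::write_json(result$provenance,
        file.path(outDir, "provenance.json"), auto_unbox = TRUE,
        digits = NA, force = TRUE)
    invisible(outDir)
}
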