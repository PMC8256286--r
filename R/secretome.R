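#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData assay<-
#' @importFrom stats pt rnorm sd setNames t.test plogis fisher.test
NULL

#' Construct a SecretomeExperiment
#'
#' @param lfq numeric matrix of LFQ intensities, proteins x samples; zeros
#'   are converted to `NA` (MaxQuant writes 0 for non-quantified)
#' @param rowData data.frame with columns `id`, `members`, `peptides`,
#'   `contaminant`, `reverse`, `onlyBySite`
#' @param colData data.frame with columns `group` and `clone`, one row per
#'   sample (clones are the individual cell lines within a group; for WT,
#'   clone equals the group label)
#' @return a [SecretomeExperiment]
#' @export
SecretomeExperiment <- function(lfq, rowData, colData) {
    lfq <- as.matrix(lfq)
    lfq[!is.na(lfq) & lfq == 0] <- NA_real_
    se <- SummarizedExperiment(
        assays = list(lfq = lfq),
        rowData = S4Vectors::DataFrame(rowData),
        colData = S4Vectors::DataFrame(colData))
    rownames(se) <- rowData$id
    as(se, "SecretomeExperiment")
}

setMethod("show", "SecretomeExperiment", function(object) {
    cd <- colData(object)
    cat("SecretomeExperiment:", nrow(object), "protein groups x",
        ncol(object), "samples\n")
    cat("  groups:", paste(sprintf("%s (n=%d)", names(table(cd$group)),
        table(cd$group)), collapse = ", "), "\n")
    miss <- mean(is.na(assay(object, "lfq")))
    cat(sprintf("  missing LFQ values: %.1f%%\n", 100 * miss))
    if ("log2imputed" %in% assayNames(object))
        cat("  log2-transformed and imputed assay present\n")
})

.detectionMatrix <- function(se) !is.na(assay(se, "lfq"))

# Replicate-detection rule: at least minWt detections among WT samples, OR,
# for some KO group, at least one detection in each of its clones.
.detectionKeep <- function(se, refGroup = "WT", minWt = 2L) {
    det <- .detectionMatrix(se)
    cd <- colData(se)
    wtOk <- rowSums(det[, cd$group == refGroup, drop = FALSE]) >= minWt
    koOk <- rep(FALSE, nrow(se))
    for (g in setdiff(unique(cd$group), refGroup)) {
        clones <- unique(cd$clone[cd$group == g])
        allClones <- rep(TRUE, nrow(se))
        for (cl in clones)
            allClones <- allClones &
                rowSums(det[, cd$clone == cl, drop = FALSE]) >= 1L
        koOk <- koOk | allClones
    }
    wtOk | koOk
}

#' Filter a secretome LFQ matrix the Perseus way
#'
#' Applies, in order: (1) removal of contaminants, reverse-database matches
#' and proteins only identified by site; (2) restriction to extracellular
#' proteins, i.e. groups with any member annotated with one of the GO-CC
#' slim terms in `goTerms` (accessions without annotation count as not
#' extracellular); (3) restriction to groups identified by at least
#' `minPeptides` distinct peptides and detected in at least two WT
#' replicates or in both clones of one KO. Detection means a non-missing
#' LFQ value.
#'
#' @param se a [SecretomeExperiment]
#' @param annotation annotation table from [readAnnotation()] (columns
#'   `accession`, `gocc`, `pfam`, terms semicolon-joined)
#' @param goTerms GO-CC slim terms defining "extracellular"
#' @param minPeptides minimum distinct peptides (default 2)
#' @param refGroup label of the reference (wild-type) group
#' @return a list with `se` (the filtered [SecretomeExperiment]) and
#'   `report`, a data.frame of stagewise counts (non-increasing) with the
#'   detected-in-all-cell-lines count as `attr(report, "detectedAllLines")`
#' @export
filterSecretome <- function(se, annotation,
        goTerms = c("extracellular matrix", "extracellular region",
            "extracellular space"),
        minPeptides = 2L, refGroup = "WT") {
    stopifnot(is(se, "SecretomeExperiment"))
    if (missing(annotation) || is.null(annotation))
        stop("annotation table is required for the extracellular filter",
            call. = FALSE)
    goMap <- .annotationMap(annotation, "gocc")
    report <- data.frame(stage = character(0), n = integer(0))
    add <- function(stage, n) rbind(report, data.frame(stage = stage, n = n))

    report <- add("initial", nrow(se))

    rd <- rowData(se)
    se1 <- se[!(rd$contaminant | rd$reverse | rd$onlyBySite), ]
    report <- add("no_decoys", nrow(se1))

    members <- strsplit(rowData(se1)$members, ";", fixed = TRUE)
    unannotated <- sum(!unlist(members) %in% names(goMap))
    isExtra <- vapply(members, function(acc)
        any(unlist(goMap[intersect(acc, names(goMap))]) %in% goTerms),
        logical(1))
    se2 <- se1[isExtra, ]
    report <- add("extracellular", nrow(se2))

    keep <- rowData(se2)$peptides >= minPeptides &
        .detectionKeep(se2, refGroup = refGroup)
    se3 <- se2[keep, ]
    report <- add("min_peptides_detection", nrow(se3))
    report <- add("final", nrow(se3))

    det <- .detectionMatrix(se3)
    cd <- colData(se3)
    allLines <- rep(nrow(se3) > 0L, nrow(se3))
    for (cl in unique(cd$clone))
        allLines <- allLines &
            rowSums(det[, cd$clone == cl, drop = FALSE]) >= 1L
    attr(report, "detectedAllLines") <- sum(allLines)
    attr(report, "unannotatedAccessions") <- unannotated
    list(se = se3, report = report)
}

#' Log2-transform and impute missing LFQ values
#'
#' Transforms the `lfq` assay to log2 and replaces each missing value in
#' column `c` with a draw from `Normal(mean_c - downshift * sd_c,
#' (width * sd_c)^2)`, where `mean_c` and `sd_c` are computed over the
#' observed log2 values of that column (Perseus-style left-shifted normal
#' imputation, performed separately for each column; defaults width 0.3,
#' down shift 1.8). Reproducible given `seed`; the global RNG state is
#' restored afterwards.
#'
#' @param se a [SecretomeExperiment]
#' @param width imputation width as a fraction of the column SD
#' @param downshift imputation down shift in multiples of the column SD
#' @param seed integer seed (required: imputation must be reproducible)
#' @return `se` with two added assays: `"log2imputed"` (complete) and
#'   `"imputed"` (logical mask); imputation parameters recorded in
#'   `metadata(se)$impute`
#' @export
imputeLfq <- function(se, width = 0.3, downshift = 1.8, seed) {
    stopifnot(is(se, "SecretomeExperiment"), width > 0)
    if (missing(seed) || is.null(seed))
        stop("an integer seed is required for reproducible imputation",
            call. = FALSE)
    x <- log2(assay(se, "lfq"))
    nObs <- colSums(!is.na(x))
    if (any(nObs < 2L)) {
        bad <- colnames(x)[nObs < 2L]
        stop("column(s) with fewer than 2 observed values: ",
            paste(bad, collapse = ", "), call. = FALSE)
    }
    mask <- is.na(x)
    .withSeed(seed, {
        for (j in seq_len(ncol(x))) {
            nm <- sum(mask[, j])
            if (!nm) next
            m <- mean(x[, j], na.rm = TRUE)
            s <- sd(x[, j], na.rm = TRUE)
            x[mask[, j], j] <- rnorm(nm, m - downshift * s, width * s)
        }
    })
    assay(se, "log2imputed") <- x
    assay(se, "imputed") <- mask
    metadata(se)$impute <- list(width = width, downshift = downshift,
        seed = seed)
    se
}

# Equal-variance two-sample t test on one row; returns c(t, p, df).
# Conventions for degenerate rows: zero pooled variance with equal means
# gives p = 1, with unequal means p = 0.
.rowStudentT <- function(a, b) {
    res <- tryCatch(t.test(a, b, var.equal = TRUE),
        error = function(e) NULL)
    if (is.null(res)) {
        if (isTRUE(all.equal(mean(a), mean(b))))
            return(c(t = 0, p = 1, df = length(a) + length(b) - 2))
        return(c(t = sign(mean(a) - mean(b)) * Inf, p = 0,
            df = length(a) + length(b) - 2))
    }
    c(t = unname(res$statistic), p = res$p.value,
        df = unname(res$parameter))
}

#' Per-protein differential test between a KO group and the reference
#'
#' Two-tailed Student (equal-variance) t test per protein group on the
#' imputed log2 values, comparing all samples of `group` (both clones
#' pooled) with the reference. With the Perseus artificial variance
#' parameter S0 at 0 the moderated statistic reduces to the plain t, which
#' is what is computed here. Fold change is `mean(group) - mean(ref)` in
#' log2 units; significance is a raw p-value threshold (no
#' multiple-testing correction by default, `padjust = "BH"` enables it).
#'
#' @param se an imputed [SecretomeExperiment] (see [imputeLfq()])
#' @param group KO group label to test
#' @param ref reference group label (default `"WT"`)
#' @param alpha significance threshold on p (default 0.05)
#' @param padjust `"none"` (default) or a [stats::p.adjust()] method
#' @param assayName assay to test (default `"log2imputed"`)
#' @return a data.frame per protein group: `id`, `log2fc`, `t`, `df`, `p`,
#'   (optionally `padj`), `significant`
#' @export
differentialTest <- function(se, group, ref = "WT", alpha = 0.05,
        padjust = "none", assayName = "log2imputed") {
    stopifnot(is(se, "SecretomeExperiment"))
    if (!assayName %in% assayNames(se))
        stop("assay '", assayName, "' not found; run imputeLfq() first",
            call. = FALSE)
    cd <- colData(se)
    ia <- which(cd$group == group)
    ib <- which(cd$group == ref)
    if (length(ia) < 2L || length(ib) < 2L)
        stop("need >= 2 samples per side (", group, ": ", length(ia),
            ", ", ref, ": ", length(ib), ")", call. = FALSE)
    x <- assay(se, assayName)
    stats <- t(apply(x, 1L, function(r) .rowStudentT(r[ia], r[ib])))
    out <- data.frame(
        id = rowData(se)$id,
        log2fc = rowMeans(x[, ia, drop = FALSE]) -
            rowMeans(x[, ib, drop = FALSE]),
        t = stats[, "t"], df = stats[, "df"], p = stats[, "p"],
        stringsAsFactors = FALSE)
    if (padjust != "none") {
        out$padj <- stats::p.adjust(out$p, method = padjust)
        out$significant <- out$padj <= alpha
    } else {
        out$significant <- out$p <= alpha
    }
    rownames(out) <- NULL
    out
}

#' Fold changes of individual KO samples against the mean reference level
#'
#' For every sample outside the reference group, computes the per-protein
#' log2 fold change against the reference-group mean, and summarises the
#' per-sample fold changes into a per-group mean (the bar-and-dots display
#' conventionally used for per-clone secretion levels).
#'
#' @param se an imputed [SecretomeExperiment]
#' @param ref reference group label
#' @param assayName assay to use (default `"log2imputed"`)
#' @return a list with `perSample` (long data.frame: `id`, `sample`,
#'   `clone`, `group`, `log2fc`) and `perGroup` (data.frame: `id`, `group`,
#'   `meanLog2fc`)
#' @export
perCloneFoldChanges <- function(se, ref = "WT", assayName = "log2imputed") {
    stopifnot(is(se, "SecretomeExperiment"))
    x <- assay(se, assayName)
    cd <- colData(se)
    refMean <- rowMeans(x[, cd$group == ref, drop = FALSE])
    koIdx <- which(cd$group != ref)
    perSample <- do.call(rbind, lapply(koIdx, function(j) data.frame(
        id = rowData(se)$id,
        sample = colnames(se)[j],
        clone = cd$clone[j],
        group = cd$group[j],
        log2fc = x[, j] - refMean,
        stringsAsFactors = FALSE)))
    rownames(perSample) <- NULL
    agg <- stats::aggregate(log2fc ~ id + group, data = perSample, FUN = mean)
    names(agg)[names(agg) == "log2fc"] <- "meanLog2fc"
    list(perSample = perSample, perGroup = agg)
}
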