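#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GlycoPeptide: a peptide that can carry C-mannoses and an O-fucose glycan
#'
#' Represents a proteolytic peptide with a fixed-modification state
#' (carbamidomethyl on Cys by default), the number of C-mannosylatable
#' consensus tryptophans, and an optional O-fucosylation site. The number of
#' consensus tryptophans is caller-controlled because the WxxC context of a
#' tryptophan can lie beyond the peptide's C terminus, so it cannot always be
#' inferred from the peptide sequence alone.
#'
#' @slot sequence upper-case amino-acid sequence (20 standard residues)
#' @slot nConsensusTrp number of tryptophans that can carry a C-mannose
#' @slot hasOFucSite whether the peptide carries an O-fucosylation site
#'   (Ser/Thr in a fucosylation context; asserted by the caller)
#' @slot oFucPosition 1-based residue position of the O-fucose acceptor, or
#'   `NA` when unknown (fucose mass is then applied at the precursor level
#'   only)
#' @slot carbamidomethyl whether Cys residues carry the +57.02146 Da fixed
#'   modification
#'
#' @seealso [GlycoPeptide()], [enumerateGlycoforms()], [fragmentIons()]
#' @exportClass GlycoPeptide
setClass("GlycoPeptide",
    representation(
        sequence = "character",
        nConsensusTrp = "integer",
        hasOFucSite = "logical",
        oFucPosition = "integer",
        carbamidomethyl = "logical"
    ),
    prototype(
        nConsensusTrp = 0L,
        hasOFucSite = FALSE,
        oFucPosition = NA_integer_,
        carbamidomethyl = TRUE
    )
)

setValidity("GlycoPeptide", function(object) {
    msg <- character(0)
    s <- object@sequence
    if (length(s) != 1L || is.na(s) || nchar(s) == 0L)
        msg <- c(msg, "sequence must be a single non-empty string")
    else {
        bad <- setdiff(strsplit(s, "")[[1L]], names(.AA_MONO))
        if (length(bad))
            msg <- c(msg, paste0("unknown residue(s): ",
                paste(unique(bad), collapse = ", ")))
        nW <- sum(strsplit(s, "")[[1L]] == "W")
        if (!is.na(object@nConsensusTrp) && object@nConsensusTrp > nW)
            msg <- c(msg, "nConsensusTrp exceeds the number of W residues")
    }
    if (object@nConsensusTrp < 0L)
        msg <- c(msg, "nConsensusTrp must be >= 0")
    if (!object@hasOFucSite && !is.na(object@oFucPosition))
        msg <- c(msg, "oFucPosition set although hasOFucSite is FALSE")
    if (length(msg)) msg else TRUE
})

#' SpectrumRun: a time-ordered series of MS1 centroid spectra
#'
#' Minimal container for an MS1 acquisition: one retention time (minutes) per
#' scan and, per scan, a two-column centroid matrix (`mz`, `intensity`).
#'
#' @slot rt numeric, scan retention times in minutes, non-decreasing
#' @slot peaks list of numeric matrices, one per scan, columns `mz` and
#'   `intensity` (intensities >= 0)
#'
#' @seealso [SpectrumRun()], [extractEIC()], [simulateMs1Run()]
#' @exportClass SpectrumRun
setClass("SpectrumRun",
    representation(rt = "numeric", peaks = "list"))

setValidity("SpectrumRun", function(object) {
    msg <- character(0)
    if (length(object@rt) != length(object@peaks))
        msg <- c(msg, "rt and peaks must have equal length")
    if (length(object@rt) > 1L && any(diff(object@rt) < 0))
        msg <- c(msg, "scan retention times must be non-decreasing")
    ok <- vapply(object@peaks, function(p) {
        is.matrix(p) && ncol(p) == 2L && all(p[, 2L] >= 0)
    }, logical(1))
    if (!all(ok))
        msg <- c(msg, "each scan must be a 2-column matrix with intensities >= 0")
    if (length(msg)) msg else TRUE
})

#' Chromatogram: an extracted ion trace
#'
#' @slot rt numeric, retention times in minutes, strictly increasing
#' @slot intensity numeric, per-scan summed centroid intensity (>= 0)
#' @slot targetMz target m/z of the extraction
#' @slot tol absolute extraction tolerance in Da
#'
#' @seealso [extractEIC()], [quantifyGlycoforms()]
#' @exportClass Chromatogram
setClass("Chromatogram",
    representation(
        rt = "numeric",
        intensity = "numeric",
        targetMz = "numeric",
        tol = "numeric"
    )
)

setValidity("Chromatogram", function(object) {
    msg <- character(0)
    if (length(object@rt) != length(object@intensity))
        msg <- c(msg, "rt and intensity must have equal length")
    if (length(object@rt) > 1L && any(diff(object@rt) <= 0))
        msg <- c(msg, "rt must be strictly increasing")
    if (any(object@intensity < 0))
        msg <- c(msg, "intensities must be >= 0")
    if (length(msg)) msg else TRUE
})

#' SecretomeExperiment: an LFQ protein-group matrix with its design
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding one `"lfq"` assay of label-free quantification intensities
#' (missing values as `NA`; zeros in a MaxQuant export denote missing and are
#' converted on construction). Row metadata carries the protein-group
#' identity and quality flags; column metadata carries the sample design
#' (`group`: e.g. WT / KO_A / KO_B; `clone`: the cell line within a group).
#'
#' Required `rowData` columns: `id` (group key), `members` (semicolon-joined
#' accessions), `peptides` (distinct-peptide count), and logical flags
#' `contaminant`, `reverse`, `onlyBySite`. Required `colData` columns:
#' `group`, `clone`.
#'
#' @seealso [SecretomeExperiment()], [filterSecretome()], [imputeLfq()],
#'   [differentialTest()]
#' @exportClass SecretomeExperiment
setClass("SecretomeExperiment", contains = "SummarizedExperiment")

setValidity("SecretomeExperiment", function(object) {
    msg <- character(0)
    if (!"lfq" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "an assay named 'lfq' is required")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("id", "members", "peptides", "contaminant", "reverse",
        "onlyBySite")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("missing rowData column(s): ",
            paste(miss, collapse = ", ")))
    cd <- SummarizedExperiment::colData(object)
    cmiss <- setdiff(c("group", "clone"), colnames(cd))
    if (length(cmiss))
        msg <- c(msg, paste0("missing colData column(s): ",
            paste(cmiss, collapse = ", ")))
    if (!length(cmiss) && length(unique(cd$group)) < 2L)
        msg <- c(msg, "design must contain at least two sample groups")
    if ("lfq" %in% SummarizedExperiment::assayNames(object)) {
        a <- SummarizedExperiment::assay(object, "lfq")
        if (any(a <= 0, na.rm = TRUE))
            msg <- c(msg, "LFQ intensities must be positive or NA")
    }
    if (length(msg)) msg else TRUE
})
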