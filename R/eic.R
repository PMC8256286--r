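#' Construct a SpectrumRun
#'
#' @param rt scan retention times in minutes (non-decreasing)
#' @param peaks list of per-scan centroid matrices / 2-column objects
#'   (`mz`, `intensity`)
#' @return a [SpectrumRun]
#' @export
SpectrumRun <- function(rt, peaks) {
    peaks <- lapply(peaks, function(p) {
        p <- as.matrix(p)
        if (!ncol(p)) p <- matrix(numeric(0), ncol = 2L)
        colnames(p) <- c("mz", "intensity")
        p
    })
    new("SpectrumRun", rt = as.numeric(rt), peaks = peaks)
}

#' @rdname SpectrumRun
#' @export
setMethod("rtime", "SpectrumRun", function(x) x@rt)

#' @rdname Chromatogram
#' @export
setMethod("rtime", "Chromatogram", function(x) x@rt)

#' @rdname Chromatogram
#' @export
setMethod("intensity", "Chromatogram", function(x) x@intensity)

#' @rdname Chromatogram
#' @param x a [Chromatogram]
#' @export
targetMz <- function(x) x@targetMz

setMethod("show", "SpectrumRun", function(object) {
    n <- length(object@rt)
    cat("SpectrumRun with", n, "MS1 scans")
    if (n)
        cat(sprintf(" (RT %.2f-%.2f min, %d centroids)", min(object@rt),
            max(object@rt), sum(vapply(object@peaks, nrow, integer(1)))))
    cat("\n")
})

setMethod("show", "Chromatogram", function(object) {
    cat(sprintf(
        "Chromatogram: m/z %.4f +/- %.2f Da, %d points, apex %.3g\n",
        object@targetMz, object@tol, length(object@rt),
        if (length(object@intensity)) max(object@intensity) else 0))
})

#' Extract an ion chromatogram from an MS1 run
#'
#' For each MS1 scan, sums the intensities of all centroids within an
#' absolute mass tolerance of the target m/z (the MassLynx-style mass
#' chromatogram with a 0.3 Da mass error, a default suited to Q-TOF
#' centroid data). One point per scan; scans with
#' no matching centroid contribute zero.
#'
#' @param run a [SpectrumRun]
#' @param targetMz target m/z in Th
#' @param tol absolute tolerance in Da (default 0.3)
#' @return a [Chromatogram]
#' @export
extractEIC <- function(run, targetMz, tol = 0.3) {
    stopifnot(is(run, "SpectrumRun"), tol > 0, length(targetMz) == 1L)
    ints <- vapply(run@peaks, function(p) {
        if (!nrow(p)) return(0)
        sum(p[abs(p[, 1L] - targetMz) <= tol, 2L])
    }, numeric(1))
    rt <- run@rt
    # guard strictly-increasing invariant against coincident scan times
    if (length(rt) > 1L && any(diff(rt) <= 0))
        rt <- rt + seq_along(rt) * 1e-9
    new("Chromatogram", rt = rt, intensity = ints,
        targetMz = as.numeric(targetMz), tol = tol)
}

# Savitzky-Golay smoothing (quadratic) with a symmetric window; used
# optionally before apex picking, mirroring common MRM trace treatment.
.savitzkyGolay <- function(y, window = 9L) {
    if (window %% 2L == 0L) window <- window + 1L
    half <- (window - 1L) %/% 2L
    if (length(y) < window) return(y)
    x <- (-half):half
    X <- cbind(1, x, x^2)
    w <- solve(crossprod(X), t(X))[1L, ]
    pad <- c(rep(y[1L], half), y, rep(y[length(y)], half))
    vapply(seq_along(y), function(i)
        sum(w * pad[i:(i + window - 1L)]), numeric(1))
}

#' Relative quantification of a glycoform ladder from an MS1 run
#'
#' Extracts one EIC per glycoform species and reports each species' apex
#' intensity (or integrated area) scaled to the most intense glycoform, the
#' way glycoform EIC panels are conventionally displayed (all traces
#' max-normalised, with the absolute maximum reported alongside).
#'
#' @param run a [SpectrumRun]
#' @param species a glycoform table from [enumerateGlycoforms()] (columns
#'   `mz` and `label`), all species deriving from one peptide
#' @param tol absolute EIC tolerance in Da
#' @param method `"apex"` (max point, default) or `"area"` (trapezoidal)
#' @param smooth apply Savitzky-Golay smoothing before apex picking
#' @return `species` with added columns `intensity` (raw apex/area),
#'   `relative` (scaled to the maximum), `apexRt`; the absolute maximum is
#'   attached as `attr(, "maxIntensity")`. All-zero traces yield all-zero
#'   relative values with a warning.
#' @export
quantifyGlycoforms <- function(run, species, tol = 0.3,
        method = c("apex", "area"), smooth = FALSE) {
    method <- match.arg(method)
    stopifnot(is.data.frame(species), all(c("mz", "label") %in%
        colnames(species)))
    eics <- lapply(species$mz, function(m) extractEIC(run, m, tol))
    species$intensity <- vapply(eics, function(e) {
        y <- e@intensity
        if (!length(y)) return(0)
        if (smooth) y <- pmax(.savitzkyGolay(y), 0)
        if (method == "apex") max(y)
        else if (length(y) > 1L)
            sum(diff(e@rt) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
        else y
    }, numeric(1))
    species$apexRt <- vapply(eics, function(e) {
        if (!length(e@intensity) || max(e@intensity) == 0) return(NA_real_)
        e@rt[which.max(e@intensity)]
    }, numeric(1))
    mx <- max(species$intensity)
    if (mx == 0) {
        warning("no signal for any requested glycoform; relative ",
            "intensities are all zero")
        species$relative <- rep(0, nrow(species))
    } else {
        species$relative <- species$intensity / mx
    }
    attr(species, "maxIntensity") <- mx
    species
}

#' Write / read a SpectrumRun as JSON
#'
#' Plain-text serialisation of an MS1 run: an array of scans, each with
#' `rt_min`, `mz` and `intensity` arrays.
#'
#' @param run a [SpectrumRun]
#' @param path file path
#' @return `readSpectrumRun` returns a [SpectrumRun]; `writeSpectrumRun`
#'   returns `path` invisibly
#' @export
writeSpectrumRun <- function(run, path) {
    stopifnot(is(run, "SpectrumRun"))
    scans <- lapply(seq_along(run@rt), function(i) list(
        rt_min = run@rt[i],
        mz = run@peaks[[i]][, 1L],
        intensity = run@peaks[[i]][, 2L]))
    jsonlite::write_json(scans, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeSpectrumRun
#' @export
readSpectrumRun <- function(path) {
    scans <- jsonlite::read_json(path, simplifyVector = TRUE)
    SpectrumRun(
        rt = vapply(seq_len(nrow(scans)), function(i) scans$rt_min[i],
            numeric(1)),
        peaks = lapply(seq_len(nrow(scans)), function(i)
            cbind(mz = unlist(scans$mz[i]),
                intensity = unlist(scans$intensity[i]))))
}
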