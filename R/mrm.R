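# Linear collision-energy seed parameters per precursor charge. Shared
# slope with a charge-decreasing intercept, so the seed never grows with
# charge at fixed m/z (higher charge states need less collision energy per
# transition in QqQ practice). Starting points only, meant to be overridden
# after per-transition optimisation.
.CE_PARAMS <- list(
    "2" = c(slope = 0.0360, intercept = 8.857),
    "3" = c(slope = 0.0360, intercept = 4.800),
    "4" = c(slope = 0.0360, intercept = 3.300)
)

#' Default collision-energy seed for a transition
#'
#' Linear-in-m/z starting values, `CE = slope * precursorMz + intercept`,
#' with a charge-dependent intercept that decreases with charge (charges
#' above 4 reuse the charge-4 line), so the default never increases with
#' charge at fixed m/z. These are seeds for manual per-transition
#' optimisation, not optimised values.
#'
#' @param precursorMz precursor m/z in Th
#' @param charge precursor charge (>= 2)
#' @return collision energy in volts
#' @export
defaultCollisionEnergy <- function(precursorMz, charge) {
    stopifnot(all(charge >= 2L))
    key <- as.character(pmin(pmax(charge, 2L), 4L))
    slope <- vapply(key, function(k) .CE_PARAMS[[k]]["slope"], numeric(1))
    intercept <- vapply(key, function(k) .CE_PARAMS[[k]]["intercept"],
        numeric(1))
    unname(slope * precursorMz + intercept)
}

#' Enumerate candidate MRM transitions for a (glyco)peptide species
#'
#' Builds the full Cartesian product of precursor charges and singly
#' protonated b/y product ions, then filters to the instrument's m/z window
#' (default 250-1250 Th applied to both precursor and product). Glycan site
#' modifications are carried into precursor masses and, by default, into
#' every product ion containing a modified residue.
#'
#' @param peptide a [GlycoPeptide] or plain sequence string
#' @param siteMods named vector of glycan modifications as in
#'   [fragmentIons()]; applied to the precursor and (if
#'   `glycanOnProducts`) to products
#' @param precursorCharges precursor charge states (default 2:4)
#' @param mzMin,mzMax instrument m/z window (default 250-1250)
#' @param glycanOnProducts carry glycan masses on product ions (default
#'   TRUE; FALSE enumerates products of the bare peptide backbone)
#' @param ce optional named or per-row collision-energy override; default
#'   uses [defaultCollisionEnergy()]
#' @return a data.frame with columns `peptide`, `precursorMz`,
#'   `precursorCharge`, `productMz`, `productLabel`, `ce`, ordered by
#'   precursor charge then product series/index; zero rows are allowed (the
#'   window may exclude everything)
#' @examples
#' nrow(enumerateTransitions("SAMPLER", mzMin = 0, mzMax = Inf,
#'     precursorCharges = 2))  # 2 * (7 - 1) = 12
#' @export
enumerateTransitions <- function(peptide, siteMods = NULL,
        precursorCharges = 2:4, mzMin = 250, mzMax = 1250,
        glycanOnProducts = TRUE, ce = NULL) {
    if (!is(peptide, "GlycoPeptide"))
        peptide <- GlycoPeptide(peptide)
    stopifnot(mzMin <= mzMax, all(precursorCharges >= 1L))
    neutral <- peptideNeutralMass(peptide) +
        sum(.siteModMasses(peptide, siteMods))
    products <- fragmentIons(peptide,
        siteMods = if (glycanOnProducts) siteMods else NULL)
    out <- do.call(rbind, lapply(sort(as.integer(precursorCharges)),
        function(z) {
            pm <- mzFromMass(neutral, z)
            data.frame(
                peptide = peptide@sequence,
                precursorMz = pm,
                precursorCharge = z,
                productMz = products$mz,
                productLabel = products$label,
                stringsAsFactors = FALSE)
        }))
    keep <- out$precursorMz >= mzMin & out$precursorMz <= mzMax &
        out$productMz >= mzMin & out$productMz <= mzMax
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
    if (is.null(ce)) {
        out$ce <- if (nrow(out))
            defaultCollisionEnergy(out$precursorMz,
                pmax(out$precursorCharge, 2L))
        else numeric(0)
    } else {
        out$ce <- rep_len(as.numeric(ce), nrow(out))
    }
    out
}

#' Schedule MRM transitions into retention-time windows
#'
#' Assigns each transition a detection window centred on its expected
#' retention time (default width 300 s) with a target scan time (default
#' 1.8 s). Transitions without a known retention time are placed in an
#' unscheduled block (`scheduled = FALSE`, window columns `NA`).
#'
#' @param transitions a data.frame from [enumerateTransitions()]
#' @param rtMap named numeric vector mapping peptide sequences to expected
#'   retention times in minutes (or a single value recycled to all rows)
#' @param windowWidth detection window width in seconds (default 300)
#' @param targetScanTime target scan time in seconds (default 1.8)
#' @return `transitions` with added columns `expectedRt`, `windowStart`,
#'   `windowEnd` (minutes), `windowWidth`, `targetScanTime` (seconds),
#'   `scheduled`
#' @export
scheduleTransitions <- function(transitions, rtMap = NULL,
        windowWidth = 300, targetScanTime = 1.8) {
    stopifnot(is.data.frame(transitions), windowWidth > 0)
    n <- nrow(transitions)
    rt <- rep(NA_real_, n)
    if (!is.null(rtMap) && length(rtMap)) {
        if (is.null(names(rtMap)))
            rt <- rep_len(as.numeric(rtMap), n)
        else {
            hit <- match(transitions$peptide, names(rtMap))
            rt <- as.numeric(rtMap)[hit]
        }
    }
    half <- windowWidth / 60 / 2
    transitions$expectedRt <- rt
    transitions$windowStart <- rt - half
    transitions$windowEnd <- rt + half
    transitions$windowWidth <- ifelse(is.na(rt), NA_real_, windowWidth)
    transitions$targetScanTime <- targetScanTime
    transitions$scheduled <- !is.na(rt)
    transitions
}

#' Write a transition list as CSV
#'
#' Vendor-importable flat table: peptide, precursor m/z and charge, product
#' m/z and label, collision energy, window centre and width.
#'
#' @param transitions a (scheduled or unscheduled) transition data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeTransitionList <- function(transitions, path) {
    cols <- c(peptide = "peptide", precursor_mz = "precursorMz",
        precursor_charge = "precursorCharge", product_mz = "productMz",
        product_label = "productLabel", collision_energy = "ce",
        rt_center_min = "expectedRt", window_s = "windowWidth")
    present <- cols[cols %in% colnames(transitions)]
    out <- transitions[, present, drop = FALSE]
    colnames(out) <- names(present)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
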