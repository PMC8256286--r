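#' Construct a GlycoPeptide
#'
#' @param sequence upper-case amino-acid string (20 standard residues)
#' @param nConsensusTrp number of C-mannosylatable tryptophans; defaults to
#'   the number of WxxW/WxxC consensus sites found within the peptide itself.
#'   Pass it explicitly when a tryptophan's consensus context extends beyond
#'   the peptide's C terminus.
#' @param hasOFucSite whether the peptide carries an O-fucosylation site
#' @param oFucPosition 1-based position of the O-fucose acceptor (optional)
#' @param carbamidomethyl apply the Cys fixed modification (+57.02146 Da)
#' @return a [GlycoPeptide] object
#' @examples
#' GlycoPeptide("WSDWSSWSPC", nConsensusTrp = 3)
#' @export
GlycoPeptide <- function(sequence, nConsensusTrp = NULL, hasOFucSite = FALSE,
        oFucPosition = NA_integer_, carbamidomethyl = TRUE) {
    if (is.null(nConsensusTrp))
        nConsensusTrp <- nrow(scanConsensusSites(sequence))
    new("GlycoPeptide",
        sequence = toupper(sequence),
        nConsensusTrp = as.integer(nConsensusTrp),
        hasOFucSite = isTRUE(hasOFucSite),
        oFucPosition = as.integer(oFucPosition),
        carbamidomethyl = isTRUE(carbamidomethyl))
}

#' @rdname GlycoPeptide
#' @export
setMethod("peptideSequence", "GlycoPeptide", function(x) x@sequence)

#' @rdname GlycoPeptide
#' @export
setMethod("nConsensusTrp", "GlycoPeptide", function(x) x@nConsensusTrp)

setMethod("show", "GlycoPeptide", function(object) {
    cat("GlycoPeptide:", object@sequence, "\n")
    cat("  neutral mass:", format(peptideNeutralMass(object), nsmall = 5),
        "Da\n")
    cat("  consensus Trp:", object@nConsensusTrp,
        "| O-fucose site:", object@hasOFucSite,
        "| carbamidomethyl:", object@carbamidomethyl, "\n")
})

#' Enumerate the glycoform ladder of a peptide
#'
#' Builds the full Cartesian set of glycoforms: hexose count 0 to
#' `nConsensusTrp` crossed with the O-fucosyl states (`none`, and
#' additionally `Fuc` and `FucGlc` when the peptide has an O-fucose site).
#' A peptide with three consensus tryptophans and an O-fucose site yields
#' the 12-species ladder (Hex0-3 x {none, Fuc, FucGlc}); without the fucose
#' site, the 4-species Hex ladder.
#'
#' @param peptide a [GlycoPeptide]
#' @param charges integer vector of precursor charges to report m/z for
#' @return a data.frame, ordered by `nHex` ascending then fucosyl state
#'   (`none` < `Fuc` < `FucGlc`) then charge, with columns `nHex`,
#'   `fucosylState`, `charge`, `neutralMass`, `mz`, `label`
#' @examples
#' p <- GlycoPeptide("WSDWSSWSPC", nConsensusTrp = 3, hasOFucSite = TRUE)
#' nrow(enumerateGlycoforms(p))  # 12
#' @export
enumerateGlycoforms <- function(peptide, charges = 1L) {
    stopifnot(is(peptide, "GlycoPeptide"), all(charges >= 1L))
    fuc <- if (peptide@hasOFucSite) .FUCOSYL_STATES else "none"
    grid <- expand.grid(
        charge = as.integer(charges),
        fucosylState = factor(fuc, levels = .FUCOSYL_STATES),
        nHex = 0:peptide@nConsensusTrp,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$nHex, grid$fucosylState, grid$charge), , drop = FALSE]
    grid$fucosylState <- as.character(grid$fucosylState)
    grid$neutralMass <- mapply(function(h, f) glycoMass(peptide, h, f),
        grid$nHex, grid$fucosylState)
    grid$mz <- mzFromMass(grid$neutralMass, grid$charge)
    grid$label <- paste0(
        "Hex", grid$nHex,
        ifelse(grid$fucosylState == "none", "",
            paste0("+", grid$fucosylState)),
        " [", grid$charge, "+]")
    rownames(grid) <- NULL
    grid[, c("nHex", "fucosylState", "charge", "neutralMass", "mz", "label")]
}

# Resolve site modifications into a per-residue glycan mass vector.
# siteMods: named numeric (position -> Da) or named character with glycan
# names from c("Hex", "Fuc", "FucGlc").
.siteModMasses <- function(peptide, siteMods) {
    n <- nchar(peptide@sequence)
    delta <- numeric(n)
    if (is.null(siteMods) || !length(siteMods))
        return(delta)
    pos <- as.integer(names(siteMods))
    if (anyNA(pos) || any(pos < 1L) || any(pos > n))
        stop("modification positions must lie within the peptide (1..", n,
            ")", call. = FALSE)
    if (is.character(siteMods)) {
        lut <- c(Hex = .MASS_HEX, Fuc = .MASS_DHEX,
            FucGlc = .MASS_DHEX + .MASS_HEX)
        bad <- setdiff(siteMods, names(lut))
        if (length(bad))
            stop("unknown glycan(s): ", paste(bad, collapse = ", "),
                call. = FALSE)
        siteMods <- lut[siteMods]
    }
    delta[pos] <- delta[pos] + as.numeric(siteMods)
    delta
}

#' Singly protonated b and y fragment ions
#'
#' Computes the m/z of b_i and y_j ions of a peptide, with glycan masses
#' carried by every fragment containing the modified residue (the C-mannose
#' is treated as non-labile, which is what makes modified-site assignment
#' from fragment series possible).
#'
#' @param peptide a [GlycoPeptide]
#' @param siteMods named vector mapping 1-based residue positions to glycan
#'   masses (Da) or glycan names (`"Hex"`, `"Fuc"`, `"FucGlc"`); `NULL` for
#'   the unmodified peptide
#' @param series which ion series to compute (subset of `c("b", "y")`)
#' @param maxIndex largest fragment index (default `n - 1`)
#' @return a data.frame with columns `label` (e.g. `"b3"`, `"y5"`), `series`,
#'   `index`, `mz`
#' @examples
#' fragmentIons(GlycoPeptide("AG"))  # y1 = 76.03931
#' @export
fragmentIons <- function(peptide, siteMods = NULL, series = c("b", "y"),
        maxIndex = NULL) {
    stopifnot(is(peptide, "GlycoPeptide"))
    series <- match.arg(series, c("b", "y"), several.ok = TRUE)
    n <- nchar(peptide@sequence)
    if (is.null(maxIndex))
        maxIndex <- n - 1L
    if (maxIndex < 1L || maxIndex > n - 1L)
        stop("maxIndex must lie in 1..", n - 1L, call. = FALSE)
    res <- .residueMasses(peptide@sequence, peptide@carbamidomethyl) +
        .siteModMasses(peptide, siteMods)
    out <- list()
    idx <- seq_len(maxIndex)
    if ("b" %in% series) {
        bmz <- cumsum(res)[idx] + .MASS_PROTON
        out$b <- data.frame(label = paste0("b", idx), series = "b",
            index = idx, mz = bmz, stringsAsFactors = FALSE)
    }
    if ("y" %in% series) {
        ymz <- rev(cumsum(rev(res)))[n - idx + 1L] + .MASS_WATER + .MASS_PROTON
        out$y <- data.frame(label = paste0("y", idx), series = "y",
            index = idx, mz = ymz, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
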