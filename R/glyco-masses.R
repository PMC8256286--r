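# Monoisotopic constants (Da). Residue masses are the standard amino-acid
# residue (dehydrated) monoisotopic masses.
.AA_MONO <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_WATER <- 18.010565
.MASS_PROTON <- 1.007276
.MASS_CAM <- 57.02146      # carbamidomethyl on Cys (fixed modification)
.MASS_HEX <- 162.05282     # hexose (C-mannose / glucose)
.MASS_DHEX <- 146.05791    # deoxyhexose (O-fucose)

.FUCOSYL_STATES <- c("none", "Fuc", "FucGlc")

.fucosylDelta <- function(state) {
    state <- match.arg(state, .FUCOSYL_STATES)
    switch(state,
        none = 0,
        Fuc = .MASS_DHEX,
        FucGlc = .MASS_DHEX + .MASS_HEX)
}

.residueMasses <- function(sequence, carbamidomethyl = TRUE) {
    chars <- strsplit(sequence, "")[[1L]]
    m <- .AA_MONO[chars]
    if (anyNA(m)) {
        bad <- unique(chars[is.na(m)])
        stop("unknown residue(s) in '", sequence, "': ",
            paste(bad, collapse = ", "), call. = FALSE)
    }
    if (carbamidomethyl)
        m[chars == "C"] <- m[chars == "C"] + .MASS_CAM
    unname(m)
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sums the residue monoisotopic masses, adds one water, and applies fixed
#' modifications (carbamidomethyl, +57.02146 Da per Cys, on by default).
#'
#' @param x a [GlycoPeptide] object or a plain amino-acid string
#' @param carbamidomethyl apply the Cys fixed modification (ignored when `x`
#'   is a [GlycoPeptide], which carries its own flag)
#' @return neutral monoisotopic mass in Da
#' @examples
#' peptideNeutralMass("G")        # 75.03203
#' peptideNeutralMass("WSDWSSWSPC")
#' @export
peptideNeutralMass <- function(x, carbamidomethyl = TRUE) {
    if (is(x, "GlycoPeptide")) {
        carbamidomethyl <- x@carbamidomethyl
        x <- x@sequence
    }
    stopifnot(is.character(x), length(x) == 1L, !is.na(x))
    if (nchar(x) == 0L)
        stop("empty peptide sequence", call. = FALSE)
    sum(.residueMasses(x, carbamidomethyl)) + .MASS_WATER
}

#' Neutral mass of a glycopeptide species
#'
#' Adds `nHex` C-mannose (hexose) masses and the mass of the O-fucosyl state
#' (`none`, `Fuc` = deoxyhexose, `FucGlc` = deoxyhexose + hexose) to the
#' peptide's neutral mass. One C-mannose adds 162.05282 Da.
#'
#' @param peptide a [GlycoPeptide]
#' @param nHex number of C-mannoses (0 to `nConsensusTrp(peptide)`)
#' @param fucosylState one of `"none"`, `"Fuc"`, `"FucGlc"`
#' @return neutral monoisotopic mass in Da
#' @examples
#' p <- GlycoPeptide("WSDWSSWSPC", nConsensusTrp = 3)
#' glycoMass(p, 1) - glycoMass(p, 0)   # 162.05282
#' @export
glycoMass <- function(peptide, nHex = 0L, fucosylState = "none") {
    stopifnot(is(peptide, "GlycoPeptide"))
    fucosylState <- match.arg(fucosylState, .FUCOSYL_STATES)
    nHex <- as.integer(nHex)
    if (nHex < 0L || nHex > peptide@nConsensusTrp)
        stop("nHex must lie in 0..", peptide@nConsensusTrp,
            " (number of consensus tryptophans)", call. = FALSE)
    if (fucosylState != "none" && !peptide@hasOFucSite)
        stop("fucosyl state '", fucosylState,
            "' requires an O-fucosylation site", call. = FALSE)
    peptideNeutralMass(peptide) + nHex * .MASS_HEX + .fucosylDelta(fucosylState)
}

#' m/z of an ion from its neutral mass and charge
#'
#' @param neutralMass neutral monoisotopic mass in Da
#' @param charge positive integer charge (protonation)
#' @return m/z in Th
#' @export
mzFromMass <- function(neutralMass, charge) {
    stopifnot(all(charge >= 1L))
    (neutralMass + charge * .MASS_PROTON) / charge
}
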