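# Independent oracles, deliberately built from first principles (elemental
# compositions and explicit window/loop enumeration) rather than from the
# package's own mass table or scanners.

.ELEM <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
    O = 15.9949146221, S = 31.97207069)

.compMass <- function(C = 0, H = 0, N = 0, O = 0, S = 0) {
    C * .ELEM["C"] + H * .ELEM["H"] + N * .ELEM["N"] + O * .ELEM["O"] +
        S * .ELEM["S"]
}

# Residue (dehydrated amino-acid) masses from elemental composition.
oracleResidueMass <- local({
    f <- list(
        G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
        P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
        C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
        N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
        K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
        H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
        Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
    m <- vapply(f, function(x)
        unname(.compMass(x[1], x[2], x[3], x[4], x[5])), numeric(1))
    function(aa) m[aa]
})

oracleWater <- unname(.compMass(H = 2, O = 1))
oracleProton <- 1.00727646
oracleCam <- unname(.compMass(C = 2, H = 3, N = 1, O = 1))
oracleHex <- unname(.compMass(C = 6, H = 10, O = 5))
oracleDHex <- unname(.compMass(C = 6, H = 10, O = 4))

oraclePeptideMass <- function(seq, cam = TRUE) {
    aa <- strsplit(seq, "")[[1]]
    m <- sum(oracleResidueMass(aa)) + oracleWater
    if (cam) m <- m + sum(aa == "C") * oracleCam
    m
}

# Brute-force consensus-site scan: test every index explicitly.
oracleScan <- function(seq) {
    n <- nchar(seq)
    out <- data.frame(position = integer(0), kind = character(0))
    tolerated <- c(strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]],
        "X", "U", "B", "Z")
    if (n < 4) return(out)
    for (i in 1:(n - 3)) {
        w <- substring(seq, i:(i + 3), i:(i + 3))
        if (!all(w %in% tolerated)) next
        if (w[1] != "W") next
        if (w[4] == "W")
            out <- rbind(out, data.frame(position = i, kind = "WxxW"))
        else if (w[4] == "C")
            out <- rbind(out, data.frame(position = i, kind = "WxxC"))
    }
    out
}

# Hypergeometric upper-tail sum for a one-sided (enrichment) Fisher test.
oracleFisherTail <- function(k, n, K, N) {
    i <- k:min(n, K)
    sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Exhaustive MRM transition enumeration with oracle masses: every
# precursor charge crossed with every b/y index, then filtered.
oracleTransitions <- function(seq, charges = 2:4, mzMin = 250,
        mzMax = 1250, cam = TRUE) {
    aa <- strsplit(seq, "")[[1]]
    res <- oracleResidueMass(aa) + ifelse(aa == "C" & cam, oracleCam, 0)
    n <- length(aa)
    neutral <- sum(res) + oracleWater
    rows <- list()
    for (z in charges) {
        pm <- (neutral + z * oracleProton) / z
        for (i in 1:(n - 1)) {
            b <- sum(res[1:i]) + oracleProton
            y <- sum(res[(n - i + 1):n]) + oracleWater + oracleProton
            for (prod in list(c("b", b), c("y", y))) {
                mz <- as.numeric(prod[2])
                if (pm >= mzMin && pm <= mzMax && mz >= mzMin &&
                        mz <= mzMax)
                    rows[[length(rows) + 1]] <- data.frame(
                        precursorCharge = z,
                        precursorMz = pm,
                        label = paste0(prod[1], i),
                        productMz = mz)
            }
        }
    }
    if (!length(rows))
        return(data.frame(precursorCharge = integer(0),
            precursorMz = numeric(0), label = character(0),
            productMz = numeric(0)))
    do.call(rbind, rows)
}

randomPeptide <- function(len, letters = strsplit("GASPVTCLINDQKEMHFRYW",
        "")[[1]]) {
    paste(sample(letters, len, replace = TRUE), collapse = "")
}
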