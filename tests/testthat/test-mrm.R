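test_that("one charge with an unbounded window yields the full b/y ladder", {
    tr <- enumerateTransitions("SAMPLER", precursorCharges = 2,
        mzMin = 0, mzMax = Inf)
    expect_equal(nrow(tr), 2 * (nchar("SAMPLER") - 1))
    expect_equal(sort(unique(tr$productLabel)),
        sort(c(paste0("b", 1:6), paste0("y", 1:6))))
})

test_that("enumeration matches the exhaustive oracle on random peptides", {
    set.seed(41)
    for (i in 1:50) {
        s <- randomPeptide(sample(5:20, 1))
        got <- enumerateTransitions(s)
        want <- oracleTransitions(s)
        expect_equal(nrow(got), nrow(want), info = s)
        expect_equal(sort(got$productMz), sort(want$productMz),
            tolerance = 1e-5, info = s)
        expect_equal(sort(got$precursorMz), sort(want$precursorMz),
            tolerance = 1e-5, info = s)
    }
})

test_that("an impossible window yields an empty list; filtering is monotone", {
    expect_equal(nrow(enumerateTransitions("SAMPLER", mzMin = 0,
        mzMax = 1)), 0L)
    set.seed(43)
    for (i in 1:10) {
        s <- randomPeptide(10)
        narrow <- enumerateTransitions(s, mzMin = 400, mzMax = 900)
        wide <- enumerateTransitions(s, mzMin = 250, mzMax = 1250)
        key <- function(d) paste(d$precursorCharge, d$productLabel)
        expect_true(all(key(narrow) %in% key(wide)))
    }
})

test_that("glycan site mods shift precursors always and products on demand", {
    s <- "WAGKRLE"
    bare <- enumerateTransitions(s, precursorCharges = 2, mzMin = 0,
        mzMax = Inf)
    mod <- enumerateTransitions(s, siteMods = c("1" = "Hex"),
        precursorCharges = 2, mzMin = 0, mzMax = Inf)
    expect_equal(unique(mod$precursorMz - bare$precursorMz),
        oracleHex / 2, tolerance = 1e-6)
    b1shift <- mod$productMz[mod$productLabel == "b1"] -
        bare$productMz[bare$productLabel == "b1"]
    expect_equal(b1shift, oracleHex, tolerance = 1e-6)
    noprod <- enumerateTransitions(s, siteMods = c("1" = "Hex"),
        precursorCharges = 2, mzMin = 0, mzMax = Inf,
        glycanOnProducts = FALSE)
    expect_equal(noprod$productMz, bare$productMz)
})

test_that("collision-energy seeds are linear and never grow with charge", {
    expect_equal(defaultCollisionEnergy(0, 2), 8.857)
    expect_equal(defaultCollisionEnergy(500, 2), 0.036 * 500 + 8.857)
    for (mz in c(300, 600, 900, 1200)) {
        ce <- defaultCollisionEnergy(rep(mz, 3), 2:4)
        expect_true(all(diff(ce) <= 0), info = mz)
    }
    # user-supplied CE overrides computed values exactly
    tr <- enumerateTransitions("SAMPLER", ce = 31.5)
    expect_true(all(tr$ce == 31.5))
})

test_that("scheduling centres 300 s windows on the expected RT", {
    tr <- enumerateTransitions("SAMPLER")
    sch <- scheduleTransitions(tr, rtMap = c(SAMPLER = 20))
    expect_true(all(sch$scheduled))
    expect_equal(unique(sch$windowStart), 17.5)
    expect_equal(unique(sch$windowEnd), 22.5)
    expect_equal(unique(sch$windowWidth), 300)
    expect_equal(unique(sch$targetScanTime), 1.8)
    # no RT map: everything lands in the unscheduled block
    un <- scheduleTransitions(tr)
    expect_true(all(!un$scheduled))
    expect_true(all(is.na(un$windowStart)))
    # co-eluting peptides share identical windows
    both <- rbind(enumerateTransitions("SAMPLER"),
        enumerateTransitions("ELPMASK"))
    sch2 <- scheduleTransitions(both,
        rtMap = c(SAMPLER = 12, ELPMASK = 12))
    expect_equal(length(unique(sch2$windowStart)), 1L)
})

test_that("transition lists export as vendor-importable CSV", {
    tr <- scheduleTransitions(enumerateTransitions("SAMPLER"),
        rtMap = c(SAMPLER = 20))
    f <- withr::local_tempfile(fileext = ".csv")
    writeTransitionList(tr, f)
    back <- read.csv(f)
    expect_equal(nrow(back), nrow(tr))
    expect_true(all(c("peptide", "precursor_mz", "product_mz",
        "collision_energy", "rt_center_min", "window_s") %in%
        colnames(back)))
    expect_equal(back$precursor_mz, tr$precursorMz, tolerance = 1e-6)
})
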