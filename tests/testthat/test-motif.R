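test_that("consensus scan finds the three tryptophans of a TSR motif", {
    sites <- scanConsensusSites("WSDWSSWSPC")
    expect_equal(sites$position, c(1L, 4L, 7L))
    expect_equal(sites$kind, c("WxxW", "WxxW", "WxxC"))
    expect_equal(sites$context, c("WSDW", "WSSW", "WSPC"))
})

test_that("consensus scan handles trivial and edge sequences", {
    expect_equal(nrow(scanConsensusSites("ACDEFG")), 0L)
    expect_error(scanConsensusSites(""), "empty")
    # terminal W lacks a +3 partner
    expect_equal(scanConsensusSites("WAAWAAW")$position, c(1L, 4L))
    # sequences shorter than a window
    expect_equal(nrow(scanConsensusSites("WAC")), 0L)
    # overlapping sites are all kept; x may itself be W
    expect_equal(scanConsensusSites("WWWW")$position, 1L)
    expect_equal(nrow(scanConsensusSites("WWWWW")), 2L)
})

test_that("windows containing foreign characters never match", {
    expect_equal(nrow(scanConsensusSites("W*AW")), 0L)
    expect_equal(nrow(scanConsensusSites("W-AC")), 0L)
    # tolerated ambiguity codes in x positions do match
    expect_equal(scanConsensusSites("WXZW")$kind, "WxxW")
})

test_that("scan agrees with a brute-force window oracle on random sequences", {
    set.seed(101)
    for (i in 1:300) {
        len <- sample(4:500, 1)
        s <- randomPeptide(len)
        got <- scanConsensusSites(s)
        want <- oracleScan(s)
        expect_equal(got$position, want$position, info = s)
        expect_equal(got$kind, want$kind, info = s)
    }
})

test_that("scan is position-covariant under prefixing", {
    set.seed(7)
    for (i in 1:25) {
        s <- randomPeptide(80)
        k <- sample(1:20, 1)
        prefix <- paste(rep("A", k), collapse = "")
        expect_equal(scanConsensusSites(paste0(prefix, s))$position,
            scanConsensusSites(s)$position + k)
    }
})

test_that("TSR motifs decompose into consensus sites (W1/W2 WxxW, W3 WxxC)", {
    hits <- findTsrMotifs("WSDWSSWSPC")
    expect_equal(nrow(hits), 1L)
    expect_equal(unlist(hits[1, c("w1", "w2", "w3")], use.names = FALSE),
        c(1L, 4L, 7L))
    expect_equal(nrow(findTsrMotifs("AAAAAAAAAA")), 0L)
    set.seed(11)
    for (i in 1:50) {
        s <- randomPeptide(200)
        hits <- findTsrMotifs(s)
        if (!nrow(hits)) next
        sites <- scanConsensusSites(s)
        for (j in seq_len(nrow(hits))) {
            expect_true(any(sites$position == hits$w1[j] &
                sites$kind == "WxxW"))
            expect_true(any(sites$position == hits$w2[j] &
                sites$kind == "WxxW"))
            expect_true(any(sites$position == hits$w3[j] &
                sites$kind == "WxxC"))
        }
    }
})

test_that("a planted TSR motif in a long inert sequence is found exactly once", {
    set.seed(5)
    for (i in 1:20) {
        bg <- sample(c("A", "G", "S"), 1000, replace = TRUE)
        start <- sample(1:991, 1)
        bg[start + c(0, 3, 6)] <- "W"
        bg[start + 9] <- "C"
        hits <- findTsrMotifs(paste(bg, collapse = ""))
        expect_equal(hits$start, start)
    }
})

test_that("group annotation uses ANY-member semantics and tracks unresolved", {
    db <- c(P1 = "AWSDWSSWSPCA", P2 = "AAAAAA", P3 = "GGGGG")
    groups <- data.frame(
        id = c("g1", "g2", "g3"),
        members = c("P1;P2", "P2;P3", "P9;P8"))
    expect_warning(ann <- annotateGroups(groups, db), "without a sequence")
    expect_equal(ann$hasConsensus, c(TRUE, FALSE, NA))
    expect_equal(ann$nSites, c(3L, 0L, 0L))
    expect_equal(ann$unresolved, c("", "", "P9;P8"))
    # unresolved members of a resolved group are not motif-free evidence
    groups2 <- data.frame(id = "g", members = "P2;P9")
    expect_warning(ann2 <- annotateGroups(groups2, db))
    expect_false(ann2$hasConsensus)
    expect_equal(ann2$unresolved, "P9")
})

test_that("FASTA reading extracts UniProt accessions", {
    f <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">sp|P12345|NAME_HUMAN some description", "WSDWSSWSPC",
        ">plainid other", "ACDEF"), f)
    db <- readProteinDb(f)
    expect_equal(names(db), c("P12345", "plainid"))
    expect_equal(as.character(db[["P12345"]]), "WSDWSSWSPC")
})
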