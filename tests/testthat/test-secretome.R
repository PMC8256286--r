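# Hand-constructed six-group fixture: one contaminant, one reverse match,
# one intracellular protein, one single-peptide id, one detected only once,
# one clean row.
makeToyExperiment <- function() {
    design <- defaultDesign()  # WT n=3 plus two KOs x two clones x 3
    ids <- c("g_cont", "g_rev", "g_cyto", "g_1pep", "g_once", "g_clean")
    lfq <- matrix(2^25, nrow = 6, ncol = nrow(design),
        dimnames = list(ids, design$sample))
    lfq["g_once", ] <- NA
    lfq["g_once", "WT_1"] <- 2^25
    rowData <- data.frame(
        id = ids, members = ids,
        peptides = c(5L, 5L, 5L, 1L, 5L, 5L),
        contaminant = ids == "g_cont",
        reverse = ids == "g_rev",
        onlyBySite = FALSE)
    annotation <- data.frame(
        accession = ids,
        gocc = ifelse(ids == "g_cyto", "cytoplasm", "extracellular region"),
        pfam = ifelse(ids == "g_clean", "TSP_1", ""))
    list(se = SecretomeExperiment(lfq, rowData, design),
        annotation = annotation, design = design)
}

test_that("the Perseus-style filter removes each fixture row for its reason", {
    toy <- makeToyExperiment()
    filt <- filterSecretome(toy$se, toy$annotation)
    expect_equal(filt$report$n,
        c(initial = 6L, no_decoys = 4L, extracellular = 3L,
            min_peptides_detection = 1L, final = 1L),
        ignore_attr = TRUE)
    expect_true(all(diff(filt$report$n) <= 0))
    expect_equal(rownames(filt$se), "g_clean")
    expect_equal(attr(filt$report, "detectedAllLines"), 1L)
})

test_that("detection in both clones of one KO rescues a WT-missing protein", {
    toy <- makeToyExperiment()
    lfq <- SummarizedExperiment::assay(toy$se, "lfq")
    # detected once per clone of KO_A only: passes; spread across two KOs:
    # fails
    lfq["g_once", ] <- NA
    lfq["g_once", c("KO_A_c1_1", "KO_A_c2_2")] <- 2^24
    lfq["g_1pep", ] <- NA
    lfq["g_1pep", c("KO_A_c1_1", "KO_B_c1_1")] <- 2^24
    rd <- as.data.frame(SummarizedExperiment::rowData(toy$se))
    rd$peptides <- 5L
    se <- SecretomeExperiment(lfq, rd, toy$design)
    filt <- filterSecretome(se, toy$annotation)
    expect_true("g_once" %in% rownames(filt$se))
    expect_false("g_1pep" %in% rownames(filt$se))
})

test_that("an empty matrix filters to an empty matrix with zeroed report", {
    toy <- makeToyExperiment()
    empty <- toy$se[integer(0), ]
    filt <- filterSecretome(empty, toy$annotation)
    expect_equal(nrow(filt$se), 0L)
    expect_true(all(filt$report$n == 0L))
    expect_equal(attr(filt$report, "detectedAllLines"), 0L)
})

test_that("imputation draws match the left-shifted normal's moments", {
    nMiss <- 10000L
    set.seed(61)
    obs <- rnorm(100)
    obs <- (obs - mean(obs)) / sd(obs) * 2 + 25  # exact mean 25, sd 2
    design <- data.frame(
        sample = c("a", "b"), group = c("WT", "KO"),
        clone = c("WT", "KO"))
    lfq <- cbind(a = 2^c(obs, rep(NA, nMiss)),
        b = 2^rnorm(100 + nMiss, 25, 2))
    rowData <- data.frame(id = paste0("p", seq_len(nrow(lfq))),
        members = paste0("p", seq_len(nrow(lfq))), peptides = 2L,
        contaminant = FALSE, reverse = FALSE, onlyBySite = FALSE)
    se <- SecretomeExperiment(lfq, rowData, design)
    imp <- imputeLfq(se, seed = 123)
    x <- SummarizedExperiment::assay(imp, "log2imputed")
    mask <- SummarizedExperiment::assay(imp, "imputed")
    drawn <- x[mask[, "a"], "a"]
    expect_length(drawn, nMiss)
    expect_equal(mean(drawn), 25 - 1.8 * 2, tolerance = 0.05 / 21.4)
    expect_lt(abs(sd(drawn) - 0.3 * 2), 0.02)
    # observed cells are untouched (log2 only)
    expect_equal(x[!mask[, "a"], "a"], obs, ignore_attr = TRUE)
    # complete columns come back unchanged
    expect_equal(x[, "b"], log2(lfq[, "b"]), ignore_attr = TRUE)
})

test_that("imputation is reproducible and fails loud on starved columns", {
    sim <- simulateLfqExperiment(nProteins = 50, seed = 11)
    i1 <- imputeLfq(sim$se, seed = 99)
    i2 <- imputeLfq(sim$se, seed = 99)
    expect_identical(SummarizedExperiment::assay(i1, "log2imputed"),
        SummarizedExperiment::assay(i2, "log2imputed"))
    i3 <- imputeLfq(sim$se, seed = 100)
    expect_false(identical(SummarizedExperiment::assay(i1, "log2imputed"),
        SummarizedExperiment::assay(i3, "log2imputed")))
    # a column with < 2 observed values is an error naming the column
    lfq <- SummarizedExperiment::assay(sim$se, "lfq")
    lfq[, "WT_2"] <- NA
    lfq[1, "WT_2"] <- 2^25
    se <- SecretomeExperiment(lfq,
        as.data.frame(SummarizedExperiment::rowData(sim$se)), sim$design)
    expect_error(imputeLfq(se, seed = 1), "WT_2")
    expect_error(imputeLfq(sim$se), "seed")
})

test_that("the Student t test matches a closed-form t CDF oracle", {
    sim <- simulateLfqExperiment(nProteins = 40, seed = 21)
    imp <- imputeLfq(sim$se, seed = 5)
    res <- differentialTest(imp, "KO_A")
    x <- SummarizedExperiment::assay(imp, "log2imputed")
    cd <- SummarizedExperiment::colData(imp)
    ia <- cd$group == "KO_A"
    ib <- cd$group == "WT"
    for (i in seq_len(nrow(x))) {
        a <- x[i, ia]; b <- x[i, ib]
        na <- length(a); nb <- length(b)
        sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
        tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
        p <- 2 * pt(-abs(tt), na + nb - 2)
        expect_equal(res$t[i], tt, tolerance = 1e-8)
        expect_equal(res$p[i], p, tolerance = 1e-8)
        expect_equal(res$log2fc[i], mean(a) - mean(b), tolerance = 1e-10)
    }
    expect_true(all(res$significant == (res$p <= 0.05)))
})

test_that("degenerate rows follow the stated conventions", {
    design <- defaultDesign()
    lfq <- matrix(2^20, nrow = 2, ncol = nrow(design),
        dimnames = list(c("flat", "split"), design$sample))
    lfq["split", design$group == "KO_A"] <- 2^22
    rowData <- data.frame(id = rownames(lfq), members = rownames(lfq),
        peptides = 2L, contaminant = FALSE, reverse = FALSE,
        onlyBySite = FALSE)
    se <- imputeLfq(SecretomeExperiment(lfq, rowData, design), seed = 1)
    res <- differentialTest(se, "KO_A")
    expect_equal(res[res$id == "flat", "p"], 1)
    expect_equal(res[res$id == "flat", "log2fc"], 0)
    expect_false(res[res$id == "flat", "significant"])
    expect_equal(res[res$id == "split", "p"], 0)
    expect_equal(res[res$id == "split", "log2fc"], 2)
})

test_that("per-clone fold changes match hand arithmetic", {
    design <- defaultDesign()
    lfq <- matrix(2^20, nrow = 2, ncol = nrow(design),
        dimnames = list(c("p1", "p2"), design$sample))
    lfq[1, design$clone == "KO_A_c1"] <- 2^21          # +1 in clone A1
    lfq[1, design$clone == "KO_A_c2"] <- 2^23          # +3 in clone A2
    rowData <- data.frame(id = c("p1", "p2"), members = c("p1", "p2"),
        peptides = 2L, contaminant = FALSE, reverse = FALSE,
        onlyBySite = FALSE)
    se <- imputeLfq(SecretomeExperiment(lfq, rowData, design), seed = 1)
    fc <- perCloneFoldChanges(se)
    ps <- fc$perSample[fc$perSample$id == "p1", ]
    pg <- fc$perGroup[fc$perGroup$id == "p1", ]
    expect_equal(ps$log2fc[ps$clone == "KO_A_c1"], rep(1, 3))
    expect_equal(pg$meanLog2fc[pg$group == "KO_A"], 2)  # (1+3)/2
    expect_equal(pg$meanLog2fc[pg$group == "KO_B"], 0)
    # samples equal to the WT mean give zero fold changes throughout
    expect_true(all(fc$perSample$log2fc[fc$perSample$id == "p2"] == 0))
    # balanced groups: mean of per-sample fold changes equals fc of means
    res <- differentialTest(se, "KO_A")
    expect_equal(res$log2fc[res$id == "p1"],
        mean(ps$log2fc[ps$group == "KO_A"]))
})
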