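test_that("protein-db generator is seed-deterministic and truth-exact", {
    db1 <- simulateProteinDb(60, motifFraction = 0.5, seed = 81)
    db2 <- simulateProteinDb(60, motifFraction = 0.5, seed = 81)
    expect_identical(as.character(db1$sequences),
        as.character(db2$sequences))
    db3 <- simulateProteinDb(60, motifFraction = 0.5, seed = 82)
    expect_false(identical(as.character(db1$sequences),
        as.character(db3$sequences)))
    # every planted site is recovered, and nothing else is found
    for (id in names(db1$sequences)) {
        got <- scanConsensusSites(as.character(db1$sequences[[id]]))
        want <- db1$truth[[id]]$sites
        expect_equal(got$position, want$position, info = id)
        expect_equal(got$kind, want$kind, info = id)
    }
    expect_equal(sum(vapply(db1$truth, function(t) nrow(t$plants) > 0,
        logical(1))), 30L)
})

test_that("motif_fraction 0 with depleted tryptophans yields no sites", {
    db <- simulateProteinDb(40, motifFraction = 0, seed = 83)
    nSites <- vapply(names(db$sequences), function(id)
        nrow(scanConsensusSites(as.character(db$sequences[[id]]))),
        integer(1))
    expect_true(all(nSites == 0L))
})

test_that("LFQ generator plants effects, motifs and decoys coherently", {
    sim <- simulateLfqExperiment(nProteins = 200, nEffect = 12, seed = 84)
    expect_length(sim$truth$effectIds, 12L)
    expect_true(all(sim$truth$effectIds %in% sim$truth$motifIds))
    expect_true(all(sim$truth$effectIds %in% sim$truth$extracellularIds))
    # planted effects are recorded per KO with the stated size
    expect_true(all(sim$truth$effects[sim$truth$effectIds, ] %in%
        c(0, -1.5)))
    expect_true(all(rowSums(sim$truth$effects != 0)[sim$truth$effectIds]
        >= 1))
    # the decoy filter removes exactly the injected decoys
    filt <- filterSecretome(sim$se, sim$annotation)
    removedByFlags <- setdiff(rownames(sim$se),
        rownames(sim$se)[!(SummarizedExperiment::rowData(sim$se)$contaminant |
            SummarizedExperiment::rowData(sim$se)$reverse |
            SummarizedExperiment::rowData(sim$se)$onlyBySite)])
    expect_setequal(removedByFlags, sim$truth$decoyIds)
    expect_false(any(sim$truth$decoyIds %in% rownames(filt$se)))
    # missingness is abundance-dependent and within a plausible band
    expect_gt(sim$truth$missingRate, 0.02)
    expect_lt(sim$truth$missingRate, 0.5)
    # determinism of the exported table
    sim2 <- simulateLfqExperiment(nProteins = 200, nEffect = 12, seed = 84)
    expect_identical(sim$table, sim2$table)
})

test_that("under the null the differential p-values are uniform", {
    pvals <- unlist(lapply(1:25, function(s) {
        sim <- simulateLfqExperiment(nProteins = 80, nEffect = 0,
            mnarC = -Inf, seed = 1000 + s)
        imp <- imputeLfq(sim$se, seed = 2000 + s)
        differentialTest(imp, "KO_A")$p
    }))
    ks <- suppressWarnings(ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("planted negative effects are recovered with the correct sign", {
    rec <- vapply(1:10, function(s) {
        sim <- simulateLfqExperiment(nProteins = 200, nEffect = 15,
            seed = 3000 + s)
        imp <- imputeLfq(sim$se, seed = 4000 + s)
        hits <- unlist(lapply(c("KO_A", "KO_B"), function(g) {
            d <- differentialTest(imp, g)
            affected <- rownames(sim$truth$effects)[
                sim$truth$effects[, g] != 0]
            d$log2fc[match(affected, d$id)] < 0
        }))
        mean(hits)
    }, numeric(1))
    expect_gte(median(rec), 0.9)
})

test_that("MS1 generator elutes species at planted apices and flags overlap", {
    sim <- simulateMs1Run(mz = c(600, 600.4, 900), ratios = c(1, 0.5, 0.2),
        apices = c(3, 4, 5), seed = 85)
    expect_equal(nrow(sim$truth$overlaps), 1L)  # 600 vs 600.4 within 0.6
    eic <- extractEIC(sim$run, 900, tol = 0.3)
    expect_lt(abs(rtime(eic)[which.max(intensity(eic))] - 5), 0.021)
    # zero-intensity run gives all-zero EICs
    dead <- simulateMs1Run(mz = 700, ratios = 0, apices = 5,
        maxIntensity = 0, seed = 86)
    expect_true(all(intensity(extractEIC(dead$run, 700)) == 0))
    # determinism
    a <- simulateMs1Run(mz = 700, ratios = 1, apices = 5, noise = 100,
        seed = 87)
    b <- simulateMs1Run(mz = 700, ratios = 1, apices = 5, noise = 100,
        seed = 87)
    expect_identical(a$run@peaks, b$run@peaks)
})
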