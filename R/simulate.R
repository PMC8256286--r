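# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed: the same call yields byte-identical output, and each
# returns the ground truth needed to compute expected downstream results
# without re-simulation.

.AA20 <- names(.AA_MONO)

.randomSequence <- function(len, letters) {
    paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Plant a consensus window ("WxxW", "WxxC") or a full TSR motif
# ("WxxWxxWxxC") at `start`, with x drawn from residues that can create no
# additional W/C anchor.
.plantMotif <- function(chars, start, kind) {
    xpool <- setdiff(.AA20, c("W", "C"))
    xs <- function(n) sample(xpool, n, replace = TRUE)
    if (kind == "TSR") {
        chars[start + c(0L, 3L, 6L)] <- "W"
        chars[start + 9L] <- "C"
        chars[start + c(1L, 2L, 4L, 5L, 7L, 8L)] <- xs(6L)
    } else {
        chars[start] <- "W"
        chars[start + 3L] <- if (kind == "WxxW") "W" else "C"
        chars[start + c(1L, 2L)] <- xs(2L)
        # the second W of a WxxW plant must not chain into a further
        # consensus window via a background W/C three residues on
        if (kind == "WxxW" && start + 6L <= length(chars) &&
                chars[start + 6L] %in% c("W", "C"))
            chars[start + 6L] <- xs(1L)
    }
    chars
}

.expectedSitesForPlant <- function(start, kind) {
    switch(kind,
        WxxW = data.frame(position = start, kind = "WxxW"),
        WxxC = data.frame(position = start, kind = "WxxC"),
        TSR = data.frame(position = start + c(0L, 3L, 6L),
            kind = c("WxxW", "WxxW", "WxxC")))
}

.generateDb <- function(ids, motifIds, lengthRange, depleteTrp, tsrFraction) {
    bg <- if (depleteTrp) setdiff(.AA20, "W") else .AA20
    truth <- vector("list", length(ids))
    names(truth) <- ids
    seqs <- character(length(ids))
    for (i in seq_along(ids)) {
        len <- sample(lengthRange[1L]:lengthRange[2L], 1L)
        chars <- strsplit(.randomSequence(len, bg), "")[[1L]]
        plants <- data.frame(start = integer(0), kind = character(0))
        if (ids[i] %in% motifIds) {
            kind <- if (stats::runif(1) < tsrFraction) "TSR"
                else sample(c("WxxW", "WxxC"), 1L)
            span <- if (kind == "TSR") 10L else 4L
            start <- sample(seq_len(len - span + 1L), 1L)
            chars <- .plantMotif(chars, start, kind)
            plants <- data.frame(start = start, kind = kind)
        }
        seqs[i] <- paste(chars, collapse = "")
        sites <- do.call(rbind, c(
            list(data.frame(position = integer(0), kind = character(0))),
            lapply(seq_len(nrow(plants)), function(k)
                .expectedSitesForPlant(plants$start[k], plants$kind[k]))))
        truth[[i]] <- list(plants = plants, sites = sites)
    }
    list(sequences = Biostrings::AAStringSet(setNames(seqs, ids)),
        truth = truth)
}

#' Simulate a protein database with planted consensus motifs
#'
#' Generates random protein sequences (lengths drawn uniformly from
#' `lengthRange`) in which tryptophan is depleted outside planted windows,
#' so that the recorded plants are the only consensus sites. A fraction of
#' proteins receives one planted WxxW/WxxC window or a full TSR
#' (WxxWxxWxxC) motif at a recorded position.
#'
#' @param nProteins number of proteins
#' @param motifFraction fraction of proteins receiving a planted motif
#' @param seed integer seed
#' @param lengthRange sequence length range (default 100-800)
#' @param tsrFraction among motif proteins, probability of a full TSR motif
#'   rather than a single consensus window
#' @param depleteTrp suppress background tryptophans (default TRUE); with
#'   FALSE, spurious consensus sites can arise by chance
#' @return a list with `sequences` (named [Biostrings::AAStringSet]) and
#'   `truth` (per protein: `plants` and the expected `sites` data.frame)
#' @export
simulateProteinDb <- function(nProteins = 500L, motifFraction = 0.2, seed,
        lengthRange = c(100L, 800L), tsrFraction = 0.3, depleteTrp = TRUE) {
    stopifnot(motifFraction >= 0, motifFraction <= 1, nProteins >= 1L)
    ids <- sprintf("SYN%04d", seq_len(nProteins))
    .withSeed(seed, {
        motifIds <- sample(ids, round(motifFraction * nProteins))
        db <- .generateDb(ids, motifIds, lengthRange, depleteTrp,
            tsrFraction)
    })
    db$motifIds <- sort(motifIds)
    db$seed <- seed
    db
}

#' Default secretomics sample design
#'
#' One wild-type line (n = 3) and two KO groups of two clones with three
#' replicates each (n = 6 per KO).
#'
#' @param refGroup reference group label
#' @param koGroups KO group labels
#' @param nRep replicates per clone
#' @return data.frame with columns `sample`, `group`, `clone`
#' @export
defaultDesign <- function(refGroup = "WT", koGroups = c("KO_A", "KO_B"),
        nRep = 3L) {
    rows <- list(data.frame(
        sample = paste0(refGroup, "_", seq_len(nRep)),
        group = refGroup, clone = refGroup))
    for (g in koGroups) for (cl in 1:2) {
        clone <- paste0(g, "_c", cl)
        rows[[length(rows) + 1L]] <- data.frame(
            sample = paste0(clone, "_", seq_len(nRep)),
            group = g, clone = clone)
    }
    do.call(rbind, rows)
}

#' Simulate an LFQ secretomics experiment with known ground truth
#'
#' Generates a MaxQuant-style protein-group table under the default
#' WT + two-KO/two-clone design: per-protein base log2 abundance
#' `Normal(baseMean, baseSd)`, replicate noise `Normal(0, noiseSd)`,
#' planted negative log2 effects on motif-bearing proteins in one or both
#' KO groups, and abundance-dependent (MNAR) missingness with probability
#' `plogis((mnarC - x) / mnarS)` of the underlying log2 value. Values are
#' exported as linear LFQ intensities with 0 for missing; decoy rows
#' (contaminant / reverse / only-by-site) are injected. A matching protein
#' database (motifs planted on effect proteins and a further random subset)
#' and a GO/Pfam annotation table are generated alongside.
#'
#' @param nProteins number of genuine protein groups
#' @param design sample design data.frame (default [defaultDesign()])
#' @param nEffect number of proteins receiving a planted effect
#' @param effectSize planted log2 effect (default -1.5, a secretion
#'   reduction)
#' @param seed integer seed
#' @param baseMean,baseSd mean and SD of per-protein base log2 abundance
#' @param noiseSd replicate noise SD (log2)
#' @param mnarC,mnarS location and scale of the logistic missingness model
#' @param motifFraction total fraction of motif-bearing proteins (effect
#'   proteins included)
#' @param extracellularFraction fraction annotated with an extracellular
#'   GO-CC slim term
#' @param tsp1FractionEffect,tsp1FractionOther probability of a TSP_1 Pfam
#'   annotation for effect / non-effect proteins
#' @param nDecoys integer vector: contaminant, reverse, only-by-site rows
#' @param singlePeptideFraction fraction of genuine rows with only one
#'   identified peptide
#' @return a list: `se` (a [SecretomeExperiment] including decoy rows),
#'   `table` (proteinGroups-dialect data.frame), `proteins`
#'   ([Biostrings::AAStringSet]), `annotation` (accession/gocc/pfam
#'   data.frame), `design`, and `truth` (effects per KO, motif ids,
#'   extracellular ids, TSP_1 ids, missingness parameters, seed)
#' @export
simulateLfqExperiment <- function(nProteins = 400L, design = defaultDesign(),
        nEffect = 20L, effectSize = -1.5, seed,
        baseMean = 25, baseSd = 2, noiseSd = 0.5,
        mnarC = 22, mnarS = 1,
        motifFraction = 0.25, extracellularFraction = 0.85,
        tsp1FractionEffect = 0.6, tsp1FractionOther = 0.02,
        nDecoys = c(contaminant = 5L, reverse = 5L, onlyBySite = 3L),
        singlePeptideFraction = 0.05) {
    stopifnot(nEffect <= nProteins)
    ids <- sprintf("SYN%04d", seq_len(nProteins))
    koGroups <- setdiff(unique(design$group), "WT")
    .withSeed(seed, {
        # --- ground-truth assignments -------------------------------------
        effectIds <- sample(ids, nEffect)
        assignment <- rep(c(koGroups, list(koGroups)),
            length.out = nEffect)
        effects <- matrix(0, nrow = nProteins, ncol = length(koGroups),
            dimnames = list(ids, koGroups))
        for (k in seq_len(nEffect))
            effects[effectIds[k], assignment[[k]]] <- effectSize
        nMotif <- max(round(motifFraction * nProteins), nEffect)
        motifIds <- union(effectIds,
            sample(setdiff(ids, effectIds), nMotif - nEffect))
        extracellularIds <- unique(c(effectIds,
            sample(ids, round(extracellularFraction * nProteins))))
        tsp1Ids <- c(
            effectIds[stats::runif(nEffect) < tsp1FractionEffect],
            setdiff(ids, effectIds)[
                stats::runif(nProteins - nEffect) < tsp1FractionOther])
        # --- protein database with motifs on motifIds ---------------------
        db <- .generateDb(ids, motifIds, c(100L, 800L), depleteTrp = TRUE,
            tsrFraction = 0.3)
        # --- quantities ---------------------------------------------------
        base <- rnorm(nProteins, baseMean, baseSd)
        x <- matrix(base, nrow = nProteins, ncol = nrow(design)) +
            matrix(rnorm(nProteins * nrow(design), 0, noiseSd),
                nrow = nProteins)
        for (g in koGroups)
            x[, design$group == g] <- x[, design$group == g] +
                effects[, g]
        pMiss <- plogis((mnarC - x) / mnarS)
        miss <- matrix(stats::runif(length(x)) < pMiss, nrow = nProteins)
        lfq <- round(2^x, 2)
        lfq[miss] <- 0
        dimnames(lfq) <- list(ids, design$sample)
        peptides <- pmax(stats::rpois(nProteins, 12L), 2L)
        single <- stats::runif(nProteins) < singlePeptideFraction
        peptides[single] <- 1L
        # --- decoy rows ---------------------------------------------------
        decoyIds <- c(
            sprintf("CON__C%03d", seq_len(nDecoys[["contaminant"]])),
            sprintf("REV__R%03d", seq_len(nDecoys[["reverse"]])),
            sprintf("SITE%03d", seq_len(nDecoys[["onlyBySite"]])))
        nDec <- length(decoyIds)
        decLfq <- round(2^matrix(rnorm(nDec * nrow(design), baseMean,
            baseSd), nrow = nDec), 2)
        dimnames(decLfq) <- list(decoyIds, design$sample)
        flags <- data.frame(
            id = c(ids, decoyIds),
            members = c(ids, decoyIds),
            peptides = c(peptides, pmax(stats::rpois(nDec, 6L), 2L)),
            contaminant = c(rep(FALSE, nProteins),
                grepl("^CON__", decoyIds)),
            reverse = c(rep(FALSE, nProteins), grepl("^REV__", decoyIds)),
            onlyBySite = c(rep(FALSE, nProteins),
                grepl("^SITE", decoyIds)),
            stringsAsFactors = FALSE)
        allLfq <- rbind(lfq, decLfq)
        # --- annotation ---------------------------------------------------
        goccPool <- c("cytoplasm", "nucleus", "plasma membrane")
        extraTerms <- c("extracellular region", "extracellular space",
            "extracellular matrix")
        gocc <- ifelse(ids %in% extracellularIds,
            sample(extraTerms, nProteins, replace = TRUE),
            sample(goccPool, nProteins, replace = TRUE))
        otherDom <- c("EGF", "Kringle", "fn3", "Ig_like")
        pfam <- vapply(ids, function(a) {
            d <- character(0)
            if (a %in% tsp1Ids) d <- "TSP_1"
            if (stats::runif(1) < 0.3)
                d <- c(d, sample(otherDom, 1L))
            paste(d, collapse = ";")
        }, character(1))
        annotation <- data.frame(accession = ids, gocc = gocc, pfam = pfam,
            stringsAsFactors = FALSE)
        # annotate decoy contaminants as extracellular to make the decoy
        # filter, not the GO filter, responsible for removing them
        annotation <- rbind(annotation, data.frame(accession = decoyIds,
            gocc = "extracellular region", pfam = ""))
    })
    se <- SecretomeExperiment(allLfq, flags, design)
    table <- .asProteinGroupsTable(allLfq, flags, design)
    list(
        se = se,
        table = table,
        proteins = db$sequences,
        annotation = annotation,
        design = design,
        truth = list(
            effectIds = sort(effectIds),
            effects = effects,
            effectSize = effectSize,
            motifIds = sort(motifIds),
            motifTruth = db$truth,
            extracellularIds = sort(extracellularIds),
            tsp1Ids = sort(unique(tsp1Ids)),
            singlePeptideIds = ids[single],
            decoyIds = decoyIds,
            mnar = c(c = mnarC, s = mnarS),
            missingRate = mean(miss),
            seed = seed))
}

.asProteinGroupsTable <- function(lfq, flags, design) {
    out <- data.frame(
        `Majority protein IDs` = flags$members,
        Peptides = flags$peptides,
        `Potential contaminant` = ifelse(flags$contaminant, "+", ""),
        Reverse = ifelse(flags$reverse, "+", ""),
        `Only identified by site` = ifelse(flags$onlyBySite, "+", ""),
        check.names = FALSE, stringsAsFactors = FALSE)
    for (s in design$sample)
        out[[paste0("LFQ intensity ", s)]] <- lfq[, s]
    out
}

#' Simulate an MS1 run containing a glycoform mixture
#'
#' Produces centroid MS1 scans at a fixed cadence in which each species
#' elutes as a Gaussian profile centred at its apex retention time, with a
#' single centroid at its m/z, plus an optional uniform noise floor of
#' random centroids.
#'
#' @param mz species m/z values (Th)
#' @param ratios relative species intensities (>= 0; scaled so the largest
#'   species peaks at `maxIntensity`)
#' @param apices apex retention times in minutes (recycled)
#' @param peakSd Gaussian elution width (SD, minutes)
#' @param rtRange run retention-time range (default covers all apices)
#' @param scanInterval scan cadence in minutes
#' @param maxIntensity apex intensity of the most abundant species
#' @param noise amplitude of the uniform noise floor (absolute intensity
#'   units; 0 disables)
#' @param nNoisePeaks random noise centroids per scan
#' @param mzWindow m/z range for noise centroids (default spans the species
#'   +/- 50 Th)
#' @param seed integer seed
#' @return a list with `run` (a [SpectrumRun]) and `truth` (species table
#'   with m/z, ratio, apex, width; `overlaps` flags species pairs closer
#'   than 0.6 Th in m/z)
#' @export
simulateMs1Run <- function(mz, ratios, apices, peakSd = 0.1,
        rtRange = NULL, scanInterval = 0.02, maxIntensity = 1e6,
        noise = 0, nNoisePeaks = 5L, mzWindow = NULL, seed) {
    stopifnot(length(mz) == length(ratios), all(ratios >= 0), peakSd > 0)
    apices <- rep_len(apices, length(mz))
    if (is.null(rtRange))
        rtRange <- c(max(0, min(apices) - 5 * peakSd),
            max(apices) + 5 * peakSd)
    if (is.null(mzWindow))
        mzWindow <- c(min(mz) - 50, max(mz) + 50)
    rt <- seq(rtRange[1L], rtRange[2L], by = scanInterval)
    amp <- if (max(ratios) > 0) maxIntensity * ratios / max(ratios)
        else rep(0, length(ratios))
    .withSeed(seed, {
        peaks <- lapply(rt, function(t) {
            ints <- amp * exp(-(t - apices)^2 / (2 * peakSd^2))
            keep <- ints > 0
            m <- cbind(mz = mz[keep], intensity = ints[keep])
            if (noise > 0 && nNoisePeaks > 0L) {
                m <- rbind(m, cbind(
                    mz = stats::runif(nNoisePeaks, mzWindow[1L],
                        mzWindow[2L]),
                    intensity = stats::runif(nNoisePeaks, 0, noise)))
            }
            m[order(m[, 1L]), , drop = FALSE]
        })
    })
    d <- outer(mz, mz, function(a, b) abs(a - b))
    overlaps <- which(d < 0.6 & upper.tri(d), arr.ind = TRUE)
    list(
        run = SpectrumRun(rt, peaks),
        truth = list(
            species = data.frame(mz = mz, ratio = ratios, apex = apices,
                peakSd = peakSd),
            overlaps = overlaps,
            noise = noise, maxIntensity = maxIntensity, seed = seed))
}
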