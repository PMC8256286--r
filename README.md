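# CMannoScan

Discovery of candidate tryptophan C-mannosylated proteins from
quantitative secretomics, with the glycopeptide-level mass spectrometry
machinery needed to follow candidates up.

## The problem

C-mannosylation attaches a single α-mannose through a C–C bond to the
indole of a tryptophan, typically within the consensus sequence
**WxxW/WxxC**. In thrombospondin type 1 repeats (TSRs) the conserved
**WxxWxxWxxC** motif can carry a C-mannose on all three tryptophans
(W1/W2 installed by the DPY19L1 transferase, W3 by DPY19L3). Because
C-mannosylation supports secretion of its target proteins, comparing the
secretomes of transferase-knockout and wild-type cells by label-free
quantification (LFQ) exposes candidate target proteins as those whose
secretion drops in the mutants. `CMannoScan` implements that screen and
its follow-up computations as a tested, reusable R package:

* **Motif scanning** — all WxxW/WxxC consensus tryptophans and full TSR
  motifs in a protein database, lifted to MaxQuant protein groups with
  ANY-member semantics (`scanConsensusSites`, `findTsrMotifs`,
  `annotateGroups`).
* **Secretome statistics** — Perseus-style filtering of a
  `proteinGroups.txt` table (decoy/contaminant removal, extracellular
  GO-CC slim restriction, peptide-count and replicate-detection rules),
  log2 transformation with left-shifted normal imputation of missing
  values (per column: mean − 1.8·SD, width 0.3·SD), per-protein
  two-tailed Student *t* tests of KO vs WT, and per-clone fold changes
  (`filterSecretome`, `imputeLfq`, `differentialTest`,
  `perCloneFoldChanges`).
* **Candidate selection and enrichment** — significant ∩ motif-positive
  per KO, one-sided Fisher exact Pfam-domain enrichment against the
  filtered background, and a background rescreen for TSP_1-domain
  proteins (`selectCandidates`, `fisherDomainEnrichment`,
  `rescreenDomain`).
* **Glycopeptide machinery** — monoisotopic masses (one C-mannose adds
  162.05282 Da; O-fucose 146.05791 Da, optionally extended by glucose),
  full glycoform ladders, singly protonated b/y fragment ions with
  non-labile glycans, extracted ion chromatograms at an absolute mass
  tolerance (default 0.3 Da) and max-normalised glycoform quantification
  (`GlycoPeptide`, `enumerateGlycoforms`, `fragmentIons`, `extractEIC`,
  `quantifyGlycoforms`).
* **MRM design** — exhaustive precursor (charges 2–4) × b/y product
  transition enumeration inside a 250–1250 m/z window, linear
  collision-energy seeds, and scheduling into 300 s retention-time
  windows (`enumerateTransitions`, `scheduleTransitions`,
  `writeTransitionList`).
* **Synthetic data** — generators for a motif-planted protein database,
  an LFQ experiment with planted secretion effects and
  missing-not-at-random dropout, and MS1 runs of Gaussian-eluting
  glycoform mixtures, each returning its ground truth
  (`simulateProteinDb`, `simulateLfqExperiment`, `simulateMs1Run`).

## Worked example

```r
library(CMannoScan)

## a synthetic secretomics experiment: WT (n = 3) vs two KO groups of
## two clones x 3 replicates, 400 proteins, 20 planted -1.5 log2 effects
sim <- simulateLfqExperiment(seed = 42)
res <- runPipeline(sim$se, sim$proteins, sim$annotation, sim$design,
    seed = 7)
res$filterReport
#>                    stage   n
#> 1                initial 413
#> 2              no_decoys 400
#> 3          extracellular 342
#> 4 min_peptides_detection 325
#> 5                  final 325
```

The 13 decoy rows fall to the flag filter, 58 intracellular proteins to
the GO-CC filter, and 17 more to the peptide-count/detection rules; 325
protein groups form the analysis universe. Testing each KO against WT
and intersecting with the motif scan:

```r
sapply(res$diff, function(d) sum(d$significant))
#> KO_A KO_B
#>   23   17
lengths(res$candidates)
#> KO_A  KO_B union
#>   15    13    24
head(res$enrichment, 1)
#>   domain  k  n  K   N oddsRatio            p significant
#> 1  TSP_1 12 24 21 325  31.44807 2.425714e-10        TRUE
length(res$rescreen)   # TSP_1 carriers in the whole background
#> [1] 21
```

24 significant, motif-bearing candidates emerge; the TSP_1 domain is
strongly enriched among them (12 of 24 carry it versus 21 of 325 in the
background), and rescreening the full background for TSP_1 recovers all
21 planted carriers. On the glycopeptide side, the TSR tryptophan ladder
of a peptide with three consensus sites and an O-fucosylation site:

```r
p <- GlycoPeptide("WSDWSSWSPC", nConsensusTrp = 3, hasOFucSite = TRUE)
nrow(enumerateGlycoforms(p, charges = 2))   # Hex0-3 x {none, Fuc, FucGlc}
#> [1] 12
head(enumerateGlycoforms(p, charges = 2), 2)
#>   nHex fucosylState charge neutralMass       mz         label
#> 1    0         none      2    1296.487 649.2508     Hex0 [2+]
#> 2    0          Fuc      2    1442.545 722.2797 Hex0+Fuc [2+]
```

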