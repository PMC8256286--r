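---
title: "Methods: from knockout secretomes to C-mannosylation candidates"
author: "CMannoScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from knockout secretomes to C-mannosylation candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scientific background

C-mannosylation is the attachment of a single α-mannose to the indole C2
atom of tryptophan through a carbon–carbon bond. It occurs in the
endoplasmic reticulum on tryptophans in the consensus context
**WxxW/WxxC**, and is concentrated in thrombospondin type 1 repeats
(TSRs), whose conserved **WxxWxxWxxC** motif can be modified on all three
tryptophans: the first two (WxxW contexts) by the transferase DPY19L1,
the third (WxxC context) by DPY19L3. The modification is chemically
stable — it survives ionisation and fragmentation — and adds a defined
hexose mass to the residue, which makes it tractable by mass
spectrometry. Because C-mannosylation supports secretion of its
carriers, proteins whose abundance drops in the conditioned medium of
transferase-knockout cells are candidates for being C-mannosylation
targets. `CMannoScan` implements that inference chain and the
glycopeptide-level computations used to confirm individual candidates.

# The differential-secretome model

## Input and filtering

The quantitative input is a MaxQuant-style `proteinGroups.txt` table:
one row per protein group (semicolon-separated member accessions), a
distinct-peptide count, `+`-marked quality flags, and one
`LFQ intensity <sample>` column per run. Zeros denote non-quantified
values and are treated as missing from the moment of ingestion.

`filterSecretome()` applies three sequential filters, each recorded in a
stagewise report whose counts are non-increasing by construction:

1. **Decoy removal** — contaminants, reverse-database matches and groups
   only identified by site.
2. **Extracellular restriction** — a group is kept if *any* member is
   annotated with one of the GO-CC slim terms *extracellular matrix*,
   *extracellular region* or *extracellular space*. Accessions without
   annotation count as not extracellular (and are tallied in the
   report), since absence of evidence cannot place a protein in the
   secretome.
3. **Identification stringency** — at least two distinct peptides, and
   detection (a non-missing LFQ value) in at least two wild-type
   replicates *or* in at least one replicate of each clone of the same
   KO. The second arm deliberately reads "both clones" as
   one-per-clone-of-one-KO: it admits proteins secreted by mutants but
   absent from wild type, which a WT-only rule would discard, while
   still requiring the observation to replicate across independent
   clones.

The report also counts groups detected at least once in every cell line
(each clone and the wild type), a descriptive completeness figure.

## Imputation

LFQ intensities are log2-transformed. Missingness in LFQ data is
abundance-dependent (missing-not-at-random): low-abundance proteins drop
below the detection limit preferentially. `imputeLfq()` therefore draws
each missing value in column $c$ from

$$x \sim \mathcal{N}(\mu_c - d\,\sigma_c,\; (w\,\sigma_c)^2)$$

with $\mu_c, \sigma_c$ the mean and SD of the observed log2 values of
that column, down shift $d = 1.8$ and width $w = 0.3$ — the standard
left-shifted normal imputation performed separately for each column.
The seed is mandatory, the imputed mask is kept as its own assay, and
the caller's RNG state is untouched. A column with fewer than two
observed values cannot yield $\mu_c, \sigma_c$ and is a loud error
naming the column. Imputation runs after filtering; imputing before
restriction to the extracellular universe would let thousands of
intracellular rows steer the column moments that the imputed values are
drawn from, which is why the pipeline fixes this order.

## Testing and fold changes

`differentialTest()` compares each KO group (both clones pooled, n = 6
under the default design) against the wild type (n = 3) with a
two-tailed **Student** (equal-variance) *t* test per protein on the
imputed log2 values. With the artificial-variance parameter of
volcano-style moderated statistics set to zero, the moderated statistic
reduces to this plain *t*, which is what is computed; Welch's variant is
deliberately not the default. Fold change is the difference of group
means in log2 units. Significance is a raw p-value threshold
($p \le 0.05$); no multiple-testing correction is applied by default
because the screen is verification-oriented — candidates proceed to
targeted follow-up — but a Benjamini–Hochberg mode is available.
Degenerate rows follow fixed conventions: zero pooled variance with
equal means gives $p = 1$, with unequal means $p = 0$.

`perCloneFoldChanges()` reports each KO sample's fold change against the
wild-type mean plus the per-KO mean of those fold changes, the display
used to inspect clone consistency; for balanced clones the mean of
per-sample fold changes equals the fold change of means.

## Motif annotation, candidates, enrichment

`scanConsensusSites()` reports every tryptophan with W or C three
residues downstream; the two intervening positions may be any residue,
including W or C, so overlapping sites are all kept (positions are
1-based, the biological residue-numbering convention). Windows
containing characters outside the tolerated alphabet (20 residues plus
X/U/B/Z) never match — a conservative choice for gap or stop characters.
`findTsrMotifs()` requires the full ten-residue W..W..W..C pattern, and
every tryptophan it reports is by construction also a consensus-scan
hit. Both operations are exposed separately rather than merged into one
rule: the screen's motif call needs only WxxW/WxxC, while TSR detection
is the stricter, domain-level statement.

`annotateGroups()` lifts sites to protein groups with ANY-member
semantics. Members without a sequence are recorded as unresolved, never
as motif-free evidence; a group with no resolved member has unknown
motif status and is excluded from the motif-positive set.

`selectCandidates()` intersects significance with motif positivity per
KO and unions the sets. `fisherDomainEnrichment()` then asks whether a
Pfam domain is over-represented among the candidates relative to the
filtered universe, with a one-sided (greater) Fisher exact test on the
2×2 table $(k, n-k, K-k, N-n-K+k)$ — one-sided because the question is
enrichment, and again without multiple-testing correction by default.
`rescreenDomain()` finally widens the candidate list to every background
group carrying a domain of interest (TSP_1 by default), decoupling
domain-level discovery from per-protein significance.

# Glycopeptide computations

Masses are monoisotopic throughout: residue masses plus water
18.010565 Da, carbamidomethyl +57.02146 Da per cysteine as the default
fixed modification, proton 1.007276 Da. Glycan deltas are hexose
162.05282 Da (C-mannose, and the glucose extension), deoxyhexose
146.05791 Da (O-fucose). A `GlycoPeptide` carries the number of
C-mannosylatable tryptophans explicitly because a consensus context can
extend beyond a proteolytic peptide's C terminus — the peptide sequence
alone can undercount, so the caller decides.

`enumerateGlycoforms()` builds the Cartesian ladder
$\{0..n_W\} \times \{\mathrm{none}, \mathrm{Fuc}, \mathrm{FucGlc}\}$
(the fucosyl axis only when the peptide has an O-fucosylation site) in a
fixed order. `fragmentIons()` computes singly protonated b/y series with
glycans treated as non-labile, so a site modification shifts exactly the
fragments containing the residue — the property that lets fragment
series localise the modified tryptophan. Product charges above 1+ are
out of the default scope.

`extractEIC()` sums, per MS1 scan, all centroid intensities within an
absolute tolerance of the target m/z (default 0.3 Da, matching
vendor-style mass-chromatogram extraction on Q-TOF centroid data; a ppm
mode would suit high-resolution data but absolute Da is the default
here). `quantifyGlycoforms()` extracts one EIC per ladder species and
reports apex intensities scaled to the most intense glycoform, with the
absolute maximum attached — the max-normalised display conventional for
glycoform panels. Apex is the default quantity; trapezoidal area and
optional Savitzky–Golay smoothing (quadratic, 9-point) are available
but off by default. Isotope envelopes are not modelled: annotation is
by monoisotopic parental mass.

# MRM design

`enumerateTransitions()` crosses precursor charges 2–4 with the full
singly protonated b/y ladder and filters both precursor and product to
the instrument window (default 250–1250 m/z). Filtering is monotone —
widening the window never removes a transition — and the enumeration is
checked against an independent exhaustive oracle in the tests. Whether
glycan masses ride on product ions is a flag (`glycanOnProducts`,
default on), since fragment glycan retention is instrument- and
energy-dependent.

Collision energies are seeds, not optimised values: linear in precursor
m/z with a charge-decreasing intercept (2+: $0.036\,m/z + 8.857$; 3+
intercept 4.8; 4+ intercept 3.3), so the seed never increases with
charge at fixed m/z, reflecting QqQ practice; any user-supplied CE
overrides the seed exactly. `scheduleTransitions()` centres a detection
window (default 300 s wide, 1.8 s target scan time) on each
caller-supplied expected retention time; transitions without an RT go to
an unscheduled block. Retention-time calibration itself is out of
scope.

# Synthetic data and what it shows

The generators produce every input the pipeline needs, with recorded
ground truth, as pure functions of their parameters and seed.

* `simulateProteinDb()` plants WxxW/WxxC windows or full TSR motifs at
  recorded positions in random sequences whose background is depleted of
  tryptophan, so planted sites are provably the only sites; planting
  also guards the residue three positions after a planted WxxW so the
  plant cannot chain into an unrecorded extra window.
* `simulateLfqExperiment()` emulates the screen's design (WT n = 3, two
  KO groups × two clones × 3) with per-protein base abundance
  $\mathcal{N}(25, 2^2)$ in log2 units and replicate noise
  $\mathcal{N}(0, 0.5^2)$ — magnitudes chosen to resemble typical LFQ
  log2 scales; planted effects default to −1.5 log2 on 20 of 400
  proteins, assigned to one or both KOs in rotation, and always placed
  on motif-bearing, extracellular proteins so truth propagates to the
  candidate stage. Missingness is MNAR via
  $P(\text{miss}) = \mathrm{logit}^{-1}((c - x)/s)$ with $c = 22$,
  $s = 1$ on the underlying log2 value; the realised rate is recorded in
  the truth object. Decoy rows and single-peptide rows are injected to
  exercise every filter arm, and TSP_1 annotations are planted
  preferentially on effect proteins so the enrichment stage has signal.
* `simulateMs1Run()` emits centroid scans at fixed cadence with Gaussian
  elution profiles per species and an optional uniform noise floor, and
  flags species pairs closer than twice the default EIC tolerance.

What passing on these data shows — and does not. The generators draw
from the very model families the pipeline assumes (log-normal
abundances, normal noise, logistic MNAR, Gaussian elution), so
recovery there validates correctness of the implementation, not
robustness of the method. Real secretomes add features the generators
omit: correlated proteins, batch and loading effects, heavy-tailed
noise, shared peptides across protein groups (members here are
singletons), isotope envelopes and chimeric spectra. Conclusions about
those require real data.

# Problem sizes and numerical choices

The test-suite and acceptance-script simulations use 400 proteins × 15
samples with 20 planted effects, 20–50 generator seeds for the
stochastic summaries (sign recovery, null calibration), 1000 random
sequences for the motif-scanner equivalence check and 50 random
peptides for the MRM oracle — sizes at which the stochastic summaries
are stable while a full run stays comfortably interactive. Ties in
apex picking resolve to the earliest scan (`which.max`). Coincident
scan times in a run are disambiguated by a nanominute jitter when a
chromatogram is built. The configuration hash embedded in every output
is a 32-bit FNV-1a over the canonical JSON of the configuration:
a provenance fingerprint, not a cryptographic one.

# Known limitations

* Group-level motif and domain calls use ANY-member semantics; a single
  spurious member can mark a whole group motif-positive.
* The extracellular filter is annotation-bound: unannotated accessions
  are dropped from the universe rather than rescued by prediction.
* No glycopeptide identification or FDR machinery — fragment lists and
  EICs support targeted verification, not database search.
* Collision-energy seeds are generic linear defaults; real assays
  optimise per transition.
* The imputation model is the field-standard left-shifted normal; it is
  a convention for making MNAR data testable, not a generative truth,
  and p-values downstream of imputation inherit that convention.
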