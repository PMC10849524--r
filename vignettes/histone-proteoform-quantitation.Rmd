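---
title: "Quantifying histone proteoforms from top-down spectra: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone proteoforms from top-down spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(histoform)
```

## The measurement model

A histone *proteoform* is a single molecule defined with chemical
precision: the backbone plus the complete set of co-occurring PTMs. For
histone H4 the package works with the mature murine sequence (102 aa,
initiator Met removed, N-terminus always acetylated) and a variable search
space of K5/K8/K12/K16/K31 acetylation and K20 mono/di/tri-methylation
(128 proteoforms). For H3.2 the analyte is the middle-down GluC tail,
residues 1–50 ending at the first Glu, with K4/K36 methylation, K9/K27
acetylation or methylation, and K14/K18/K23 acetylation (3200 proteoforms).

The measurement has two stages, and the package models both:

1. **MS1.** Intact species ionize into a charge-state envelope. Precursors
   are isolated in a 3.4 Da window, which we interpret as the *full*
   isolation width (a precursor matches a class within ±1.7 Da) — the
   convention instrument isolation uses; the alternative (±3.4) is a
   configuration away via `ms_config()`. Because one acetyl (42.04 Da
   average) and three methyls (3 × 14.03 Da) differ by only ~0.04 Da, all
   equal-nominal-mass proteoforms fall into one window: proteoforms are
   grouped into *isobaric classes* by single-linkage clustering of intact
   masses at the window width. Single linkage (rather than fixed bins)
   avoids splitting near-identical masses across a bin edge, and is
   seedless and deterministic. Co-isolated class members co-fragment, so
   MS1 can only quantify classes; members must be disentangled at MS2.

2. **MS2 (ETD).** Electron-transfer dissociation cleaves the N–Cα bond,
   giving N-terminal c ions and C-terminal z ions that retain labile PTMs.
   We implement c as the quasi-molecular species (b + NH3) and z as the
   z-dot radical (y − NH2); the constants are encapsulated in one place
   and validated through the complementarity invariant
   `c[i] + z[L−i] = M + m(H)` plus the 10 ppm acceptance check, so a
   maintainer switching to a z+1 convention must re-verify both. Fragment
   matching uses a 10.0 ppm tolerance against the observed peaks
   (neutralized at their annotated charge, z = 1 when unannotated; charge
   inference is deliberately not implemented).

### Apportionment

Fragment intensities of co-isolated species mix linearly: an observed
fragment mass receives intensity from every class member whose ladder
contains it. `match_fragments()` therefore builds a binary incidence
matrix `A` (rows = observed masses merged within tolerance, columns =
candidates) and `apportion()` solves

    min ‖A x − b‖   subject to x ≥ 0

with a Lawson–Hanson active-set NNLS written in-package, then normalizes
`x` to fractions. Proteoform abundance is MS1 class intensity × fraction,
rescaled per sample to percent of family, with technical replicates
averaged after normalization. Observed-mass merging uses the
intensity-weighted mean with ties resolved toward the lower mass. Fragment
intensities enter raw — no per-ion response calibration — which is a
stated limitation, not an oversight: the synthetic generator emits
intensities under the same convention, so recovery tests are
self-consistent, and real-data users must rescale if they have response
factors.

Two degeneracies are handled explicitly rather than hidden:

* Candidates whose evidence columns are identical are *indistinguishable*;
  their pooled fraction is split uniformly and an ambiguity flag is set
  (an all-zero spectrum likewise yields a flagged uniform split).
* Mixtures of multiply-modified positional isomers can be
  *chimera-degenerate*: c/z evidence constrains only the cumulative-mass
  distributions from each terminus, and two different mixtures (e.g.
  {K5ac,K16ac}+{K8ac,K12ac} versus {K5ac,K12ac}+{K8ac,K16ac} at swapped
  weights) can produce identical evidence. This is a limit of the
  measurement, not of the solver: NNLS returns one optimum of an
  equal-residual family. Exact-recovery tests therefore plant identifiable
  mixtures (members differing at a single modification site), and users
  should read near-equal fractions across co-occurring isomers with this
  in mind.

### Localization

A site of a candidate is reported *unambiguous* when the observed matched
fragments pin it down within the class: every alternative candidate
assigning a different state to that site fails to explain at least one
matched mass. An empty matched set leaves every site ambiguous.

## Mass scales and constants

Intact-precursor matching defaults to the isotope-averaged scale — at the
resolutions used for intact H4 the deconvolved mass is an averaged mass —
while fragments are always matched monoisotopically. All masses derive
from a single embedded element table (`inst/extdata/mass_tables.json`,
versioned): monoisotopic masses to six decimals and the conventional
(abridged IUPAC) atomic weights H 1.008, C 12.011, N 14.007, O 15.999,
S 32.06 for the average scale; the proton is fixed at 1.007276 Da. The
conventional-weight choice is deliberate: with it, the theoretical average
mass of H4 carrying N-terminal plus three lysine acetylations reproduces
the neutral mass implied by its published precursor (m/z 761.2961, +15)
within ~1 ppm, whereas finer isotopic-abundance-weighted tables land ~14
ppm away — average masses are only defined relative to an atomic-weight
convention, and the conventional table is the one this analyte was
evidently processed under. `me2`/`me3` are exact multiples of `me1` by
construction.

## Statistics

Comparisons report two independent effect metrics: the percentage-point
difference of group means (`pp`, which for chromatin reads directly as the
fraction of the genome affected) and the fold change computed on group
means (matching the convention 0.91 = 36/39.4, not a mean of per-sample
ratios). Volcano-style significance requires *both* p < 0.05 and fold ≥
1.5 (or ≤ 1/1.5); `pp` is never gated on fold. Two groups get Welch's
two-tailed t-test; three get one-way ANOVA with Tukey HSD over the
studentized range. Multiplicity is handled by Benjamini–Hochberg
(`bh_adjust()`, hand-written step-up cross-checked against `p.adjust`) and
by the Benjamini–Krieger–Yekutieli two-stage linear step-up
(`fdr_two_stage()`): stage one estimates the true-null count at
α′ = α/(1+α), stage two reruns the step-up at α′·m/m0. Note the two-stage
adjusted values may legitimately fall *below* raw p-values (the m0
rescaling); the q ≥ p identity holds for BH only.

Footprint enrichment uses the hypergeometric upper tail for the overlap
between a gene set and a node's high confidence transcriptional targets.
Consensome percentiles use max-rank tie handling — tied genes share the
best percentile, which is deterministic and conservative toward HCT
inclusion (ties never split across the cutoff) — and the HCT set is
genes *strictly above* the 95th percentile, i.e. exactly the top 5 % when
scores are distinct. The gene universe defaults to the union of all genes
scored in any consensome, overridable where a study fixes it externally
(the thermoregulatory-node test fixes N = 691 with 15 marked nodes). Odds
ratios apply the Haldane–Anscombe 0.5 correction on zero cells so log-OR
scatter plots stay finite.

Methylation–expression integration applies the filters with their stated
boundary conventions — |Δmeth| strictly > 5 points, q < 0.05; padj < 0.05
with |log2 FC| ≥ 0.263 *inclusive* (0.263 = |log2 1.2|, the 20 %
expression-change cutoff) — identically to promoter and intragenic
records, and classifies joined genes as hypo-up, hyper-down (the inverse
associations), or concordant. A `coverage` column, when present, triggers
the minimum-coverage-10 rule of RRBS summarization.

## The synthetic-data generator

`sim_config()` encodes the study conditions as defaults: three housing
conditions (TN/RT/SC), 4 animals per group (the design used 3–5), two
technical replicates per sample averaged after normalization, lognormal
multiplicative intensity noise at CV 0.10 (the simplest defensible MS
intensity error model, CV-parameterized with mean 1), 80 % fragment-ladder
coverage, and a Dirichlet(1) base abundance profile over a sparse active
set with small (CV 0.05) between-animal jitter. Charge envelopes are
discretized Gaussians chosen so peaks land inside the acquisition scan
ranges: H4 centered at z = 13 (sd 1.5; every enumerated mass stays inside
700–1400 m/z for z 9–16) and the H3.2 tail at z = 9 (sd 0.5; z = 9 is the
only charge state inside 585–640 m/z for all 3200 masses, so scan-range
clipping removes whole charge states independently of mass and introduces
no abundance bias). A planted group effect shifts a chosen `{}` metric by
a specified number of percentage points in one condition, creating signal
the comparison machinery must recover.

What the generator does *not* emulate — and what green tests therefore do
not certify about real data: isotope fine structure (consistent with
average-mass matching), chromatographic elution and co-isolated
non-histone contaminants, ETD side products (c•/z+1 hydrogen-transfer
satellites), detector saturation, and per-ion response variation. Problem
sizes in the shipped tests (classes of ≤ 20 candidates, dozens of runs,
100-trial noise batteries, 2000-replicate null simulations) were chosen as
the smallest that exercise every code path with stable statistics.

## Degenerate inputs and tie-breaks

MS1 peaks without charge annotation cannot be neutralized and stay
unmatched (counted, never silently dropped); a precursor equidistant from
two classes goes to the lower-mass class with a tie counter; samples with
zero total intensity are excluded with a warning; `{K9un}` is a valid
contains-query on the unmodified state; exact `<>` queries resolve
unlisted sites to `un`, so each matches exactly one proteoform.

## File formats

mzML is read through Bioconductor's mzR; the package's canonical fixture
format is a versioned, human-diffable JSON peak-list dialect
(`write_spectra_json()`/`read_spectra()`), with abundance tables as TSV
(notation strings parseable by `parse_notation()`) and run manifests as
YAML. PTM schemas ship as editable YAML so further variants can be added
without code changes. mzXML is not supported.
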