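---
title: "Site taxonomy, conservation, and the repression regression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site taxonomy, conservation, and the repression regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsite)
```

## The problem

Animal microRNAs are usually assumed to recognize targets through the 5'
seed (miRNA bases 2--7 or 2--8) pairing with the target's 3' UTR. A body of
crosslinking and proteomics evidence shows this is incomplete: AGO-bound
regions exist that carry no 5'-seed match for any miRNA but are perfectly
complementary to a miRNA's 3' end, and transcripts carrying only such
non-conventional sites are measurably repressed at the protein level.
`mirsite` makes that site space explicit and quantitative. It

1. detects every seed-like match of a miRNA on a transcript, for the
   conventional 5'-end seed, the mirrored 3'-end seed, and plant-like
   central 11-mers, in each of the 5' UTR, coding region (ORF) and 3' UTR;
2. classifies each site into a closed 54-type taxonomy (region x pairing
   mode x seed kind x conservation) and tallies a 54-entry count vector per
   miRNA--transcript pair;
3. screens each type's counts against protein log2 fold changes after
   miRNA transfection (Pearson r with t-based p, raw p < 0.05);
4. regresses the nine informative counts onto repression with a compact
   9-4-1 feedforward network, returning a repression score in (0,1) and a
   predicted log2 fold change;
5. classifies AGO-bound (PAR-CLIP style) cluster sequences as
   conventional-only, non-conventional-only, both, or none.

## Site definitions

All miRNA positions are 1-based from the 5' end. A target motif is the
reverse complement of the seed subsequence; matching is exact
Watson--Crick, with no G:U wobble and no gaps inside the match. Site
calling is by this motif match alone.

| mode  | kind   | miRNA positions | literal target A |
|-------|--------|-----------------|------------------|
| 5'-end | 6mer   | 2--7            | --               |
| 5'-end | 7merA1 | 2--7            | across position 1 (target 3' side) |
| 5'-end | 7merM8 | 2--8            | --               |
| 5'-end | 8mer   | 2--8            | across position 1 |
| 3'-end | 6mer   | 14--19          | --               |
| 3'-end | 7merA1 | 14--19          | across position 20 (target 5' side) |
| 3'-end | 7merM8 | 13--19          | --               |
| 3'-end | 8mer   | 13--19          | across position 20 |
| central | 11mer | s..s+10, s in 2..9, covering 9--12 | -- |

Design notes on the genuinely open choices:

* **3'-end anchor.** The 3'-end 6-mer is anchored at position 14
  (`anchor = 14`), with the 7-mer extension reaching position 13. The
  alternative anchoring at 13 (6-mer 13--18) is exposed as
  `anchor = 13` everywhere a scan is run, because both conventions appear
  in the non-conventional-site literature.
* **A1 geometry at the 3' end.** The A1-style kinds require a literal
  adenosine in the target regardless of the miRNA base across from it. For
  the 5'-end seed this is the standard TargetScan convention: the A sits
  across miRNA position 1, on the target's 3' side. We mirror the geometry
  at the 3' end: the A sits across the position flanking the 3' seed
  toward the miRNA terminus (position 20), which places it on the target's
  5' side. The mirror is taken about the seed, not about the target.
* **Precedence.** Each matched locus is assigned exactly one kind, by
  8mer > 7merM8 > 7merA1 > 6mer; a locus counted as a larger kind is
  excluded from every smaller kind whose span it contains. This is what
  makes the 54 counts a partition rather than a nesting.
* **Central sites** are deduplicated by target locus: a window matched by
  several 11-mer frames (possible for repetitive miRNAs) is one site.
* **Reported spans** are the seed-match span only, A1 base included; the
  25-nt alignment window never extends the reported span.

## The duplex alignment (reporting only)

Each reported site carries a local alignment of the miRNA against a 25-nt
target window centered on the site, computed by an affine-gap
Smith--Waterman over antiparallel base pairs: Watson--Crick +5, G:U wobble
+1, mismatch -3, first gap column -8, further columns -2 (miRanda-like
values). No score threshold is applied and the alignment never changes
whether a site is called; it exists so a reader can inspect pairing
geometry outside the seed. The implementation is cross-checked in the test
suite against `Biostrings::pairwiseAlignment` under an equivalent
substitution matrix.

## Conservation

Conservation enters as precomputed conserved blocks in transcript
coordinates (BED, 0-based half-open, chrom = transcript id), e.g. the
product of intersecting a multiple-species alignment across human, chimp,
mouse, rat and dog and mapping it into mRNA space. Blocks shorter than
8 nt are dropped, the rest merged. A site is *conserved* iff its full span
is contained in one merged block: containment, not overlap, because it is
the stricter and exactly reproducible reading, and the A1 base is part of
the span. Computing conservation from raw alignments is out of scope.

## The correlation screen

For each of the 54 types, the per-pair count is correlated (Pearson,
two-sided t-based p) with repression magnitude `-log2fc`, so that "more
sites, stronger repression" prints as a positive coefficient;
`response = "log2fc"` flips to the raw scale. The screen is a raw
p < 0.05 filter with no multiple-testing correction -- deliberately, since
its role is feature triage, not inference; its operating characteristics
under the null are part of the test suite and the acceptance script.
Types with constant counts are reported as undefined rather than dropped,
so the output always has 54 rows in canonical order.

Cohort ECDF comparisons (`ecdf_compare`, `cohort_indices`) contrast
targets with exactly one site of a named class -- and no other site of any
class -- against targets with an all-zero count vector, using the
two-sample Kolmogorov--Smirnov statistic.

## The repression network

The regressor is a 9-4-1 feedforward network, logistic sigmoid in both
layers, trained by online (per-example) backpropagation with squared-error
loss.

* **Inputs**: the nine retained counts, min--max normalized per feature
  over the training set (counts are small integers; the normalization is
  stored in the model). Constant features map to zero.
* **Target transform**: training responses are negative log2 protein fold
  changes. With `c = max(|log2fc|)` over the training set, the target is
  `y = -log2fc / c`, clipped to `(0.01, 0.99)` to keep sigmoid targets
  attainable. The network output is the repression score in (0,1) and
  `-score * c` recovers fold-change units, so higher score means stronger
  predicted repression and the predicted log2 fold change is always
  negative.
* **Defaults**: learning rate 0.01, 4 hidden units, 1000 epochs, weights
  initialized Uniform(-0.5, 0.5) from a caller-supplied seed, momentum 0.
  The presentation order is one seeded shuffle reused across epochs, which
  keeps the fit bit-reproducible from `(data, seed)`; per-epoch
  reshuffling adds nothing at these problem sizes.
* **Cross-validation** (`cross_validate`, default k = 10) shuffles once
  (seeded), deals near-equal folds that partition the records, and scores
  RMSE on predicted versus observed log2 fold change, back-transformed
  through each training split's own `c`. RMSE is reported in
  log2-fold-change units -- the scale the response lives on; a normalized
  reading can be recovered by dividing by `c`.
* **Degenerate inputs**: empty data, any non-negative log2fc, and an
  all-zero target scale are validation errors, not silent fixes.

The fitted object is a classed S3 model (`repress_ann`) with the standard
surface: `print`, `summary`, `coef`, `predict` (score or log2fc),
`fitted`, `residuals`, `plot` (observed vs predicted), `simulate`, plus
JSON serialization (`write_ann`/`read_ann`). `predict_repression` is the
end-to-end composition scan -> project -> forward for one
miRNA--transcript pair.

## What the synthetic generators emulate

All package-level guarantees are demonstrated on seeded synthetic data
with planted ground truth, because the real inputs (proteomics fold-change
tables, AGO PAR-CLIP libraries, conservation tracks) are external
downloads.

* `gen_mirna` draws uniform-composition 22-mers, rejecting any candidate
  in which a target motif of one pairing mode is contained in a motif of
  another mode -- otherwise some planted plans would be intrinsically
  unrealizable (a periodic miRNA can embed its 5'-seed motif inside its
  central 11-mer motif).
* `gen_transcript` draws background sequence free of any motif of the
  paired miRNA (rejection-checked by scanning), plants the requested
  sites at seeded positions with guard bases that block silent upgrades
  to larger kinds, emits conserved blocks (>= 8 nt) covering exactly the
  sites planted as conserved, and verifies by re-scanning that the
  recovered 54-vector equals the planted truth, redrawing on any residual
  collision (cap 1000, then an error). Default region lengths are
  100/200/300 nt (5' UTR / CDS / 3' UTR) -- compact but regionally
  proportioned like a short mRNA, and comfortably larger than the maximal
  planted span.
* `gen_foldchange_dataset` draws feature counts i.i.d. Poisson(0.7)
  (count spectra dominated by 0--2, like per-type site counts) and
  responds with `log2fc = -c * sigmoid(w* . x_norm + b*) + noise`, with
  `c = 2` log2 units, `b* = -2`, `w*` positive Uniform(0.5, 2) (more
  sites, more repression), and Gaussian noise of sd 0.02; the sum is
  clamped just below zero (clamping rather than resampling, so the noise
  distribution is untouched away from the boundary). The ground truth
  `w*` is returned so parameter recovery can be measured.
* `gen_screen_dataset` produces the screen's null (counts independent of
  response) and single-informative-type configurations.

What the generators do **not** emulate: real UTR/CDS length and
composition distributions, PAR-CLIP T-to-C conversion artifacts, shared
seed families across miRNAs, expression-dependent noise, and the
annotation-version effects that dominate published PAR-CLIP tallies.
Passing the closed-loop and recovery suites therefore demonstrates
algorithmic correctness -- the scanner counts exactly what is present; the
network recovers a planted monotone response -- not field performance on
biological data.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the scanner-versus-oracle
sweep on 1000 random pairs (transcripts up to ~300 nt), the closed loop on
200 fixture transcripts, network recovery on 2000 pairs (1500 train / 500
held out), 10-fold cross-validation on a 1501-pair synthetic set, and the
null screen on 200 replicates of 100 records. These sizes give stable
statistics while keeping a full run in tens of seconds.

## Known limitations

* Bulged-seed and distributed-pairing site classes are not modelled; the
  taxonomy is exact-match seeds plus central 11-mers.
* Thermodynamics (duplex free energy, site accessibility) plays no role
  in calling or scoring.
* The network uses only the nine counts; context features (local AU
  content, position in UTR) are out of scope.
* Published repression scores and PAR-CLIP counts depend on specific
  miRNA and transcript annotation releases and on trained weights that
  were never published; this package reproduces the method, and its own
  numbers are those its tests and acceptance script compute.
* Sequence resolution from gene ids or RefSeq accessions is left to the
  user; inputs are sequences plus a region-boundary table.
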