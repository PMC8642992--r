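---
title: "Discovering protein-coding circRNAs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering protein-coding circRNAs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`circorf` turns back-splice junction (BSJ) calls into a ranked list of
circRNAs with coding potential and the junction-specific designs needed
to validate them. This vignette explains the models behind each stage,
the tunable parameters, and the choices made where the design was
genuinely open.

## Coordinates and circle registration

BSJ input is BED-style **0-based half-open**; the annotation is GFF3
**1-based inclusive**. Under this convention a genomic span printed as
`start–end` has circle length `end − start`, which is what makes
published circle lengths reproduce exactly from published coordinates.
Every reconstructed circular sequence is *junction-registered*: position
0 is the first base downstream of the BSJ (the splice-acceptor side), so
the junction always lies between the last and first base of the string.
All "junction-spanning" arithmetic — ORF walks, junction k-mers, siRNA
overhangs, primer amplicons — relies on this single registration.

Category calls use a fixed precedence (exonic > intronic >
sense-overlapping > antisense > intergenic) so the most informative call
wins and the five categories partition all inputs. Whether
"sense-overlapping" should require partial exon overlap or any
same-strand overlap is not settled usage; `circorf` uses *any
same-strand overlap not explained by the exonic or intronic rules* and
documents the call in the catalog.

## The synthetic-data generator

The generator builds a toy genome (default: 2 × 100 kb contigs, 30
genes on both strands), plants 100 BSJ events apportioned over the five
categories (79/1/4/15/1 % by largest-remainder, so realized counts are
within one of the target), and simulates a five-pair tumor/normal count
matrix plus junction-spanning reads. One seed determines every byte;
stages draw from substreams at fixed offsets so they can be regenerated
independently.

### The engineered coding cassette

Six genes host engineered coding circles (one "hot" analog whose host
exon is 959 nt — a single-exon circle from a large internal exon — and
five 600-nt hosts). Writing `L` for the circle length and `s` for the
ORF start (the gene's annotated start codon), the cassette guarantees,
*by construction*:

* a polypyrimidine tract (60 nt C/T) ending 10 nt before the ATG — the
  IRES-like element the scanner must find;
* an in-frame stop immediately upstream of the ATG, so no upstream start
  can extend the planted ORF;
* a stop-free, ATG-free codon body from `s` to the junction, with
  `(L − s) mod 3 = 2` so the junction-spanning codon is split 2 + 1;
* a downstream exon sharing its first **7 nt** with the circle's
  acceptor end. The junction-proximal codons therefore reproduce the
  linear (parental) protein, and divergence is confined to exactly the
  final two residues ("TD") before a stop at circle position 13.

The 7-nt shared prefix is the linchpin of two competing requirements:
the stop codon must start at least 10 nt past the junction (so a FLAG
tag inserted *before the stop* leaves the junction 20-mer intact), while
the shared run must stay below the 10-nt counting anchor (so the
junction 20-mer never occurs in the linear transcript, keeping BSJ read
counting and junction siRNAs circle-specific). Seven shared nucleotides
satisfy both with margin.

### The count model

Counts are negative binomial with shared dispersion
(`var = μ + φμ²`, default φ = 0.1 — a typical patient-to-patient
overdispersion), around a log-normal baseline
`μ = depth · exp(N(0, 0.5))` with default depth 50 junction reads per
circle per sample (most circles in discovery experiments sit below 100
junction reads). Coding circles are planted up `planted_fc`-fold
(default 6) in **every** pair — the pattern of a validated, consistently
elevated coding circle — and 36 non-coding circles are planted *down*
at `1/planted_fc` in 3, 4 or 5 pairs.

Two deliberate choices deserve emphasis:

* **Symmetric planting.** TPM is a relative measure: if a sixth of a
  100-feature table quadruples in tumors, every planted fold change is
  compressed by the inflated denominator, and effects planted at the
  screen's threshold become coin flips. Planting the decoys down, with
  the down-mass matched to the coding up-mass
  (36 × (1 − 1/6) = 6 × (6 − 1)), keeps per-sample totals balanced so
  relative fold changes track planted values. This mirrors standard
  advice for RNA-seq simulation design (balanced DE avoids
  normalization artifacts).
* **Effect size clear of the margin.** The screen's recurrence rule
  (per-pair FC > 2 in ≥ 3 of 5 pairs) sees per-pair log2 noise of
  s.d. ≈ 0.7 at φ = 0.1. A planted six-fold change leaves ~2 log2 units
  of margin, so planted positives are recovered by construction rather
  than by luck; the screen's *operating characteristics* are measured
  separately at a four-fold change (power) and at null (type-I error),
  where the answer is allowed to be statistical.

Parental linear transcripts are simulated so the length-normalized rate
ratio circle:linear is uniform on [0.01, 0.06], the regime observed for
a highly expressed coding circle relative to its host mRNA.

### What the generator does and does not emulate

It emulates: exon/intron gene structure on both strands, all five BSJ
categories, spliced multi-exon circles, overdispersed paired counts
with planted recurrent effects, junction-anchored reads, and an RNase R
arm that retains circular reads and drops linear ones. It does **not**
model sequencing errors, fragment-length distributions, multi-isoform
genes, intron lariats, or genuine IRES structure. Green tests therefore
certify the *logic* of the pipeline — coordinate arithmetic, filter
semantics, round-trips — not performance on real libraries, where
alignment artifacts and isoform ambiguity dominate.

## Quantification

A read counts toward a circle iff it contains the junction
2·anchor-mer exactly (anchor default 10 nt per side; duplicated k-mers
across circles trigger a warning). TPM is computed with the textbook
formula per sample; an all-zero sample stays all-zero. For
circle-versus-linear comparisons both feature sets are normalized in
**one** table (`combined_circ_linear_tpm()`): two tables separately
scaled to 10⁶ cannot both sum to 10⁶ while every circle sits far below
its parent — a shared denominator is how a joint quantification reports
both features, and it makes the 0.01–0.06 ratio regime reproducible.
The expression screen itself normalizes the circle table alone. Ratios
with a zero denominator are reported as `NA`, never 0.

## The expression screen

Fold changes use pseudocount ε = 0.5; the test is a two-sided paired t
on `log2(tpm + ε)`, with the decision rule *fold-change magnitude > 2
and p < 0.05* applied to raw p-values (a Benjamini–Hochberg column is
available behind `adjust = "BH"`). A moderated-variance model would be
the natural upgrade on real data; the plain paired t keeps the decision
rule transparent and exactly reproduces the published thresholds.
Zero-variance features get p = 1 plus a degenerate flag rather than an
error. Recurrence uses strict `FC > 2` (values exactly 2 do not count)
in ≥ 3 pairs. The ROC utility computes AUC by the tie-corrected rank
statistic and reports the Youden-optimal cutoff *at an observed value*,
breaking J ties toward higher specificity — the convention in clinical
reporting.

## The coding screen

Every ATG on the circle (including starts that themselves span the
junction) opens a codon walk modulo L under the standard nuclear code.
Walks stop at the first in-frame stop or after `max_cycles` (default 3)
full turns, in which case the ORF is flagged *rolling-circle* and its
protein truncated at the cap — never silently emitted. `nt_length`
includes the stop codon; the protein excludes it. Stopped ORFs are
deduplicated to the longest per stop position; rolling walks are kept
one per initiating ATG (deduplicating them per frame-orbit would break
rotation covariance whenever an orbit contains several ATGs). Codons
containing ambiguity codes abort the walk with a flag. For circles
whose length is not a multiple of 3, a walk visits every position
within three turns, so a single stop anywhere terminates every ORF —
the `max_cycles` cap only ever bites on genuinely stop-free circles.

The IRES scanner is an explicit proxy, not a folding model: 150-nt
windows at 10-nt steps scored as
`pyrimidine fraction + longest C/T run / window + 0.2·[ATG within 20 nt
downstream]`, threshold 1.0, overlapping hits merged. The weights place
typical random sequence near 0.75–0.9 and a planted 60-nt tract with a
downstream start near 1.3. Externally predicted intervals can be
imported verbatim and are reported 1-based inclusive, matching how IRES
coordinates are printed. Candidate ranking applies the funnel in order
— expression + recurrence, circle length within [200, 3000] nt,
junction-spanning ORF ≥ 50 aa, ORF start within the first half of the
circle (a documented stand-in for the unstated "ORF position"
criterion; fully configurable), and an IRES hit not wholly inside the
ORF's final 30 nt — then ranks by ORF length, ties by IRES score.

## Validation designs

The FLAG tag (3×DYKDDDDK by default) is inserted immediately before the
ORF's stop codon: the construct's junction 20-mer equals the wild
type's and its protein is the wild-type protein plus tag residues, both
re-verified by re-screening the construct. Start mutants use ATG→CTG
(one transversion, no new ATG) and warn when an alternative in-frame
start can still reach the original stop. Divergent primers anneal on
opposite sides of the junction (length 18–24 nt, GC 40–60 %, amplicon
80–200 nt) and are chosen by a deterministic score (GC distance from
50 % plus amplicon centering) — no nearest-neighbor thermodynamics, by
design, so results are reproducible and testable. Junction siRNAs must
straddle the junction with ≥ 4 nt on each side and not occur in the
linear transcript. Tryptic digestion cleaves after K/R except before P;
peptides covering a divergence position between the circle protein and
the parental prefix are the distinguishing (mass-spectrometry-visible)
evidence. The TCF promoter scan matches (A/T)(A/T)CAAAG on both
strands; N never matches.

## Numerical conventions and test scales

Percentages in catalog summaries round half away from zero (printed-
report style). Determinism is byte-level for all non-timing outputs.
The shipped tests run the generator at 100 circles / 5 pairs
(the default screen), ORF-oracle comparisons on 500 random circles of
length ≤ 30 against an exhaustive modular-walk oracle, rotation checks
on 100 circles across all rotations, DE calibration on 1,000 null
features (50 planted at four-fold for power), and 1,000 random-protein
digest identities — sizes chosen to give the statistical checks
comfortable resolution while keeping a full run in tens of seconds.

## Known limitations

Classification uses one representative transcript per gene; alternative
circular isoforms sharing a BSJ are not resolved. Counting is
exact-match (no mismatches), so sequencing errors at the junction are
invisible by design. The IRES heuristic has no structural component.
The paired t-test does not share variance across features. None of
these affect the package's contracts on synthetic data; all matter when
moving to real libraries.
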