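---
title: "Methods: error-aware isomiR characterization with mirforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: error-aware isomiR characterization with mirforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirforge)
```

# The problem

IsomiRs are mature miRNA variants that differ from their canonical
sequence at the 5' and/or 3' end: non-templated nucleotide additions
(typically 3' uridylation), terminal substitutions, or shifted processing.
Distinguishing them from technical artifacts is the central difficulty:
the small-RNA pipeline (RNA extraction, cDNA synthesis, library
preparation, sequencing) produces erroneous sequence variants (ESVs) whose
positional distribution mimics isomiRs — they concentrate at read ends.
Phred scores only describe the sequencer, not the upstream chemistry, so
error control must be *measured* from the data. `mirforge` implements
that measurement and the downstream variant-calling, annotation, target
and expression analyses, all exercisable on a built-in generator.

# The ESV error model

## Measurement

Collapsed reads (unique sequences with counts) are aligned ungapped to two
abundant control RNAs — emulating an 18S rRNA (1750 nt) and a short
ribosomal-protein mRNA (540 nt) — chosen because reads deriving from
anywhere in these transcripts are not expected to be RNA-edited, so every
mismatch is pipeline error. The aligner scans every offset exhaustively,
takes the placement with the fewest mismatches (ties: smallest offset;
ties between references: first reference in input order) and discards
reads above `max_mismatches = 3`. Indel-containing reads simply fail to
align; with 18–25-nt reads this loses a negligible, unbiased fraction.

## The ratio convention

Read positions fall into three classes: the first `window` bases
(5'-terminal), the last `window` (3'-terminal) and the rest (internal).
The window defaults to 2 and is configurable, because "the last bases" of
a read is not a sharply defined region; 2 keeps the terminal classes
well-populated while capturing the end bias. Each class ratio is the
count-weighted *per-base-call mismatch frequency*:

$$ r_c = \frac{\text{mismatching base calls in class } c}
             {\text{aligned base calls in class } c}. $$

Two alternative conventions exist in the literature: ratios of
variant-bearing reads to perfectly aligned reads, and per-position
mismatch/match odds. We use the per-base-call frequency because (i) it is
directly comparable to the Phred-implied per-bp error probability
$10^{-Q/10}$ (e.g. Q32 → 0.00063), which is the benchmark that makes the
3'-terminal excess interpretable; and (ii) it is an unbiased estimator of
a per-base substitution rate, so simulation-based validation has an exact
target. Under typical values (3'-terminal ≈ 0.21, 5'-terminal ≈ 0.02,
internal ≈ 0.0004) a read-level odds convention would instead converge to
$[1-(1-q)^w]/(1-q)^w \approx 0.60$ at the 3' end — a quantity that depends
on the window width and is not comparable across conventions.

## From rates to thresholds

The count of reads identical to a canonical miRNA, $N$, sets the scale for
how many ESV copies of any specific variant the pipeline could plausibly
generate from that canonical pool. A variant of class $c$ must reach

$$ \max(\texttt{min\_count},\ \lceil \alpha\, r_c\, N \rceil) $$

to be accepted. $r_c N$ is an upper bound on the expected count of reads
carrying *some* class-$c$ error at a given position; a specific variant
(one position, one alternative base) occurs at roughly a sixth of that, so
$\alpha = 2$ gives an order-of-magnitude safety margin against noise in
$\hat r_c$ without suppressing genuine variants. `min_count = 10` guards
the internal class, whose rate is so low that $\alpha r_c N$ is often
below one read. Both are configurable (`filter_params()`).

# IsomiR classification

Classification is seed-anchored: a read is considered against a canonical
only where the canonical's seed (bases 2–8) occurs *exactly* in the read.
The implied offset fixes an ungapped alignment and the category:

* `canonical` — identical;
* `isomir_3p_sub` — same 5' start, substitutions confined to the last
  `window` bases;
* `isomir_3p_len` — same 5' start, 3' extension (or shortening);
* `isomir_5p` — different 5' start or a first-base substitution;
* `mismatch_internal` — internal substitutions (takes precedence when a
  read carries both internal and terminal edits).

When several canonicals anchor, the fewest-edits assignment wins, with
ties broken by canonical id order — determinism matters more here than any
particular choice. Reads whose only edits fall inside the seed do not
anchor to that canonical; consequently seed-internal allelic variants are
not discoverable by this route (they surface, if at all, as anchors to
other family members). This is the same behavior as seed-extension isomiR
aligners and is a documented limitation.

Two filters remove variant classes that cannot be distinguished from
artifacts even in principle:

* reads *shorter* than their canonical are dropped — degradation products
  of the canonical are sequence-identical to 5'/3'-shortened isomiRs;
* *templated* end variants (the extension matches the genomic context in
  the precursor/flanks) are dropped — precursor fragments produce the same
  sequences. Substitutions are never templated by definition. Reportable
  isomiRs are therefore exactly the non-templated 5', 3' and 3'-length
  variants.

Internal single substitutions passing the ESV threshold with an allele
read fraction `variant/(variant + canonical)` *strictly* above 0.40 are
reported as polymorphisms (allelic variants) rather than RNA editing; the
fraction uses only the two allele counts, not other isoforms, matching the
two-allele framing of such variants.

# Novel-miRNA validation and cluster annotation

Candidate precursors (with ingested discovery scores; the discovery
algorithm itself is out of scope) pass a score cutoff of ≥ 2, a repeat
filter (more than 15 exact genomic loci, both strands, flags an
interspersed repeat) and five read/structure criteria: (1) evidence in ≥ 2
samples; (2) ≥ 10 perfectly matching mature/star reads; (3) the two arms
pair with each other in the folded hairpin with 0–4-nt 3' overhangs;
(4) 5'-processing homogeneity — the modal 5' start carries ≥ 90% of the
dominant arm's perfect reads (the 0.9 quantifies "consistent 5' end" and
is configurable); (5) > 60% of each mature's bases paired.

Folding is maximum-cardinality nested base pairing (AU/GC/GU, minimum loop
3) by dynamic programming with a deterministic traceback (pair the outer
bases if optimal, else shrink from the left, else bifurcate at the
smallest split). A thermodynamic folder is deliberately not used: criteria
3 and 5 are pairing-count criteria, and a pairing-maximal structure gives
them a well-defined, reproducible meaning. The folding kernel is verified
against exhaustive structure enumeration for sequences up to 14 nt.

Gene clusters chain same-contig, same-strand loci whose inter-gene *gap*
(end of one to start of the next, 0-based half-open internally) is at most
10 kb, single-linkage; gap-wise distance is the stricter and conventional
reading of "within 10 kb". GFF3 output converts to 1-based inclusive
coordinates.

# Target prediction

A target site is a perfect Watson–Crick reverse complement of the seed
(mature bases 2–8, 1-based; no G:U in seed). The optional stability filter
extends the seed duplex in both directions while Watson–Crick or G:U
pairing holds — internal loops and bulges terminate extension — and sums
nearest-neighbor stacking energies over the paired run, with the standard
ten-parameter Watson–Crick stack table bundled (`rna_nn_table()`) and a
fixed −0.5 kcal/mol for wobble-containing stacks (a simplification; wobble
stacks are weak and rarely decisive at the −18 kcal/mol threshold).
Transcript-level set comparisons (canonical vs variant repertoires) count
a transcript once regardless of site multiplicity, so a 3'-only variant
adds exactly zero targets by construction, while a seed variant defines a
disjoint site motif. This engine is intentionally simpler than a full
hybridization folder: it is self-contained, monotone (more complementary
context never destabilizes) and sufficient for seed-plus-supplementary
scoring; absolute energies are not comparable to full-model values.

# Expression and qPCR analysis

Counts are normalized to reads per million per sample; replicate samples
of a tissue are averaged afterwards. A miRNA is *ubiquitous* when its
max/min tissue RPM ratio is ≤ 3 (requiring nonzero expression everywhere)
and *enriched* in a tissue set S when every member of S exceeds 10× the
mean RPM of the non-members, S grown greedily from the top tissue so that
"one or a few" tissues (e.g. muscle + heart) can qualify; the mean of the
others is the baseline, and a zero baseline yields no call (a fold over
zero is undefined). Developmental summaries count a miRNA as detected at
≥ 1 raw read (configurable) and report per-stage abundance proportions,
with family-level sums.

ΔΔCt analysis normalizes each Cq against the arithmetic mean of the two
reference miRNAs (the combination of the two references is not otherwise
specified; the arithmetic mean of Cq is the conventional choice), takes
the focal-tissue mean ΔCt minus the mean over all other samples pooled,
and reports fold = $2^{-\Delta\Delta Ct}$ with a pooled-variance t-test
and Bonferroni correction by the number of contrasts in the batch.

# The synthetic-data generator

The generator emulates the read structure the analysis assumes, with a
ground-truth manifest for every read:

* canonical matures 18–25 nt on designed hairpins (55–70 nt) whose arms
  are exact prefix/suffix substrings with 30-nt genomic flanks recorded;
  seed heptamers are unique across genes; the base following the 5p arm
  and the base downstream of the 3p arm are fixed to `A` so a planted 3'
  U-addition is always non-templated;
* planted variants, relative to a parent canonical of weight 1: a 3' U
  addition (2.5), a 3'-terminal substitution (2.5), a first-base 5'
  variant (0.25) and an internal allelic variant at 0.5 allele fraction.
  The 3'-class abundances are set so planted variants clear five times
  their ESV threshold under the default error rates — with a 3'-terminal
  rate of 0.21 the threshold is 0.42 N, so reliably detectable 3' variants
  must rival their canonical in abundance, which the real data's
  "variant more abundant than canonical" cases mirror;
* control-RNA fragments (default 20% of the library — the control-read
  share is a free choice, set to make error estimation well-powered at
  desk scale), degradation fragments (3'-truncated canonicals, 5%) and
  precursor fragments (random precursor substrings, 5%, which exercise the
  templated-variant exclusion);
* per-base substitution errors, applied independently at the class rate
  of each position (5'-terminal 0.02, internal 0.0004, 3'-terminal 0.21);
  no indel errors, since length variants are handled as a separate class
  and templated length variants are discarded anyway;
* single-end 36-cycle reads with 3' adapter read-through and a constant
  quality symbol (coupling qualities to the error model is a non-goal:
  the package's point is that Phred does not predict these errors).

What the generator does *not* emulate: sequence-dependent error hotspots,
PCR duplication, ligation bias, true RNA editing beyond the planted edits,
and realistic miRNA abundance distributions (gene weights are equal).
Passing recovery tests therefore demonstrates the *logic* of the pipeline
— rate estimation, thresholding, templated/length exclusions,
classification — not robustness to every bias of real libraries.

# Numerical choices and problem sizes

Error-rate validation and the shipped acceptance computation use 100,000
control-derived reads, where each class estimate sits within 3 binomial
standard deviations of its rate; full-pipeline recovery uses the default
100,000-read library with 20 genes. Unit tests use smaller libraries
(5,000–30,000 reads). All generators are deterministic given the
configuration seed; every stochastic test fixes one. Tie-breaks are
specified everywhere (alignment: smallest offset; classification: fewest
edits then id order; collapsing: count then lexicographic; folding: the
traceback order above) so repeated runs are byte-identical.

# Known limitations

* Seed-internal variants cannot anchor (above); allelic variants in the
  seed must be assessed by direct pair comparison
  (`compare_allelic_pair()`).
* The duplex model ignores loops, bulges, dangling ends and initiation
  terms; its threshold is calibrated to the bundled table only.
* Ungapped alignment discards indel-bearing reads rather than modeling
  them.
* The hairpin folder maximizes pairing count, not free energy; criteria
  derived from it are conventions, not thermodynamic statements.
* Per-sample versus pooled thresholding is left to the caller: the filter
  operates on whatever read pool it is given.
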