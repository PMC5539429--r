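---
title: "Methods: Tn-seq competitiveness analysis in tncomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Tn-seq competitiveness analysis in tncomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tncomp)
```

## The experimental design being modelled

A mariner (HIMAR1) transposon library — insertions strictly at TA
dinucleotides — is grown under an antimicrobial challenge and in an
untreated control, in two biological replicates, for a small number of net
population doublings (the design this package targets concludes two to
four). Each sequenced sample is one of: the **input** library before
outgrowth, the **nontreated** control after outgrowth, or a **treated**
culture after outgrowth. Because the transposon construct carries flanking
MmeI sites, each read consists of a fixed 32-nt transposon end sequence
followed by a short tag of chromosomal DNA that localizes the insertion.

Under exponential selection, an insertion with relative fitness $w$
changes in frequency by $w^D$ over $D$ doublings. The per-gene
**competition index**

$$\mathrm{CI} = \frac{\text{normalized treated count}}
                     {\text{normalized untreated count}}$$

therefore estimates $(w_\text{treated}/w_\text{untreated})^D$, with
$\mathrm{CI}=1$ meaning no treatment-specific effect. Genes are called by
fold-change concordance, not by a significance test: twofold or more, in
the same direction, in both biological replicates.

## Pipeline stages and their parameters

### Read preparation

The transposon end sequence (default
`CGATCTAGACCGGGGACTTATCATCCAACCTG`, 32 nt) is located by scanning every
offset of the read and taking the **leftmost offset achieving the minimal
Hamming distance**, accepted when that distance is at most
`max_mismatches` (default 3). Scanning, rather than anchoring at offset 0,
is the safer superset — it tolerates small amounts of leading adapter —
and an `anchor0` switch restores anchored behaviour. `N` never matches
anything, including another `N`: an uncalled base cannot support a match.

The genomic tag is the `tag_length` bases immediately following the
transposon match. The default is 17 nt. MmeI liberates 16–18 bp and
protocols differ in how many bases are usable; because the correct value
is a property of the library construction rather than of the software, it
is a parameter, not a constant. Reads in which the transposon is found but
fewer than `tag_length` bases remain are counted as *too short*; reads
without an acceptable match are *no transposon*; everything else is
*used*. These three buckets partition the input exactly — the accounting
identity `total = no_tn + too_short + used` is asserted throughout and is
the first thing to check when numbers look odd.

Quality scores are parsed but unused: the analysis depends on exact tag
identity, and a miscalled tag base simply fails to map rather than mapping
wrongly, so quality filtering would only re-label reads that already drop
out.

### Site mapping

Tags are matched against a precomputed index of every genomic k-mer on
both strands, **exactly and unique-only**: zero mismatches (a 17-mer has
little redundancy to spare, and a one-mismatch hit is more likely a
sequencing error on another site's tag than a real insertion), and tags
occurring more than once across both strands of all replicons are counted
as *ambiguous* but never located. Random assignment of multi-mappers would
manufacture counts at repeated loci; discarding them costs a known,
reported fraction of reads instead. k-mers containing `N` are unmappable
and excluded from the index. A palindromic k-mer is indexed once per
strand and is therefore always ambiguous — correctly so, since the read
cannot tell the two orientations apart.

The insertion-site coordinate is the genomic base abutting the transposon
junction: `(s, +)` for a forward match starting at `s`, and
`(s + k - 1, -)` for a reverse-strand match occupying `[s, s + k - 1]`.
Opposite-strand sites at one TA are kept separate — all downstream
statistics are gene-level sums, where merging would change nothing — and
the site table records whether each junction begins a TA on its strand as
a QC column (in a clean mariner library it always should).

### Quantification and normalization

A site contributes to a gene iff its position lies in the gene's **core
region**: with gene length $L$ and edge width $e = \lfloor 0.1 L \rfloor$,
the core is $[start + e,\; end - e]$. Insertions in the outer 10% of an
ORF frequently leave enough of the protein intact to score as functional,
so they are ignored; `floor` makes genes shorter than 10 bp degrade
gracefully to a whole-gene core. The rule is strand-independent — a
transposon disrupts a gene whichever way either faces. A site inside two
overlapping cores credits both genes.

Samples are normalized on the premise that **intergenic insertions are
selectively neutral**: positions covered by no annotated gene interval
(edges belong to genes, not to the intergenic mask) should be equally
represented everywhere, so each sample is scaled by
$\mathrm{NF}(s) = \min_t I(t) / I(s)$, where $I$ is the intergenic read
total. Exactly the minimal sample(s) get NF = 1, and the grouping spans
all samples of the run — both replicates, all conditions — in one pool.
Because NF is a scalar per sample, normalizing per-site counts and
normalizing per-gene sums are algebraically identical; the package
normalizes gene sums. Zero intergenic reads in any sample is an error, not
a silent NF of infinity.

Reported tables print NF at 3 decimals and the normalized sample total as
`round(total_reads × NF)` with **half-away-from-zero** rounding (matching
the convention of printed reports in this field, where the printed NF
times the printed total reproduces the printed normalized total); all
statistical computation uses full-precision reals.

### Filters and classification

* **Underrepresented**: normalized input count below 100 in *either*
  replicate. The comparator is strictly-less-than by default
  (`under_cmp = "lt"`), with `"le"` available; published descriptions of
  this screen family state the rule both ways and the difference touches
  only genes exactly at the boundary.
* **Growth-impaired**: nontreated/input ratio below 0.5 — i.e. more than
  a twofold competitiveness loss without any treatment — in either
  replicate by default (`growth_mode = "either"`; `"both"` is available).
  "Either" is the conservative choice against mistaking a general growth
  defect for treatment sensitivity. The ratio is only evaluated for genes
  that passed the underrepresentation filter, which guarantees a nonzero
  denominator.
* **Classification**: `REDUCED_COMPETITIVENESS` iff CI ≤ 0.5 in both
  replicates; `INCREASED_COMPETITIVENESS` iff CI ≥ 2 in both; boundaries
  inclusive (figure-legend conventions in this literature use ≤/≥, and an
  open boundary would make calls depend on floating-point dust at exactly
  0.5). A CI with untreated count 0 is undefined and excludes the gene
  (`NOT_ANALYZED`) rather than being imputed; a `pseudocount` option
  exists but defaults off, because an imputed ratio at the depths involved
  is an arbitrary number with a confident face.

## The simulator

`sim_config()` describes a complete synthetic experiment; its defaults are
the package's reference conditions: a 200 kb single-replicon genome with
150 ORFs of 300–3000 bp, 5000 insertions, log-normal initial abundances
(σ = 0.5), D = 3 doublings, 2 × 10⁶ reads per sample, 60-nt reads with 1%
per-base transposon errors and error-free tags, and two biological
replicates realized as independent multinomial draws from per-site
log-normally jittered abundances (σ = 0.1).

Choices worth spelling out:

* **Gene packing.** 150 ORFs drawn i.i.d. uniform on 300–3000 bp have an
  expected total of ~247 kb and cannot fit a 200 kb genome. The generator
  therefore draws lengths uniformly and, when the draw does not fit with
  the required ≥ 50 bp gaps, rescales lengths linearly toward the 300 bp
  minimum. The resulting ~85% coding density is realistic for a bacterial
  chromosome. Leftover space is distributed randomly among the gaps.
* **Tag uniqueness.** Generated genomes are rejected and redrawn unless
  ≥ 99% of their k-mers (both strands) are unique, so exact mapping is
  near-lossless by construction — as it is for a real bacterial genome at
  k = 17.
* **Selection** is deterministic exponential growth, $a_i' \propto a_i
  w_i^{D}$, with sequencing noise as the only stochastic term. With
  thousands of cells per mutant, genetic drift is second-order relative to
  multinomial sampling at these depths. Insertions in gene cores inherit
  the gene's fitness; edge and intergenic insertions are neutral —
  encoding the same assumption the edge-exclusion and normalization rules
  make.
* **Two sequencing modes.** `sim_fastq()` writes literal reads
  (transposon + strand-correct tag + random filler, constant quality) and
  exercises the full read-processing path. `sim_counts()` draws the same
  multinomial site counts without rendering reads: with zero error rates,
  trimming and exact unique mapping are lossless, so the count mode is
  distributionally identical to the FASTQ mode's output while being orders
  of magnitude faster. The equivalence is itself tested (an error-free
  FASTQ run recovers its library's site counts exactly, up to
  ambiguous-tag sites).
* **What is not modelled.** PCR duplicates and amplification bias, indels,
  quality-score structure, chromosomal position effects, bottlenecks and
  drift, multi-replicon genomes, and real TA-site density variation. A
  passing recovery test therefore shows the *analysis* is correct under
  the stated generative assumptions, not that real libraries meet those
  assumptions.

## Calibration and recovery checks

The test suite runs the simulate→analyze chain at two operating points,
20 seeds each, at 10⁶ reads per sample with the default 150-gene genome:

* **Null calibration** (all $w = 1$): across 20 seeds the fraction of
  analyzable genes called in either direction must be ≤ 2%; observed runs
  give essentially 0, as expected — per-gene counts in the thousands make
  a spurious concordant twofold change in both replicates vanishingly
  unlikely.
* **Recovery** (eight genes at $w_\text{treated} = 0.63$, D = 3, expected
  CI $0.63^3 \approx 0.25$): ≥ 95% of gene × seed combinations must be
  called `REDUCED_COMPETITIVENESS` and the median estimated CI must lie
  within ±20% of 0.25. Observed: 100% recovery, median within ~1%.
* **Scale invariance**: tripling one sample's counts changes no CI beyond
  floating-point tolerance, because the intergenic NF absorbs any
  per-sample scalar exactly.

These problem sizes (10⁶ reads count-level for the screens, one 2 × 10⁶
read FASTQ sample for the accounting check) keep the full suite and the
acceptance script within a few minutes on a single core while leaving the
statistical margins above wide.

## Numerical and convention choices

* Coordinates are 1-based inclusive everywhere, matching PTT/GFF3 and the
  IRanges/Biostrings infrastructure the package is built on.
* Tie-break in fuzzy scanning: leftmost among minimal distances,
  implemented by only accepting strict improvements while scanning left to
  right (which also enables an early exit at the current best).
* Reported integer columns round half away from zero; `base::round()`
  rounds half to even and would disagree with printed reports on exact
  halves.
* Degenerate inputs: empty FASTQ files yield all-zero accounting; a
  profile with no sites yields zero gene counts and an error only where an
  undefined quantity would otherwise propagate (NF with zero intergenic
  reads); genes shorter than 10 bp have a whole-gene core; palindromic and
  repeated tags are ambiguous by construction.
* Annotation input accepts PTT and GFF3; whether coordinates are CDS-level
  or gene-level is the annotation's business — the pipeline treats the
  interval as "the ORF" either way, and runs should document which flavour
  they supplied.

## Known limitations

* Exactly two biological replicates are supported for classification; the
  concordance rule is defined over a replicate pair.
* No significance testing, fitness ($W$) estimation, or FDR control — the
  method is fold-change concordance, by design.
* Unique-only exact mapping discards reads from repeated loci; genes
  residing largely in repeats will look underrepresented and be excluded
  rather than mis-scored.
* Circular-origin-spanning genes and spliced features are rejected rather
  than handled.
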