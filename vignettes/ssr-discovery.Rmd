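---
title: "In-silico discovery of polymorphic SSR markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico discovery of polymorphic SSR markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrscape)
```

## The problem

Simple sequence repeats (SSRs, microsatellites) are tandem repetitions of
2–6 bp motifs. They make cheap, co-dominant, multi-allelic markers, but
most loci mined from a reference genome turn out monomorphic in the
panel of interest, so wet-lab screening wastes most of its effort.
When whole-genome resequencing of a panel is available, polymorphism can
instead be screened *in silico*: align each accession's reads to the
reference, count the repeat units each spanning read implies, call a
diploid repeat-count genotype per accession at every candidate locus,
and keep the loci where the panel actually segregates. `ssrscape`
implements that strategy end to end at desk scale, together with a
synthetic-data generator that provides ground truth for every stage.

## Mining perfect repeats

`find_ssrs()` reports every maximal perfect tandem run of a *primitive*
motif (one that is not itself a tandem of a shorter word) with unit
length 2–6. Minimum repeat counts default to 6, 5, 4, 4, 4 for di-
through hexanucleotides. Mononucleotide runs are excluded by the
primitivity rule (an "AA" unit is a tandem of "A"). Runs are broken at
N. A run representable at several unit lengths is reported once, at the
smallest primitive unit, so (AT)×6 is never double-counted as (ATAT)×3.

Two numerical details are worth stating:

* **Run anchoring.** Detection scans for period-*k* character equality,
  so a run is anchored at the leftmost position where the periodicity
  starts. When background happens to extend a planted motif's
  periodicity by a partial unit, the reported motif is the
  corresponding rotation (e.g. `GAT` instead of `ATG`), which is the
  same repeat tract by any operational definition. Motifs are reported
  as they occur on the forward strand; no reverse-complement or
  rotation merging is done at detection time.
* **Overlap resolution.** Maximal runs at *different* unit lengths can
  overlap on adversarial sequences (`...ATATATAT|GATGATGATGAT...`
  supports both a di- and an overlapping trinucleotide run). Reported
  loci must not overlap, so the locus starting earlier (then the
  smaller unit length) wins. Uniform random sequence essentially never
  triggers this; the rule exists so the output is well-defined on all
  inputs, and the brute-force oracle in the test suite applies the same
  rule.

Locus-level filters mirror the standard discovery cascade: loci with no
feasible primer pair are dropped first, then motifs whose alphabet is
only A/T (notoriously hard to score), then every member of any pair of
loci lying closer than 100 bp (both members are removed — a locus with
a close neighbour cannot be amplified specifically regardless of which
neighbour is kept). Each stage records input/kept/removed counts in a
`filter_ledger` whose conservation (kept + removed = input; stages
chain) is enforced on every run, not only in tests.

## Primer feasibility

`design_primer_pair()` is a deterministic feasibility oracle, not a
thermodynamic designer. Candidate forward primers are substrings of the
250 bp left flank ending at least 1 bp before the tract; reverse
primers are reverse complements of right-flank substrings starting at
least 1 bp after it. A candidate must have length 18–25 nt (optimum
20), GC ≥ 0.40, melting temperature within 59–61 °C (optimum 60), no
homopolymer run of 5+, and the pair's 3'-terminal 4-mers must not be
mutually complementary. Melting temperature uses the composition
formula

$$T_m = 64.9 + 41\,(n_{GC} - 16.4)/N,$$

which is monotone in GC count at fixed length — sufficient for a
reproducible designable/undesignable split, and documented here
precisely because it is *not* a nearest-neighbour model: absolute
designability rates will differ from a thermodynamic designer's. Among
admissible pairs whose product (spanning the whole tract) lies in
100–400 bp, the pair minimising (|Tm − 60| summed, then |len − 20|
summed, then product length, then leftmost/shortest) is returned, so
identical inputs always give identical pairs. Forward primers are
M13-tailed (`CACGACGTTGTAAAACGAC` at the 5' end) for fluorescent
fragment sizing.

## Genotyping repeat length from alignments

A read is *spanning* at a locus when its alignment covers the tract
plus a 10 bp anchor on both sides (the anchor width is configurable;
published STR callers do not document a single canonical value). Its
observed repeat count is

> (reference tract span + inserted − deleted bp whose reference
> position falls inside the tract) / unit length,

*off-frame* when that is not a whole number of units. Indels touching
the anchor windows set a flank-indel flag. Reads are taken at face
value — no local realignment.

Stutter (the PCR/sequencing artifact that shifts apparent repeat counts
by whole units) is modelled globally and symmetrically: a read reports
its true allele $a$ with probability $1 - p_s$ and otherwise gains or
loses $g \sim \text{Geometric}(\rho)$ units with fair sign:

$$P(k \mid a) = \begin{cases} 1 - p_s & k = a\\
p_s\,(1-\rho)\,\rho^{|k-a|-1}/2 & k \ne a.\end{cases}$$

Defaults are $p_s = 0.05$, $\rho = 0.8$. A diploid genotype's per-read
likelihood is the equal mixture $\tfrac12 P(k\mid a_1) + \tfrac12
P(k\mid a_2)$; candidate alleles are the distinct in-frame observed
counts plus the reference count, the genotype space is all unordered
pairs under a uniform prior, and the call's quality is the posterior of
the maximum-a-posteriori pair. Posterior ties break toward the pair
containing the reference allele, then lexicographically, so calls are
deterministic. This replaces locus-specific learned stutter models and
haplotype realignment used by full STR callers; it preserves the
decision structure (quality, flank-indel and stutter filters) while
being fully specified.

Calls are filtered in this order, each failure recorded as a MISSING
reason: fewer than 5 spanning reads (`no_reads`); flank-indel read
fraction > 0.15 (`flank_indel`); no usable in-frame read (`off_frame`);
discordant-read fraction > 0.15, off-frame reads included
(`stutter`); posterior < 0.9 (`low_qual`). The three fraction/quality
thresholds are the conventional STR call-filter settings this pipeline
is built around. Flank-indel reads are excluded from the likelihood, so
the flank check runs before quality can be computed; the remaining
order puts cheap read-level evidence before the posterior check.

## Polymorphism screening

A locus is dropped as `mono_or_missing` when no accession has a
non-reference PASS call (that covers both the all-missing and the
all-homozygous-reference cases); dropped as `low_nonref` when fewer
than 2 accessions carry a non-reference allele (a heterozygous ref/alt
call counts as carrying one); kept otherwise. The ≥ 2-accession
keep-rule follows the procedural statement of the cascade this package
reproduces; an optional `max_missing_fraction` tightens the missingness
screen for panels where half-dark loci are unwanted. Kept loci are
annotated genic/intergenic by ≥ 1 bp overlap with gene features
(GFF3 1-based inclusive coordinates converted centrally to the 0-based
half-open convention used everywhere else).

## Marker statistics on band scores

Validation-style data are dominant 1/0 band scores per (locus, allele).
Because dominant scoring cannot distinguish homozygotes from
heterozygotes, allele frequencies are *band shares*: carriers of an
allele divided by total carrier counts at the locus. On those
frequencies,

$$H_e = 1 - \sum_i p_i^2, \qquad
\text{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2,$$

the Botstein/PowerMarker convention for PIC; \(0 \le \text{PIC} \le H_e
< 1\) always, with equality only at monomorphic loci. Report tables
round half-up to 2 decimals; all computation keeps full precision.
PCA mean-imputes missing marks per column, centres, and takes the SVD
with the sign of each component fixed so its largest-magnitude loading
is positive. Accession distances are Jaccard distances on the binary
profiles — a nucleotide-substitution model is not applicable to band
data, so no attempt is made to mimic one. Trees come from Saitou–Nei
neighbour joining (via `ape`); additive matrices are recovered exactly,
and negative branch lengths are clamped to zero and flagged. A
STRUCTURE-format exporter (one row per accession, −9 for missing)
covers downstream Bayesian clustering, which this package deliberately
does not re-implement.

## The synthetic-data generator

`simulate_reference()`, `simulate_panel()` and `simulate_reads()`
emulate the study conditions the pipeline targets: a multi-chromosome
reference with planted perfect SSR tracts, a 21-accession diploid panel
resequenced to 30× depth, and stutter-noised reads. Defaults that the
conditions do not pin down were chosen once as field-realistic values
and documented here: 40% of loci polymorphic with alternate alleles
within ±3 repeat units (resequencing panels of a selfing crop segregate
at a minority of mined loci, and repeat-count variants cluster near the
reference length), read length 100 bp, substitution errors at
10⁻³/bp outside the anchors, 30% of loci covered by a planted gene.

Design guarantees that make truth exact rather than probabilistic:
planted loci sit in evenly spaced slots wide enough that the proximity
filter and 250 bp flanks can never collide; guard bases prevent a
tract's periodicity from extending into its flanks; and after planting,
the background is screened and any accidental qualifying run is
disrupted, so mining truth is unambiguous. Each locus is drawn
polymorphic with the configured probability, and the recorded truth
flag is evaluated on the realised genotypes with exactly the screen's
keep-rule, so screen-versus-truth comparisons are definitional, not
statistical. Reads are emitted pre-aligned (correct POS and CIGAR, with
indels placed at interior unit boundaries of the tract) rather than as
FASTQ: alignment is outside the package's scope and the planted CIGARs
exercise the genotyper's tract arithmetic directly. Reads are written
as single-end records (flag 0); simulating mate pairs would add SAM
bookkeeping without adding information, since only spanning reads
inform the genotype.

Everything is a deterministic function of the config seed
(byte-identical FASTA/SAM/TSV on re-runs).

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: indel sequencing errors outside tracts,
locus-specific stutter rates, PCR duplicates, coverage and GC biases,
misalignment around repeats, and reference errors. Concordance numbers
on synthetic data are therefore upper bounds on real-data performance.

## Problem sizes and verification

The test suite verifies detection against a brute-force
per-(position, unit-length) scanner on 200 random 10 kb sequences;
genotype calls against exhaustive enumeration over the candidate-pair
space; He/PIC against closed forms and 10⁴ random simplex draws; NJ
against additive-matrix recovery; and the full pipeline against
simulator truth (perfect mining precision/recall and screen
precision/recall on clean data; ≥ 99% genotype concordance at 30×
depth with 5% stutter over > 1000 locus × accession cells). The
bundled acceptance script additionally recomputes, from the printed
survey tables shipped in `inst/extdata/`, the per-chromosome and
genome-wide SSR densities, the discovery-cascade totals (19,397 pursued
and 5,986 polymorphic loci), the dinucleotide share, and the validation
panel's amplification rate and mean He/PIC. Synthetic runs in tests and
the acceptance script use 2 chromosomes × 20–25 loci with the
21-accession, 30× panel — the smallest sizes at which every stage and
filter is exercised with non-trivial counts.

## Known limitations

* Perfect repeats only: compound and interrupted SSRs terminate runs.
* The Tm formula and feasibility-style primer search reproduce a
  *deterministic* designable/undesignable split, not a thermodynamic
  designer's output; absolute designability counts on a real genome
  will differ.
* The global stutter model has no locus-specific learning and no
  haplotype realignment; heavily stuttering dinucleotide loci will lose
  more calls to the stutter filter than a learned model would.
* Band-share frequencies understate allele-frequency information
  relative to co-dominant scoring; He/PIC values are comparable across
  loci scored the same way, not with codominantly derived values.
* BAM input requires Rsamtools; plain-text SAM is the canonical format.
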