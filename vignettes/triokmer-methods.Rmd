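---
title: "Mining de novo variant candidates from trio k-mer spectra"
author: "triokmer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining de novo variant candidates from trio k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the idea

A de novo mutation is present in a child but in neither parent's germline.
The conventional way to find one in a sequenced mother–father–child trio is
to map all three read sets to a reference, call variants in each, and
subtract — which spends almost all of its work on the overwhelming majority
of sequence the three genomes share. `triokmer` inverts the order: it first
discards everything shared at the k-mer level, and only then turns the tiny
child-specific remainder into mappable sequence.

The method runs in four stages:

1. **Counting.** Canonical k-mers (default `k = 31`) are counted per family
   member. The canonical form of a k-mer is the lexicographic minimum of
   itself and its reverse complement, so reads from either strand collapse
   onto one key.
2. **Ratio filtering.** For each child k-mer with count `f_c`, the parental
   counts `f_f` and `f_m` are looked up and the k-mer is kept when both
   ratios `f_f/f_c` and `f_m/f_c` fall strictly below `tau0 = 0.3`. A k-mer
   absent from both parents has ratio 0 — the de novo signature. Inherited
   sequence has ratios near 1 and is discarded.
3. **Error correction.** Sequencing errors create child-unique k-mers too.
   A k-mer `kappa` with count `f` is compared against its present
   Hamming-distance-1 neighbors: with `mu` and `sigma` the population mean
   and standard deviation of the counts over the neighbors plus `kappa`
   itself, `kappa` is called error-free when `z = (f - mu)/sigma > z0 = 0.8`
   and `f > f0 = 4`. An error k-mer is the low-count shadow of a true
   neighbor, so its `z` is negative; a true variant k-mer sits at or above
   its neighborhood's level.
4. **Extension.** Kept k-mers are too short to map uniquely, so each seed is
   extended left and right while exactly one of the four possible
   single-base continuations exists in the child's store, stopping at a
   branch, a dead end, or a length cap of 1000 bp. The resulting contigs
   are written as FASTA for an external aligner/caller (BWA + GATK or
   similar); the called VCF can be fed back into `refine_vcf()`.

Refinement re-applies the k-mer evidence to externally called variants: a
call passes when at least one k-mer of its alternate haplotype (the
reference flanks spliced around the alternate allele) is in the kept set,
and the summed counts of its found alt-window k-mers reach `min_sum = 3`.

A final, independent screen (`proximal_lncrna_variants()`) implements the
gene-proximity rule used for long non-coding RNA candidates: a variant
qualifies at distance `d` when it lies both within a known disease gene
extended by `d` bp up- and downstream and within an annotated lncRNA
interval; the conventional grid of distances is 100, 200, 500 and 1000 bp.

## The coupled Bloom filter

Whole-genome k-mer tables do not fit comfortably in memory, so parental and
child counts are held in a *coupled Bloom filter*: two bit planes of equal
length `m`, sized by the standard formula

    m = ceiling(-n * ln(p) / (ln 2)^2)

for `n` keys at target false-positive rate `p` (default 0.01). A k-mer `s`
with count `f` selects `h` positions via double hashing (two seeded 64-bit
string hashes `a`, `b`; position `i` is `(a + i*b) mod m`) and

* sets the `h` membership bits in the first plane (`B+`), and
* *assigns* bit `i` of `min(f, 2^h - 1)` to position `i` in the second
  plane (`B-`).

Decoding checks the membership bits (any zero means absent), then
reassembles the `h` count bits. `h` is both the number of hash functions
and the count bit width; the default `h = 8` saturates counts at 255,
which is ample for ratio tests around `tau0` at 30x coverage.

Three consequences of this design are worth stating plainly, because they
shape everything downstream:

* **Membership is one-sided exact.** Membership bits are only ever set, so
  an inserted k-mer always passes. A passing key whose assembled count bits
  read 0 must therefore be a collision artifact (every inserted count is at
  least 1), and decode reports 1 for it rather than declaring the key
  absent.
* **Counts are approximate.** Count bits are assigned, last write wins. At
  the standard sizing the count plane receives `h*n/m ≈ 0.83` writes per
  bit, so a substantial fraction of keys decode to a corrupted count; the
  corruption vanishes as `m` grows (the package's tests verify ~100%
  accurate decoding at `m = 4096n`). Filtering tolerates this because the
  decision only needs ratios near `tau0`, but the error-correction z-score
  and the single-parent guard of inherited k-mers are measurably affected;
  the test suite quantifies both on simulated trios rather than assuming
  ideal behavior.
* **False positives decode to arbitrary counts.** An absent key that passes
  membership by chance assembles unrelated bits. In the z-score stage this
  matters: of the ~3k substitution neighbors queried per k-mer, a false
  positive with a spuriously high assembled count drags the neighborhood
  mean up and can push a true variant k-mer below `z0`.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 31 | k-mer length; odd avoids palindromic self-complementary k-mers |
| `p` | 0.01 | Bloom false-positive target; drives `m` |
| `h` | 8 | hash functions = count bit width; counts saturate at `2^h - 1` |
| `tau0` | 0.3 | parent/child count-ratio threshold (strict `<`) |
| `z0` | 0.8 | z-score threshold (strict `>`) |
| `f0` | 4 | minimum count (strict `>`; a count of exactly 4 is removed) |
| `max_len` | 1000 bp | contig length cap |
| `min_sum` | 3 | minimum summed alt-window support in refinement |

Two conventions fill gaps the method statement leaves open:

* The standard deviation in the z-score is the population form
  (divide by N). When `sigma = 0` — an isolated k-mer with no present
  neighbors, or a neighborhood of identical counts — there is no evidence
  that the k-mer is an error shadow, so it is retained whenever `f > f0`.
* "Distance 1" neighbors are single substitutions: insertions and
  deletions change the length and cannot be queried in a fixed-k store.
  Neighbors are canonicalized and deduplicated; a neighbor that folds onto
  the k-mer itself is skipped.

## Extension semantics

Each phase (right, then left) repeatedly queries the four candidate
continuations of the terminal `k-1` overlap. Exactly one present candidate
extends the contig; more than one terminates the phase with a `branch`
stop; none terminates with `dead_end`; and an extension that would exceed
`max_len` stops with `max_len`. A branch stop keeps the contig built so
far. Because all queries canonicalize, extension crosses strand
representation transparently — a walk can continue through a locus whose
canonical k-mers come from the opposite strand, and two seeds from
complementary strands of one locus reconstruct the same contig. Contigs
whose sequence (or reverse complement) is contained in another emitted
contig are dropped, longest first with lexicographic tie-break, so the
output is deterministic.

## The trio simulator

`simulate_trio()` generates the conditions the method is designed for: a
single random chromosome (default 100 kb, uniform base composition), each
parent heterozygous for planted variants on the haplotype transmitted to
the child (so every inherited variant reaches the child), child-only de
novo SNVs and short indels (up to 6 bp), and uniform-coverage reads
(default 30x, 151 bp) from both haplotypes with i.i.d. substitution errors
(default 1%) and constant base qualities — the method never reads
qualities. Variant positions are spaced at least `min_spacing = 100` bp
(more than `2k` for the default `k`) apart so that per-variant k-mer
accounting is exact in the ground truth.

What it deliberately does not model: repeats and low-complexity sequence
(the main source of branch stops in real genomes), GC and coverage bias,
indel sequencing errors, PCR duplicates, quality-dependent error profiles,
and recombination. Passing tests on these simulations therefore show that
the machinery is correct under the method's own assumptions — not that the
thresholds transfer unchanged to real human data, where repeat-induced
branches shorten contigs and coverage dips weaken the ratio signal.

One structural artifact of uniform linear read sampling is worth knowing:
within roughly a read length of the sequence ends, coverage drops because
few read start positions remain, so a parent can miss an end k-mer
entirely and the child's copy then looks child-unique. The ground-truth
tests exclude these end regions explicitly.

## Numerical and degenerate-input choices

* Strict inequalities everywhere the thresholds are applied (`< tau0`,
  `> z0`, `> f0`, `>= min_sum` — the support sum is "not less than").
* `bloom_size()` demands `n >= 1` and `0 < p < 1`; empty tables cannot be
  encoded.
* Windows containing any non-ACGT character are skipped during counting;
  non-ACGT queries are rejected with an error.
* Multi-allelic VCF records are split per alternate allele; symbolic
  alleles are skipped with a warning; a reference-allele mismatch against
  the FASTA is an error, not a warning.
* Alt-window enumeration takes every window overlapping the alternate
  allele span (anchor base included), truncated at contig ends, then
  canonicalizes and deduplicates. An SNV with full flanks yields exactly
  `k` windows; a pure deletion yields the windows spanning its junction.
* Gene extension clamps at position 1 and ignores strand (the extension is
  symmetric); variant positions use the VCF anchor base.
* The problem sizes in the test suite and the acceptance script — 100 kb
  genomes at 30x for the statistical checks, 15–50 kb for mechanical
  checks — were chosen so that every stage is exercised at realistic
  per-base coverage while a full run stays in the minutes range on one
  core.

## Known limitations

* The count plane's assignment semantics make decoded counts approximate at
  the standard sizing; the package characterizes the corruption empirically
  (tests freeze measured floors) instead of hiding it. Workloads that need
  near-exact counts should lower `p` or raise `m` explicitly — accuracy
  approaches 100% once `m >> n*h`.
* The error-correction z-score inherits Bloom false-positive neighbors;
  with ~3k neighbor queries per k-mer at `p = 0.01`, roughly half of all
  true variant k-mers acquire at least one spurious neighbor, which lowers
  their retention. Candidate loss at the k-mer level is largely recovered
  at the variant level, because a variant needs only one surviving
  alt-window k-mer.
* Inherited variants are guarded by a single parent's counts; a corrupted
  parental decode can leak an inherited k-mer through the ratio filter.
  The refinement stage's variant-level exclusion is correspondingly weaker
  than its de novo recall.
* Extension is a unitig walk, not an assembler: no bubble popping, no
  paired-end scaffolding, and a single branch terminates a phase.
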