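---
title: "Calling L1-mediated 3' transductions: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling L1-mediated 3' transductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The detection model

A germline L1-mediated 3' transduction inserts, at a *target* locus, a
composite allele: target site duplication (TSD), a 5'-truncated L1, the
*transduced sequence* (TS) copied from a unique *source* locus downstream of
the donor element, and a new polyA tail. In paired-end short-read data the
L1 body is effectively unmappable, but the TS is unique sequence: read pairs
with one end anchored in the target flank and the other end inside the TS
map as inter-chromosomal ("TL") discordant pairs, while pairs reaching into
the L1 body or the polyA tail surface as single-anchored ("SA") pairs with
an unmapped or ambiguously placed (mapq 0) mate.

The caller therefore works outwards from an upstream MEI call set:

1. **Candidate regions.** Every non-reference L1 insertion interval is
   widened by `window` (default 500 bp) on both sides. A discordant pair is
   collected by a region when a confidently mapped end (mapq >=
   `min_anchor_mapq`, default 20) overlaps the search interval; the other
   end is the region's *mate*. Both MEI confidence tiers are consumed: a
   weak MEI candidate costs little because everything downstream must still
   be supported by clustering.
2. **Mate realignment.** Each mate sequence is realigned to the reference
   with a seed-and-extend local aligner (16-mer index, affine-gap
   Smith-Waterman extension; match +1, mismatch -2, a gap of length L costs
   2 + (L-1)). A placement qualifies when at least `min_realign_len`
   (default 50) query bases lie in aligned columns -- roughly half an
   Illumina read, the minimum for trustworthy placement. The best hit is the
   highest-scoring placement; **TM** counts placements scoring at least
   `near_best_fraction` (default 0.9) of the best and separates unique
   mates (TM ~ 1) from repetitive ones (high TM). The aligner contract is
   score-based, so any local aligner could back it; an exhaustive
   Smith-Waterman scanner (`sw_scan()`) is kept in the package as an
   independent reference path and the test suite asserts best-hit/TM
   equivalence between the two on fixtures up to 100 kb.
3. **Source clustering.** Qualifying mates are partitioned by chromosome and
   chained by interval overlap (single linkage, >= `min_overlap` = 1 bp, no
   gaps: book-ended intervals do not chain). A chain is a source cluster
   when it has 4-30 members (both bounds inclusive) and mean TM <= 3.0
   (inclusive). Fewer than four reads is indistinguishable from mapping
   noise at ~20x; more than thirty flags solo repetitive elements or
   collapsed duplications (`REPETITIVE_SOURCE`); a high mean TM means the
   "source" is not unique sequence. The reference substring of the chained
   interval is reported as the transduced sequence -- the longest gap-free
   stretch the reads support.
4. **Hallmarks and filters.** The polyA count is the number of region mates
   containing >= `polya_k` (default 6) consecutive non-reference A or T:
   unmapped/mapq-0 mates count on sequence content alone; mapped mates only
   where the reference lacks the homopolymer. TSDs are carried over from the
   MEI annotation rather than re-derived. Calls are flagged `SEGDUP`
   (target search interval in a segmental duplication), `REF_L1_AT_TARGET`
   (annotated L1-family repeat at the target, where reads of the reference
   element masquerade as insertion evidence), or `SHORT_TS` (reconstructed
   TS < `min_ts_length`, default 50 bp -- below the reliable minimum for
   short reads). PASS requires an empty flag set.
5. **Donor class.** Class 2 when an annotated L1-family repeat lies within
   `donor_flank` (5 kb) of the source interval, class 1 otherwise (the donor
   element segregates separately from the reference).
6. **Merging.** Across samples, calls merge when target insertion points
   (midpoint of the MEI interval) lie within `merge_distance` (100 bp,
   single-linkage) and source intervals reciprocally overlap >= 50%; merged
   events are polymorphic when absent from at least one cohort sample. The
   100 bp / 50% values are package choices -- the merge rule behind the
   published non-redundant counts is not specified -- and both are exposed.

## Statistics

Per-sample transduction rate is `100 * n_TD / n_L1` over *all* non-reference
L1 insertions (solo plus transducing). Species summaries average per-sample
rates and attach a one-sample t interval, `t(0.975, n-1) * sd / sqrt(n)` --
this is the arithmetic that reproduces the bundled cohort's printed
summaries exactly, which is why rates are averaged per sample rather than
pooled over counts. Species comparisons use a Wald z statistic on per-sample
percentage rates with a normal reference; the underlying published model is
unstated, so a binomial-GLM Wald variant is provided behind
`method = "glm"`. With n = 5 per species the normal approximation is
acknowledged as approximate; the suite checks type-I error stays within
[0.02, 0.10] at alpha = 0.05. Exact reproduction of published P-values is
deliberately not a target. Validation FDR is plain arithmetic:
`100 * (tested - confirmed) / tested`.

Subfamily enrichment builds, per subfamily, the 2x2 table (transducing vs
solo, is-subfamily vs not) and computes the two-sided Fisher exact p-value
(minimum-likelihood convention; verified in tests against a from-scratch
hypergeometric enumeration for margins <= 30) plus the sample odds ratio.

# The simulator: what it emulates, and what it does not

`sim_config()` defaults state the data regime the caller targets: 101 bp
FR pairs, 20x coverage, insert 350 +/- 50 bp, 0.1% substitution error,
heterozygous events on a 5 Mb i.i.d.-uniform background split over five
chromosomes; per event a 4-25 bp TSD, a 100-6000 bp 5'-truncated suffix of a
consensus, a 60-500 bp TS, a 10-30 bp polyA. Solo L1 insertions (identical
anatomy minus the TS) are the negatives. Reads are mapped back to the
*original* reference with `bwa mem`, so the TL/SA signatures arise naturally
rather than being scripted. The MEI input file is derived from the truth
with +/-100 bp positional jitter and a configurable fraction of false
candidate loci, emulating an imperfect upstream caller without
re-implementing one.

Deliberate simplifications, and hence what a green test does *not*
establish: the background is uniform random (real genomes have repeat
families, GC structure and low-complexity tracts that depress mappability);
errors are substitutions only; coverage is unbiased; the consensus library
is synthetic (one ancestor, derived subfamilies at 8% divergence); and
transduction sources are drawn on a different chromosome than their target.
The last choice is structural, decided up front: the TL evidence class is
inter-chromosomal by definition, and same-chromosome distant pairs are
intentionally not emitted as a discordant category (they would be recovered
only through SA realignment), so same-chromosome events would measure an
acknowledged blind spot rather than the caller's contract.

Two boundary conventions worth knowing:

* **Allele arithmetic.** The implanted allele is literally
  `TSD + L1 + TS + polyA + TSD`, so the genome grows by the full allele
  length including both TSD copies (the 908 + 126 + 20 + 2x12 = 1078 bp
  worked example in the tests). Real TPRT duplicates an existing site
  (net growth one TSD copy); the simulator follows the stated allele
  contract, and nothing downstream depends on the distinction.
* **PolyA boundary ambiguity.** If the reference bases immediately after a
  source TS happen to be A, they are indistinguishable from the event's
  polyA tail and the reconstruction may overrun the TS by a base or two.
  The fidelity test therefore checks the reconstruction against
  `TS + polyA`, not the TS alone.

## Sensitivity under the stated world

At the declared operating point the end-to-end sensitivity measured by
`scripts/acceptance.R` is ~0.86-0.92. The misses are a direct consequence of
the published thresholds, not of tuning: mates whose source-aligned portion
falls below 50 bp (reads mostly inside the polyA tail) are discarded, and
chains occasionally split where two read intervals are exactly book-ended
(zero overlap fails the >= 1 bp overlap rule), dropping support below four
reads for short TS events at heterozygous half-coverage. In the degenerate
noise-free limit -- homozygous events, zero error, exact MEI positions, TS
>= 150 bp -- recovery is complete with no false PASS calls, and the suite
asserts exactly that.

# Numerical and degenerate-input choices

* All coordinates are 0-based half-open internally; BED is consumed
  natively, RepeatMasker tables are shifted on load, SAM/VCF positions are
  converted at the boundary. Half-open overlap means `[a,b)` and `[b,c)`
  never overlap, and the suite tests the boundary on every track type.
* Best-hit ties break lexicographically by (chrom, start, strand) for
  determinism; cluster and call ordering is fully specified, so identical
  inputs yield byte-identical outputs (asserted).
* TM is counted over near-best hits after overlap deduplication (two
  placements overlapping >= 50% of the shorter count once). Counting *all*
  hits versus near-best hits is the one genuinely open aligner question;
  `near_best_fraction` exposes it.
* Mean-TM uses an inclusive boundary (a 4-read chain with TMs 1,1,2,8 --
  mean exactly 3.0 -- is kept). TM values are integers, so the tightest
  constructible super-threshold mean with four reads is 3.25; the boundary
  tests use that pair plus an explicit `max_mean_tm = 2.99` probe.
* Empty inputs (no MEI rows, no discordant pairs, a region with no mates,
  zero simulated events) flow through as empty results, not errors; the only
  hard errors are malformed files, invalid configuration and out-of-range
  interval queries.
* Strand of repeat annotation is stored but unused: every filter in the
  method is positional.

# Known limitations

* Transductions shorter than ~50 bp are invisible by construction, as are
  events inserting into or sourced from low-mappability regions --
  limitations inherent to short reads, shared with the method this package
  implements.
* 5' transductions, orphan transductions (TS without detectable L1),
  somatic calling and gene-retrocopy (GRIP) discrimination are out of scope;
  GRIPs share TSD/polyA/unique-sequence hallmarks and will be called --
  distinguishing them needs orthogonal evidence.
* The Wald comparison treats per-sample rates as approximately normal;
  with five samples per group this is serviceable for ordering species but
  not for precise tail probabilities.
* The long-read module assumes spanning reads and substitution-dominated
  error; at 10% error it recovers segment lengths to ~10%, which the suite
  checks, but real homopolymer-biased indel error will be less kind to the
  polyA boundary.
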