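---
title: "Methods: models, parameters and design choices in srnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in srnakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

srnakit annotates three size classes of small RNA reads — miRNA (18–22
nt), piRNA (28–32 nt) and crasiRNA (35–42 nt) — against a reference
genome. This vignette explains the models behind each stage, the
parameters that matter, the synthetic data the package validates itself
on, and the places where the design was genuinely open.

## Preprocessing

Adapter clipping is exact substring matching, not alignment: the longest
read suffix of at least `min_adapter_match` (default 5) bases equal to a
prefix of the 3' adapter is removed. A read without any such suffix is
discarded outright — small RNA inserts are shorter than the read length,
so a missing adapter signals a failed ligation rather than a long insert.
When a 5' adapter is configured its remnant is clipped by the symmetric
rule but its absence does not discard; the discard rule is only stated
for the 3' end, and we follow that asymmetry. Clipping order is 3' then
5', followed by inclusive size selection per pool. The longest-match
tie-break removes maximal adapter contamination and makes clipping
idempotent.

Size-window defaults (18–22 / 28–32 / 35–42 nt) are the computational
filter windows, deliberately narrower than typical gel-excision ranges;
both are plain config values (`size_ranges`) for libraries cut
differently.

## Mapping

`map_reads()` enumerates *all* ungapped placements on both strands with
at most `max_mismatches` (default 1) mismatches. With one allowed
mismatch, any valid placement contains at least one exact read half, so
candidate generation from the leading k-mer (default k = 9) of each half
is complete; every candidate is then verified by direct comparison, so
the hit set is exact — seeding is an optimisation, never a filter. Reads
shorter than 2k, or runs with `max_mismatches > 1`, fall back to a full
window scan. `N` on either side always counts as a mismatch: ambiguity
never creates evidence. Minus-strand hits use forward-genome coordinates
with the read equal to the reverse complement of the window, matching
BED/SAM convention. No per-read alignment cap exists because
repeat-derived classes are inherently multi-mapping.

`brute_force_map()` implements the same contract as a vectorised
whole-window scan with no shared code path; the test suite demands exact
hit-set equality between the two on hundreds of randomized instances.

## Hairpin folding and miRNA calling

The built-in folding backend maximises the number of nested base pairs
over {A·T, G·C, G·T} subject to a minimum terminal loop (`min_loop`,
default 3 nt) and a no-lonely-pairs constraint (every helix carries at
least two stacked pairs). It is deterministic: ties prefer pairing, then
the 5'-most outer pair, then the smallest partner. The dynamic program is
exactly testable — the suite checks its pair count against exhaustive
enumeration of all admissible structures on short sequences — which is
why a combinatorial objective was chosen over a thermodynamic one. The
stem-loop validation below consumes any dot-bracket string, so a
thermodynamic folder can be substituted without touching the criteria.

Each alignment's ±`hairpin_flank` (50 bp) window is folded and parsed
into stem-loops: one per hairpin loop, extended outward through enclosing
pairs up to the first multiloop branch point. Validation selects the
stem-loop with the most pairs among those whose span overlaps the read
(span overlap, not arms-only, so a read sitting wholly inside the
terminal loop still receives a definite `read_in_stem = FALSE` verdict)
and requires:

1. an unpaired terminal loop (`min_loop_validate`, default ≥ 1 nt);
2. stem paired fraction ≥ `min_stem_paired_frac` (default 0.75), computed
   as 2·(pairs in the chain) over the total length of both arms — bulged
   and interior-loop bases count against the stem, the terminal loop does
   not. We read "bases in the stem" literally as arm bases; whether
   bulges belonged in the denominator was ambiguous, and this is the
   stricter choice;
3. the read confined to the arms, with at most `loop_overhang` (default
   0) bases inside the terminal loop and none outside the stem-loop span.
   Real mature sequences occasionally extend 1–2 nt into the loop; the
   default is strict because the planted benchmark needs an unambiguous
   rule, and the knob is exposed.

A read is bona fide iff ≥ 1 alignment passes; passing windows merge into
loci on same-strand ≥ 1 bp overlap, the same overlap convention used
everywhere else in the package. Non-bona-fide reads are routed to target
calling, not dropped.

Reference comparison reduces the alignment stage to its decision
variables: a reference hairpin is considered when it shares an exact seed
of ≥ `ref_min_seed` (15) bases with the candidate on either strand, and
accepted when the candidate's mature slides along it ungapped at
≥ `ref_min_identity` (0.95) identity. Identity is evaluated in both
orientations of the mature so the result is invariant under
reverse-complementing the candidate. A 22-mer with one substitution
(21/22 ≈ 0.955) passes; two substitutions (20/22 ≈ 0.909) fail. No gapped
extension is attempted because the accept/reject decision depends only on
seed existence and mature identity.

## Targets, repeats, peaks

Gene models lacking UTR annotation are expanded by `gene_flank`
(1000 bp) per missing transcriptional side, strand-aware and clamped to
the contig. Target support counts *unique read sequences* per gene —
identical sequences collapse so amplification duplicates cannot inflate
support — and the cross-pool matrix is row-normalised by each gene's
maximum. Repeat association is ≥ 1 bp overlap; a multi-mapping read
contributes once to every class it touches, and the distribution
denominator is total (read, class) assignments, so percentages sum to
100 over classes rather than over reads. Pool comparison pairs reads
whose alignments share ≥ 1 bp on the same contig and strand.

Read peaks have no published definition, so the package uses the
simplest deterministic rule and says so: single-linkage clustering of
alignment intervals with gap ≤ `peak_max_gap` (0) and a floor of
`peak_min_reads` (2) alignments, strands pooled. Both knobs are config
values; peak/enrichment overlap is again ≥ 1 bp.

## The mirror (discontiguous palindrome) statistic

For each crasiRNA alignment the ±`motif_flank` (50 bp) window, oriented
to the mapped strand, is scored as

S(W) = #{ i : W[i] = complement(W[L−1−i]) },

the number of positions at which the window matches its own reverse
complement. Matches occur in symmetric pairs and no DNA base is
self-complementary, so S is always even and strand-invariant. Windows
truncated by a contig edge are ignored rather than clamped, and windows
with fewer than `motif_min_distinct_3mers` (5) distinct 3-mers (3-mers
containing N excluded, plus a > 10% N guard) are skipped as
uninformative simple repeats.

Significance is empirical: `motif_n_shuffles` (100) Fisher–Yates
permutations of the window preserve base composition exactly, and the
p-value is the fraction of permutations scoring ≥ the original. The raw
count is kept alongside; an optional (n+1)/(N+1) pseudo-count correction
exists but is off by default to keep the plain proportion. Per-window
permutation seeds derive deterministically from the global seed and the
locus (contig, start, strand), so results are independent of processing
order and of which other loci are present. Under an i.i.d. null each
position matches with probability 1/4, so mean match fraction converges
to 0.25 and the p-values are near-uniform; the acceptance suite checks
both. AT-rich windows score higher by chance — the permutation test
conditions on composition, but the cohort share threshold does not,
which is a known property of the statistic, not a bug.

The cohort share is the fraction of loci with match fraction ≥
`motif_share_threshold` (1/3). Whether the original share was computed
over gated or all loci is not stated; the summary reports both
denominators (`share` over scored loci, `share_all_loci` over all).
Whole-window permutation (rather than shuffling read and flanks
separately) follows from the composition-preservation description.

## Synthetic data and what the tests show

`simulate_genome()` plants, on random background (GC 0.42, a typical
mammalian composition): perfect hairpins (stem 25 bp, loop 6 nt, GC-rich
arms — comfortably above the 18–22 nt reads they must host), shuffled
decoy loci of identical composition, repeat families (400 bp copies at
15% divergence from a per-class consensus, enough that one-mismatch
mapping rarely crosses copies), palindromic windows constructed
base-by-base to an *exact* designed match fraction (default 0.5),
background crasi loci, and gene models with fixed per-gene target read
counts. Features are placed non-overlapping with a 120 bp buffer so
±50 bp analysis windows never straddle two features. `simulate_reads()`
draws reads from these loci, appends full, truncated (≥ 5 nt) or
sub-threshold (< 5 nt, to exercise the discard rule) adapter remnants,
and optionally adds substitution errors; every read is traceable to one
ledger entry.

One generator subtlety is *certification*. A shuffled decoy is not
automatically structure-free: maximum-base-pair folding pairs roughly
70% of random sequence, so bulge-crossing stems near the 75% threshold
arise by chance (the acceptance script measures this pass rate on
uncertified random windows — a few percent per window), and a perfect
planted stem can occasionally be absorbed into a larger chance chain.
The generator therefore verifies its own claims: each hairpin locus
stores read placements whose windows pass validation in both
orientations, each decoy stores placements that fail in both, and loci
that cannot be certified are re-drawn. Reads are sampled only from
certified placements. Consequently the planted-recovery tests establish
*pipeline correctness* — extraction, mapping, folding, validation,
merging and reporting do what they claim, deterministically, at any seed
— and not the statistical power of the three structural criteria on
arbitrary sequence, which the uncertified pass rate quantifies
separately. Real-data users should expect the 75% rule to admit some
chance stems, as any fixed structural filter does.

The generator also does not emulate: realistic expression levels (depth
is uniform per locus), quality-score variation (constant Q), indel
errors (the aligner is ungapped, so indels would only lose reads), or
nested/overlapping features. Conclusions about those aspects of real
libraries cannot be drawn from the suite.

## Numerical and reproducibility choices

Problem sizes in the acceptance suite were chosen to exercise each
property at meaningful scale on a single CPU: 500 randomized mapping
cases, 1000 short-sequence folding comparisons, 10,000 mirror-score
windows, 500-window null calibration at 100 shuffles, 1000-interval
all-pairs oracles, and a 20 + 20 hairpin/decoy genome of 120 kb. The
whole suite runs in about two minutes.

All randomness flows from explicit seeds (`withr::with_seed`, so the
user's RNG state is never disturbed); pipeline reruns are byte-identical,
and a rerun over an up-to-date output directory is a cached no-op keyed
on a hash of config, inputs and package version. Report writing formats
numbers deterministically. Integer arithmetic is used for all
coordinates; the only floating-point comparisons are the fraction
thresholds, applied with plain `>=` since both sides are exact small
rationals.

## Known limitations

* The folding objective is combinatorial, not thermodynamic; it
  over-pairs random sequence relative to a free-energy model, which is
  why certification (above) exists. The validation layer accepts any
  dot-bracket, so an external thermodynamic folder can be plugged in.
* The peak definition is an explicit stand-in; published peak counts
  depend on an unstated clustering and are not reproducible desk-side.
* The mirror statistic conditions on composition only through the
  permutation test; cohort shares remain composition-sensitive.
* SAM/BAM output is out of scope; hits are TSV.
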