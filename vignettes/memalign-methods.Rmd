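---
title: "Anchor-based vertical-division alignment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based vertical-division alignment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`memalign` aligns sets of long, similar nucleotide sequences by vertical
division: exact matches shared across the set become anchors, the sequences
are cut at the anchors, the short pieces are aligned independently, and the
pieces are reassembled. This vignette explains the underlying models, the
parameters that matter, and the design decisions taken where more than one
reasonable construction exists.

## The anchoring model

### Text model and alphabet

Input sequences are uppercased and every character outside `{A,C,G,T}` is
replaced by the gap character `-`. The preprocessed sequences are
concatenated into a single integer text with one sentinel after each
sequence. Two representation choices matter downstream:

* **Sentinels are pairwise distinct and sort below every sequence symbol.**
  No suffix comparison can cross a sequence boundary, so the suffix array of
  the concatenation behaves exactly like a generalized suffix array of the
  set.
* **Each masked position also carries its own distinct symbol**, ranked
  between the sentinels and `A`. A masked base therefore matches nothing —
  not even another masked base — which simultaneously (i) keeps `-` out of
  every exact match, (ii) stops left/right extension at masked bases, and
  (iii) makes the suffix-array enumeration agree exactly with the
  brute-force definition of maximal exact matches in which boundaries and
  unknowns count as universal mismatches. A single shared `-` symbol would
  hide matches whose occurrences are all followed (or preceded) by masked
  bases.

A consequence of masking-to-gap is that masked positions are
indistinguishable from alignment gaps in the output: the final alignment
degaps to the input with its masked characters removed. Pipelines that need
to preserve `N` runs positionally should restore them from the input
coordinates afterwards.

### MEMs as LCP-interval tree nodes

A maximal exact match (MEM) is a substring together with *all* of its
occurrence positions (two or more, possibly several in one sequence) such
that the characters immediately right of the occurrences are not all equal
and likewise on the left, with a boundary or masked base counting as "never
equal". This group definition is precisely what the suffix-array machinery
computes: every right-maximal repeated substring corresponds to one node of
the LCP-interval tree, so `find_lcp_intervals()` enumerates **all tree
nodes** with lcp value at least `l_min` by a stack traversal of the LCP
array — including nodes nested inside runs whose interior lcp values exceed
the threshold. Enumerating only the outermost threshold runs would miss
longer matches shared by fewer suffixes (for example the repeat `abcab`
inside an `ab` run), and with it part of the anchor supply.

Left extension is specified as extending each interval's occurrence group
leftwards while all left characters agree. The implementation exploits an
identity instead of looping: the left extension of a group is itself a tree
node (same occurrences, longer string, still right-maximal), so it is
sufficient to *keep exactly the left-maximal nodes* and discard the rest as
duplicates. The result is identical to literal extension plus
deduplication, but avoids quadratic work on near-identical inputs, where
non-left-maximal nodes abound.

Suffix array construction uses prefix doubling (`O(N log^2 N)`) in C++;
correctness, not asymptotic optimality, is the contract, and desk-scale
texts (tens of megabases and below) are far from the regime where a linear
construction would be felt.

### Coverage, size, and colinear selection

MEMs must cover more than `floor(c * n)` of the `n` sequences (coverage
threshold `c`, default 0.7) and are ranked by *size* — match length times
the number of covered sequences — because large MEMs contribute most to the
eventual alignment. Selection seeks the pairwise-colinear subset of maximum
total size, where two MEMs are colinear when their occurrences are disjoint
and identically ordered in every sequence containing both.

Colinearity is *not* transitive when anchors cover different subsets of
sequences, so a longest-increasing-subsequence recurrence over a single
reference ordering is not exact. Selection therefore runs a
branch-and-bound search: candidates are visited in the order of their
position in the sequence covered by most of them (mean start elsewhere),
but each candidate may be inserted at any chain position consistent with
the before-relation, with suffix-weight pruning. Up to 25 candidates the
search is exhaustive; beyond that a deterministic two-pass greedy
(key-order append, then size-descending feasible insertion, keeping the
heavier chain) is used — for high-coverage anchor sets the before-relation
is nearly a total order and greedy chains are optimal or near-optimal in
practice. MEMs with several occurrences in one sequence are first reduced
to the occurrence closest to the MEM's median relative position across
single-occurrence sequences (leftmost as fallback): enumerating occurrence
combinations is exponential, and the median rule is deterministic and
testable.

*Global* mode keeps or drops whole MEMs. *Local* mode starts from the
global optimum and re-admits rejected MEMs by trimming their left edge
uniformly across occurrences (and dropping irreconcilable occurrences); a
trimmed MEM survives only if its remainder is at least `l_min` long and
still above coverage. Local mode therefore never has a smaller chain than
global mode, which is the behaviour wanted for low-similarity or
overlap-rich inputs.

### Partial chains via local alignment

For each selected anchor and each sequence it misses, the anchor string is
aligned (affine-gap Smith–Waterman: match 2, mismatch −3, gap open 5, gap
extend 2; a gap of length *g* costs `5 + 2g`) against the window of that
sequence between its occurrences of the flanking anchors. The best local
hit is accepted if its gap-column fraction is at most 0.8 (the
`gap_frac_max` parameter); by construction the hit lies inside the window,
so colinearity is preserved. The scoring scheme is the package's own choice
of a standard nucleotide scheme; any exact Smith–Waterman is
contract-equivalent, and the test suite cross-checks scores against
`Biostrings::pairwiseAlignment` as an independent implementation.

## Segmentation and assembly

Anchors cut each sequence into anchor occurrences, *segments* (pieces
between two consecutive chain anchors that both cover the sequence; at
least two member sequences), and *fragments* (everything else — pieces
spanning skipped anchors, late-covered heads/tails, wholly uncovered
sequences). Single-member inter-anchor pieces are reclassified as fragments
because aligning a singleton is vacuous. Zero-length pieces are kept so
that, per sequence, blocks plus fragments tile `[1, len]` exactly — the
invariant that guarantees the final alignment degaps to its input.

Segments are aligned independently (and in parallel when `threads > 1`;
results are merged strictly in plan order, so output never depends on
scheduling). The internal backend is a progressive aligner — shared *k*-mer
distances, UPGMA guide tree, banded profile–profile merges — so the
pipeline runs with no external binaries; MAFFT or any command-line aligner
can be substituted per segment (`backend = "mafft"` or
`"external:<template>"`), with outputs validated by the degap round-trip
and an automatic fallback to the internal aligner. Segments whose mean
member length exceeds `size_cap` (default 50 kb) are re-divided by the
anchor pipeline itself with `l_min` halved (floor 4); this recursion is
capped at two levels, after which the backend is called directly.

Anchor blocks that contain approximate occurrences are realigned with the
internal aligner before assembly, since their members are similar but not
identical.

### Banded sequence–profile alignment

Fragments are attached shortest-total-pending-length-first (ties by input
order), each by global alignment against the profile of the already-aligned
columns between its flanking anchors; existing rows only ever gain shared
gap columns, so their mutual alignment is untouched. The profile DP scores
a column pair through residue frequencies
(`match * dot + mismatch * (nz1*nz2 − dot)`), and scales gap penalties by
the consumed column's non-gap mass, so skipping a mostly-gap column is
nearly free. The DP runs in a diagonal band: the band half-width starts at
`band_k` (default 16) and doubles while the optimal path touches the band
edge; for profiles wider than 1 kb the band diagonal is first proposed by
FFT cross-correlation of the residue indicator channels. With a band at
least as wide as both inputs the banded result provably equals the
unbanded optimum, which the acceptance suite checks against a full-matrix
oracle. Deterministic tie-breaks (diagonal over gap moves) fix the
alignment shape.

### Concatenation and junction refinement

Blocks are concatenated in plan order. Refinement then alternates two
steps to a fixed point: all-gap columns are deleted, and within a window of
10 columns on each side of every block junction, a residue flanking a gap
run may slide across the run — provided source and destination straddle the
junction — whenever that strictly lowers the window's sum-of-pairs cost
(match 0 / mismatch 1 / gap 2, gap–gap 0). Because each slide strictly
lowers the whole-alignment SP cost (only two columns change) the procedure
terminates, never worsens SP, and is idempotent; all three properties are
asserted in the test suite. The window-local slide set is the package's own
realization of junction refinement: it is deterministic and
score-monotone, which is what the assembly stage needs from it.

## Scoring

`sp_score()` implements the sum-of-pairs cost with match 0, mismatch 1,
residue-versus-gap 2, and gap–gap 0; the average divides the total by the
number of sequences `n` (not by the number of pairs) — an unusual but
deliberate convention, kept exactly as stated so reported values are
comparable. Terminal gaps receive no special treatment. `q_tc_score()`
computes the Q score (reference residue pairs recovered / reference
residue pairs) and TC score (reference columns whose residues all share one
test column / reference columns) after verifying that both alignments hold
the same sequences.

## The family simulator

`simulate_family()` emulates a family of homologous sequences at a
controlled pairwise similarity: a uniform-random ancestor, and each child
derived independently from it (star tree). Substitutions are i.i.d. per
site with probability `p` solved from the target similarity `s` through
`(1−p)^2 + p^2/3 = s` (two independently mutated copies match at a site
with exactly probability `s`), so realized identity — measured over
true-alignment columns where both rows have residues — is centered on the
target; the suite verifies ±3 percentage points at 5 kb. Indel events occur
at `indel_rate` per site (default 0.005) with geometric lengths of mean
`mean_indel_len` (default 2), split evenly between insertions and
deletions; these defaults are in the range typical of within-species
organellar and viral comparisons, chosen once and not revisited. Insertions
from different children are never homologous and occupy separate columns of
the tracked true alignment.

The simulator deliberately omits rate heterogeneity, hierarchical tree
structure, codon structure, and large rearrangements. Tests passing on
simulated families therefore demonstrate the pipeline's correctness
invariants (exact degap round-trip, no all-gap columns, accuracy parity
with direct alignment) and its qualitative segmentation behaviour — not
performance on recombinant, rearranged, or deeply divergent real data.

## Parameter summary

| parameter | default | meaning |
|---|---|---|
| `l_min` | 30 bp | minimum MEM length; 39 gives parity with k-mer-seeded vertical dividers |
| `coverage` (`c`) | 0.7 | MEM must cover more than `floor(c·n)` sequences |
| `mode` | global | whole-MEM selection vs. trim-to-fit |
| `gap_frac_max` | 0.8 | max gap-column fraction for approximate occurrences |
| `band_k` | 16 columns | initial band half-width (doubles on edge contact) |
| `size_cap` | 50 kb | mean segment length triggering recursive division |
| `refine_window` | 10 columns | junction refinement window half-width |

`l_min` trades anchor specificity against supply: too small floods the
chain builder with repeats, too large finds no anchors below ~90%
similarity. `c` trades segment count against fragment count: lower `c`
admits more, narrower anchors and more fragments.

## Degenerate inputs and numerical notes

Fewer than two non-empty sequences, or a chain with no usable anchors,
degrade to a single direct backend alignment of the whole set (the
degenerate one-segment plan). Empty fragment windows are skipped; empty
segment members become all-gap rows. All DP scores are small floating-point
sums of integer-valued terms; comparisons use exact `>` with a `1e-12`
guard only at the Smith–Waterman optimum-cell tie-break (smallest target
end, then smallest query end). Selection ties are broken by size, then
length, then leftmost occurrence. The test-suite oracle comparisons for the
suffix array, MEM sets, and colinear optimum are exact; banded-versus-full
DP agreement is asserted to `1e-9`.

Test and acceptance problem sizes are the package's chosen study
conditions: suffix-array oracles on 200 random sets up to 2 kb total; MEM
oracles on 100 sets up to 5×200 bp for every `l_min` in 2–20; 50 simulated
families up to 20 × 10 kb at 85–99% similarity for the round-trip
invariant; 20 families of 8 × 3 kb at 95% for accuracy parity (SP within
10% and Q within 10% of the direct aligner); and a similarity ladder
0.70–0.99 for the segmentation trend.

## Known limitations

* Chain selection above 25 candidates is greedy (deterministic, and
  provably never below the key-order chain), so pathological anchor
  configurations may yield a sub-maximal chain; in the high-coverage regime
  used by the pipeline this has not been observed to matter.
* A single extremely long segment (e.g. when similarity collapses in one
  region) falls through to the backend aligner after two recursion levels
  and dominates runtime — the known failure mode of vertical division.
* Masked (`N`) positions are not preserved positionally (see above).
* The banded profile DP is heuristic when the band does not saturate;
  the doubling schedule stops at the first band whose optimum leaves the
  band edge untouched, which can in principle under-shoot on adversarial
  profiles.
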