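---
title: "Classifying plant non-specific lipid transfer proteins by their eight-cysteine scaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant non-specific lipid transfer proteins by their eight-cysteine scaffold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsltp)
```

## The scaffold and the classification problem

Plant non-specific lipid transfer proteins (nsLTPs) are small (~7–10
kDa), usually basic proteins with an internal hydrophobic cavity that
binds and shuttles lipids.  Their sequences are highly diverse, but all
family members share eight cysteines at conserved relative positions,
forming four disulfide bonds.  Written as blocks, the scaffold is

```
C - Xn - C - Xn - CC - Xn - CXC - Xn - C - Xn - C
```

with five variable-length spacers.  Molecular weight alone (the
classical nsLTP1/nsLTP2 split) fails to place many family members, so
this package classifies on the spacer lengths themselves: each of the
five types I–V admits a characteristic set of residue counts in each
gap (`spacing_rules()` holds the full table).  Two further signals
complement the spacing:

* the polarity of the single residue inside the CXC block
  (hydrophilic in nsLTP1-like Type I, hydrophobic in Types II–V), and
* conserved non-cysteine residues captured by Prosite-styled patterns
  for Types I and II (`builtin_patterns()`).

## Motif detection

`find_cys_motifs()` enumerates *every* increasing 8-tuple of cysteine
positions satisfying the block constraints (Cys3/Cys4 adjacent,
Cys5/Cys6 separated by exactly one residue, at least one residue in
every variable gap), sorted by start position then span.  Enumeration
rather than first-match keeps the mechanism separate from policy: the
classifier, not the motif finder, decides which candidate to report
when several exist.  A `max_candidates` guard (default 10,000) turns
pathological cysteine-dense inputs into an explicit error instead of a
combinatorial stall.

Coordinates are 1-based throughout, the native convention both of R
and of protein sequence annotation (residue 1 is the first residue);
reports print the same numbers users would cite (e.g. "Leu8").

Sequences lacking the full motif are screened against four
cysteine-deficient scaffold categories (A–D) that drop one or two of
the eight cysteines.  Categories C and D share the block skeleton
`C, CC, CXC, C` and are distinguished only by their admissible gap
sets; since their first-gap sets are disjoint, a single placement never
satisfies both, but a sequence containing alternative placements can
legitimately report both categories, and `find_deficient_motifs()`
does so rather than inventing a tie-break.

## The spacing classifier

`classify_spacing()` tests an observed gap vector against each type's
admissible sets and returns the full compatible set plus a resolved
call (`I`..`V`, `ambiguous`, `unclassified`) and a per-slot evidence
table.  Two reading conventions for the rule table matter:

* comma lists are unions of exact values and dashes are inclusive
  integer ranges (`7,13-15` means {7, 13, 14, 15}) — the only
  self-consistent reading of the published table;
* the Type III g4 entry contains an isolated value 2 next to the range
  21–24.  It is transcribed literally by default; because it is most
  plausibly a typographic artifact, `spacing_rules(iii_g4_drop_stray =
  TRUE)` removes it.

**Core vs strict mode.**  The default (`core`) tests only the five
inter-cysteine gaps.  The N-terminal offset and C-terminal tail lengths
depend on where the signal peptide was cleaved, and this package
accepts mature or precursor sequences as given rather than predicting
cleavage; terminal-length gating is therefore opt-in (`strict`).

**Ambiguity.**  The Type III and Type V rule sets overlap (e.g. gaps
10, 17, 9, 22, 7 satisfy both).  No tie-break is implied by the
spacing system itself, so ambiguity is always reported; users who need
a decision can impose a priority order with `prefer`.  Types I and II
can never be jointly compatible — their g1 sets ({8–10} vs {7}) are
disjoint — and the test suite asserts this both on the tables and on
random vectors.

## The Prosite pattern engine

Patterns are parsed from standard Prosite syntax (literals, `[..]`
classes, `{..}` negated classes, `x` wildcards with `(n)`/`(n,m)`
repeats, `<`/`>` anchors).  Matching is **exhaustive enumeration** of
all spans, not regular-expression search: every wildcard width in the
repeat range is explored, so greedy/lazy semantics are irrelevant by
construction.  The unknown residue `X` matches nothing except
wildcards — a conservative choice that prevents `X`-padded sequences
from satisfying conserved positions.  Negated classes are supported
for user patterns even though the built-ins never use them.

The built-in Type I and Type II patterns transcribe the published
motifs, reading the printed `×` glyph as the single-position wildcard
and `X_5-7_` as `x(5,7)`.  One known tension is deliberately left in
place: the Type I pattern implies a fixed 19-residue Cys4–Cys5 gap
while the spacing table allows {18–20, 29}.  The pattern-vs-spacing
consistency check therefore asserts only that pattern-implied gap
ranges lie **within the interval hulls** of the corresponding rule
sets, and does not force the two sources to agree exactly.

The engine's correctness is established against an independent oracle:
each random pattern is mechanically translated into an equivalent
regular expression and evaluated by R's PCRE engine over every
substring; the two routes must agree exactly (they do, on thousands of
random pattern/sequence pairs).

## Pattern induction

`induce_pattern()` derives a Prosite-styled pattern from an alignment
by per-column amino-acid occurrence.  Per column, with frequencies
computed over non-gap residues:

1. all-cysteine columns become literal `C` when `anchor_cys = TRUE`
   (pinning the scaffold);
2. columns below `min_occupancy` (default 0.50) become wildcards;
3. a top-residue frequency at or above `literal_threshold` (default
   0.90) yields a literal;
4. otherwise the smallest frequency-descending residue set reaching
   `class_cum_threshold` (default 0.90) yields a class if it has at
   most `class_max_size` (default 4) members; else the column is a
   wildcard.

Maximal wildcard runs collapse to `x(m,M)` where `m`/`M` are the
minimum/maximum per-member non-gap residue counts over the run, so
every training member's de-gapped run length is representable.  The
sequence collections the built-in patterns were originally derived
from are not reproducible at desk scale, and no numeric conservation
thresholds accompany them; the defaults here are chosen so that
positions conserved at roughly 86% or more — the level typical of the
functionally important positions in this family — become literals or
small classes, and all four knobs are exposed.

One caveat follows directly from the rules: when a literal or class
column is not fully occupied (occupancy between `min_occupancy` and 1),
members gapped at that column will not match the induced pattern.  On
generator-produced alignments gaps occur only inside wildcard runs, so
training-set acceptance is exact there — which is what the tests
assert; on arbitrary real alignments, acceptance of every member is
guaranteed only with `min_occupancy = 1`.

## Physicochemical profiling

Molecular weight is the sum of average residue masses plus one water
(monoisotopic mode available); the mass table is the standard one used
by common proteomics servers and is injectable.  Net charge at a given
pH is the Henderson–Hasselbalch sum over the N-terminus, H, K, R
(positive) and the C-terminus, D, E, C, Y (negative), with a
Bjellqvist-style default pKa set (N-terminus 7.5, C-terminus 3.55,
D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0); any entry can
be overridden or disabled.  The isoelectric point is found by bisection
on [0, 14] to |charge| < 1e-4 (each Henderson–Hasselbalch term is
monotone in pH, so the bracketed root is unique); a sequence with no
titratable groups of one sign returns the boundary with a flag.
Weights and pI are computed on the residues as given — whether those
are mature or precursor sequences is the caller's decision, consistent
with the package not predicting signal peptides.

The CXC polarity partition is a declared convention: hydrophilic
{S, T, N, Q, D, E, K, R, H}, hydrophobic {A, V, L, I, M, F, W, Y}, and
G, P, C, X as "other" — the family literature only anchors N as
hydrophilic and L, F as hydrophobic, and glycine/proline/cysteine are
left unassigned to avoid overclaiming.

## Distances and trees

Pairwise identity comes from global (end-to-end) Needleman–Wunsch
alignment with affine gaps (Gotoh), BLOSUM62 scores, gap open 10 and
extend 0.5 (a gap of length L costs open + (L−1)·extend), with a
deterministic traceback preferring diagonal, then up, then left.
Identity is identical aligned pairs over all aligned columns (a
shorter-sequence denominator is available).  Distances are
1 − identity.  These global identities are *not* numerically equivalent
to local/BLAST identities, so the >15% candidate filter is exposed as
a utility (`identity_filter()`) rather than claimed equivalent to a
database screen.

UPGMA (size-weighted average linkage, heights at half the merge
distance — hence ultrametric output) and neighbor joining (standard
Q-criterion, trifurcating root, negative branch lengths clamped to zero
with a message) are implemented directly so the pipeline is
self-contained.  All ties break on the lexicographically smallest pair
of cluster labels (a cluster is labelled by its smallest leaf), and
children are ordered by the same key, so both builders are
deterministic and invariant to input order without any seed.  Newick
output uses six decimal places and quotes labels containing unusual
characters; `as_phylo()` bridges to the `ape` ecosystem.

## What the simulator emulates — and what it does not

The generator exists so that every stage is verifiable without any
sequence database:

* `sample_type_sequences()` draws each spacing slot uniformly from the
  chosen type's rule sets and fills spacers from a cysteine-free
  alphabet, giving exactly eight cysteines per sequence; the CXC X
  residue is drawn hydrophilic for Type I and hydrophobic for Types
  II–V, matching the observed polarity trend.
* `sample_from_pattern()` realizes a pattern element by element
  (uniform within classes and wildcard ranges) and records the element
  spans, which the decoy generator reuses.
* `make_decoys()` plants exactly one violation per sequence: a motif
  cysteine replaced by alanine (`drop_cys`), one gap pushed outside its
  source set (`shift_gap`), or conserved non-cysteine residues permuted
  until the pattern no longer matches (`shuffle_conserved`).
* `synthetic_alignment()` aligns fixed-length element columns directly
  and right-pads variable wildcard runs with gaps, optionally
  corrupting conserved columns at rate 1 − conservation.

Simulated sequences share only the *constraints* of real nsLTPs.  They
do not reproduce real amino-acid composition, correlated residue usage,
signal peptides, or the insertion/deletion structure of natural
alignments.  Passing tests therefore demonstrate that the machinery is
correct under the declared model — pattern semantics, spacing
membership, tree reconstruction — not that real-world recovery rates
would be 100%.

## Numerical and design choices

* Redundancy removal (`dedupe_identical()`) uses exact residue-string
  equality ("100% identity"), keeps first occurrences, and is
  idempotent.
* The FASTA writer wraps at 60 columns, declared so round-trips are
  bit-exact.
* Floating-point ties in the tree builders are detected with small
  absolute tolerances (1e-12 UPGMA, 1e-9 NJ Q-values) before the
  lexicographic tie-break.
* Problem sizes in the test suite and acceptance script (1,000 random
  pattern/sequence pairs, 500 realizations per built-in pattern, 1,000
  simulated sequences per type, 50-member induction alignments, 60
  sequences through the full pipeline) were chosen to exercise each
  property at a scale where failures of the kinds the decoys plant
  would be detected with overwhelming probability while keeping a
  complete run in the minutes range on one core.

## Known limitations

* The classifier is only as sharp as the spacing table: the Type III/V
  overlap is real and reported as ambiguity.
* Deficient-category assignment inherits the published table's partial
  overlaps; categories are reported per placement, not adjudicated.
* No HMM or PSSM scoring: patterns are hard constraints, so a single
  non-conforming residue at a conserved position removes a match (the
  decoy tests rely on exactly this property).
* Global-alignment identity differs from database-search identity;
  trees built from small simulated sets validate the algorithms, not
  the evolutionary history of the family.
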