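---
title: "Decomposing immunoglobulin V(D)J junctions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing immunoglobulin V(D)J junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igjunction)
```

## The problem

A recombined immunoglobulin cDNA is a mosaic: a germline V segment whose
3' end may have lost bases to exonuclease activity, then a coding joint,
then (for heavy chains) a D segment trimmed at both ends, a second joint,
and a 5'-trimmed J segment. Each joint can contain palindromic (P)
nucleotides — created when the coding-end hairpin is opened off-center,
hence complementary to the adjacent *untrimmed* germline end — and
nontemplated (N) nucleotides added by TdT. In ruminants, whose germline
gene repertoire is small, this junctional diversity (together with
somatic hypermutation) carries much of the burden of generating a useful
preimmune repertoire, and fetal bovine repertoires show both unusually
long N insertions (up to 36 nt) and unusually aggressive trimming of the
D segments.

`igjunction` turns a cDNA read plus a germline reference set into an
exact decomposition: which V, D, J were used; how many bases each gene
end lost; and the P/N/P content of each junction. Everything downstream —
usage tables, junction statistics, spectratypes, consensus deduction of
uncatalogued D segments — is arithmetic on that decomposition.

## Segment assignment

Assignment is by optimal Smith–Waterman local alignment
(`Biostrings::pairwiseAlignment`, the same engine the analyses this
package systematizes were built on), with match +1, mismatch −1 and an
affine gap scheme in which a gap of length $L$ costs
$4 + L \cdot e$ (as a penalty): $e = 5$ against V and J references and
$e = 0.3$ against D references. The marginal D extension penalty is
deliberate: bovine D segments share short repetitive motifs (TAT/GGT
codon runs), and a nearly free gap extension lets the D alignment span
them so that only genuinely nontemplated or palindromic bases remain in
the junctions. A single-base gap therefore costs 9 against V/J and 4.3
against D.

The stages, per read:

1. Best V and best J over all germline candidates of the chain
   (ties broken by score, then aligned length, then gene id — the data
   admit exact ties, so determinism has to be imposed).
2. If the V and J spans overlap on the read, each boundary moves to the
   midpoint of the overlap (the upstream segment keeps the extra base of
   an odd-length overlap) and the trimming counts are recomputed from the
   truncated alignments. We recompute rather than report pre-resolution
   counts: the resolved boundary is the only self-consistent reading of
   the read, and conservation (spans + junctions tile the read exactly)
   would otherwise fail.
3. The read subsequence strictly *between* the V and J boundaries is
   aligned against every D gene. A D hit needs a score of at least 5 —
   five consecutive matches' worth of evidence — otherwise the read is
   annotated with no D and the whole insert reported as one junction.
   With fewer than ~5 matching bases a D call would be indistinguishable
   from chance against a database of segments sharing short motifs.
4. Exonuclease counts are the germline bases absent from each aligned
   end; trimming is inferred, not observed, so "absent from the best
   alignment" is the operative definition throughout.
5. Junction decomposition (below), CDR3 delimitation from reference
   anchors, and QC flags.

Reads with a weak best V score (default < 20) are retried once as
reverse complements and the better orientation kept; a local aligner
almost always finds *some* positive-scoring match, so "no V hit" must be
read as "no convincing V hit".

Light chains run the identical engine with no D stage. (The original
light-chain analyses used a BLAST heuristic for pairwise alignment; using
one engine for both chains trades bug-for-bug fidelity for a single
tested code path, and is the only place this package knowingly deviates
from the workflow it systematizes.)

## Junction decomposition

P nucleotides can only exist where the donor end was not trimmed. For an
untrimmed upstream end the reverse complement of the donor 3' terminus is
compared base by base with the junction, moving outward from the
boundary; the run of matches is `p_left`. Symmetrically for `p_right`
against the downstream 5' terminus. Whatever remains is N. If both P
claims would overlap, the left (upstream) claim is satisfied first —
junctions are read 5'→3', and some deterministic priority is needed for
the rare double-claim. The decomposition always concatenates back to the
junction string (a hard invariant, tested on every simulated and
annotated read).

```{r}
decompose_junction("GTACCT", upstream_end_seq = "TACTAC", upstream_exo = 0,
                   downstream_start_seq = "GATC", downstream_exo = 2)
```

A read is flagged `high_exo` when more than 29 nt are inferred excised
from either end of its D segment: with that much of the segment gone, the
D assignment itself rests on little sequence and downstream tallies
should treat it with caution. The threshold is strict (`> 29`), exposed
as a parameter, and the flag never fires for light chains or D-less
reads.

## Repertoire summaries

* `usage_table()` cross-tabulates (V, D, J) for QC-passing reads; all
  percentages are exact rationals, rounded half-away-from-zero only at
  presentation (matching how such tables are conventionally reported as
  integers).
* `junction_stats()` reports, per junction type, the median and range of
  N and P lengths, the fraction of junctions with any N, the fraction
  with long N runs, and median trimming per gene end. "Long N" counts
  runs of length ≥ 10 by default — published ranges for "long" additions
  start at 10, so the inclusive reading is internally consistent — with a
  strict `> 10` available via `long_n_inclusive = FALSE`.
* `base_composition()` pools only the N strings (P and germline bases are
  excluded by construction).
* `spectratype_density()` computes a Gaussian-kernel density of CDR3
  lengths on a uniform grid spanning `[min − 3h, max + 3h]` with
  Silverman's rule bandwidth by default. The window clips ~0.3% of the
  kernel tail mass, so the density is renormalized to integrate to 1 by
  the trapezoid rule. Capillary-electrophoresis fragment sizes include
  constant primer flanks; the `offset` parameter (default 0) maps
  nucleotide lengths onto that scale when needed.

## Fuzzy RSS scanning

D segments are flanked by recombination signal sequences; paired RSS
motifs with a wide central gap locate candidate D genes in genomic
sequence. `parse_pattern()` accepts PROSITE-style patterns — literals,
`[XY]` classes, `N` wildcards, `N(a)` fixed runs, `N(a,b)` variable gaps
— and `scan_fuzzy()` reports every placement whose mismatch total over
*fixed* positions stays within a global budget (the semantics of the
classic `fuzznuc` tool: variable gaps carry no expected base, so they
cannot mismatch). Subject `N` bases satisfy nothing, a conservative
choice for candidate calling. The candidate segment is the central
variable region between the heptamers; `extract_d_candidates()` pulls it
out, reverse-complementing minus-strand matches.

The scanner's matching core is deliberately simple (per-block mismatch
vectors plus a depth-first search over gap placements with budget
pruning) and is property-tested against a full brute-force enumeration of
every start position × gap combination.

## Consensus deduction of uncatalogued D segments

When many cDNAs align poorly to every known D yet resemble each other, an
unlisted germline segment is the parsimonious explanation — provided the
supporting reads come from *distinct* recombinations, defined here as
unique (V gene, CDR3 length) pairs, with a default minimum of 20.
`derive_consensus()` stacks the inter-V–J regions onto the longest member
by pairwise local alignment (the MSA construction is pluggable: any
precomputed alignment matrix is accepted, so an external aligner can be
substituted), then calls per-column plurality with IUPAC codes on ties
and flags unanimous columns as conserved.

Two thresholds matter, and both are explicit because the procedure they
formalize published only a star notation for conserved columns:

* `min_coverage` (default 0.5) drops columns supported by too few
  members. Junction bases flanking the shared core extend a member's
  stacking alignment only by chance matching (probability ≈ 0.27 per
  member), so flank coverage concentrates well below full coverage; when
  deducing an exact germline core we recommend — and the tests use — a
  floor of 0.8.
* `trim_unconserved_flanks` additionally trims terminal non-conserved
  columns. Flanking junction bases are essentially random across members
  and essentially never unanimous, while the core (absent mutation) is.

Consensus of partially trimmed members can only recover the shared core;
columns dropped at the flanks are reported separately as low-support
extensions rather than silently discarded. One genuine identifiability
limit: P nucleotides adjacent to an *untrimmed* shared gene end are
determined by the germline sequence, identical across members, and
therefore indistinguishable from the segment itself; exact-recovery
checks disable P generation at those ends.

## The repertoire generator

`simulate_repertoire()` emulates a fetal cDNA library: seeded gene picks
(uniform by default, weights configurable), geometric per-end trimming,
P at untrimmed ends, A/T-biased N insertions, optional uniform
substitution noise standing in for somatic hypermutation. The study it
emulates measured rather than simulated, so every distribution here is a
stand-in; the defaults are chosen to reproduce its published junction
statistics:

* **N length** per junction is a *hurdle* geometric: zero with
  probability $\pi_0$, else $1 + \mathrm{Geom}(q)$. A plain geometric
  cannot simultaneously match a median of 1, a mean of 2.5 and 65%
  nonzero (the observed VD profile); the hurdle family matches all of
  them plus the ~4.5% frequency of runs ≥ 10 with
  $(\pi_0, q) = (0.35, 0.26)$ for VD and $(0.32, 0.25)$ for DJ. These
  put the true medians (1 and 2) close to the 0.5 quantile boundary —
  that is what the real data look like — so sample medians at n = 2000
  occasionally land one off; distribution checks therefore test the CDF
  at the hinge points rather than sample medians.
* **Trimming** means (3, 7.3, 9, 3 for V3'/D5'/D3'/J5') give geometric
  medians of 2, 5, 6 and 2, truncated so at least `min_remnant = 10`
  bases of each gene survive — a D remnant always clears the evidence
  floor with margin.
* **N base probabilities** default to A 0.31, C 0.17, G 0.19, T 0.33.
* **P** occurs at an untrimmed end with probability 0.4 (so ~16–19% of
  junctions carry P after accounting for trimming), with length
  $1 + \mathrm{Geom}(0.6)$ capped at 6.

### Identifiability

The generator's central design question: when is the truth *recoverable*
from the assembled read? A junction base that happens to continue the
trimmed germline sequence, or to extend a P-complementarity run, makes
the optimal alignment or the greedy P call disagree with the generating
truth — not a bug in the annotator, but genuine ambiguity in the read.
With `identifiable = TRUE` (default) the generator resamples junction
content until:

1. greedy decomposition of the assembled junction against the true gene
   ends reproduces the generated P/N strings;
2. no ungapped extension of any gene alignment past its true boundary has
   a prefix scoring ≥ 0 (match +1 / mismatch −1) — a positive prefix
   would move the optimum, a zero prefix would tie it with a longer
   alignment, which the deterministic tie-break prefers;
3. no *gapped* extension into a trimmed germline continuation scores ≥ 0
   under that side's gap scheme (checked by a small anchored affine DP;
   this matters almost exclusively on the D sides, where a gap costs only
   4.3);
4. the true D gene uniquely wins the D stage (verified with the actual
   engine over all D genes; offending reads are regenerated on a shifted
   substream). Near the 10-base remnant floor, a chance gapped match
   against another D gene can otherwise tie the true one roughly once per
   thousand reads.

P and N lengths are drawn once and only base *content* is resampled, so
the constraints do not distort the configured length distributions;
constraints 2–4 can redraw trims, which is why distributional-fidelity
tests and the generator-emulation statistics use `identifiable = FALSE`
(pure draws). The switch exists precisely so the annotator's behavior on
ambiguous reads can be studied: on unconstrained data the annotator
systematically absorbs some junction bases into segment alignments — an
inherent property of best-alignment junction calling, shared by any
analysis built on it, and worth remembering when comparing junction
statistics across pipelines.

What passing the recovery tests does **not** show about real data: real
reads carry somatic hypermutation, sequencing error, allelic variation
and genuinely ambiguous junctions; recovery there cannot be 100% and the
generator makes no such claim. What it does show is that the bookkeeping
— coordinates, trimming counts, P/N classification, conservation — is
exact whenever the read is unambiguous.

## Scale of the shipped checks

The test suite and acceptance script simulate 2000-read heavy-chain
repertoires (and smaller light-chain sets) against synthetic references
with 6 V, 14 D (31–154 nt, mirroring the real length range) and 3 J
genes; scanner–oracle equivalence uses subjects up to ~470 bp with the
real two-heptamer motif and budget; alignment–oracle equivalence uses
exhaustive dynamic programming on all pairs up to 12 nt. These sizes keep
the full property suite in a few minutes while leaving every quantity
measured at repertoire scale.

## Known limitations

* Somatic hypermutation is noise here, not a model; hotspot motifs,
  clonal structure and indel-generating SHM are out of scope.
* D assignment for very short CDR3s is intrinsically unreliable (shared
  motifs between D genes); the evidence floor and the high-exonuclease
  flag mark, but cannot fix, that ambiguity.
* Gene vs allele cannot be distinguished from sequence alone; reference
  sets should treat variants as separate entries.
* The published analysis counted a small number of reads (~2%) with gaps
  inside the D alignment; how gap columns entered its exo/N tallies is
  not stated, and this package's convention (gap columns are simply part
  of the alignment; junction strings come from the read) is one
  self-consistent choice among several.
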