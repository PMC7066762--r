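---
title: "Flattening haplotype-annotated variation graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flattening haplotype-annotated variation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapflat)
```

## The model

A population graph $G=(V,E)$ is a directed acyclic graph.  Each node $v$
carries a non-empty DNA sequence $v_S$ over $\{A,C,G,T\}$ (plus `N`, which
real references contain); each edge $(u,v)$ carries a non-empty subset
$(u,v)_H$ of the registered haplotypes $H = \{H_0,\dots,H_{h-1}\}$.  Every
haplotype is a path whose concatenated node sequences spell that genome,
and each edge's haplotype set equals exactly the set of haplotypes whose
paths traverse it — `validate_graph()` enforces all of this.

The flattening target is the *null graph* $G^E=(V',\emptyset)$: an
edge-free graph whose node sequences satisfy a two-sided contract for a
chosen window length $k$:

* **completeness** — every length-$k$ substring of every encoded haplotype
  is a substring of some node of $G^E$;
* **soundness** — every length-$k$ window of every node of $G^E$ is a
  substring of some encoded haplotype.

Soundness is the haplotype constraint: unobserved combinations of nearby
variants are never materialised, so the index cannot attract reads to
recombinant sequence that no sample carries, and the amount of work in any
region is bounded by $h$ rather than by the number of variant
combinations.

Assumptions: the graph is acyclic, sequences are forward-strand only, and
haplotype paths are exact (phased input).  Unphased heterozygous genotypes
are rejected at the VCF boundary rather than guessed.

## The three operations

`flatten(g, k)` removes edges one class at a time, with fixed priority
collapse > extend > duplicate:

**Collapse** (`collapse_edge`) merges $(u,v)$ when `out(u) = 1` and
`in(v) = 1`: every path through $u$ continues into $v$, so merging changes
no spelling.  The merged node keeps the lexicographically smaller id,
spells $u_Sv_S$, and concatenates provenance.

**Extend** (`extend_edge`) removes an edge by copying a $(k-1)$-length
flank across it: prefix direction prepends the right flank of $u$ to $v$
(requires `in(v) = 1` and $|u_S| \ge k-1$), suffix direction appends the
left flank of $v$ to $u$ (requires `out(u) = 1` and $|v_S| \ge k-1$).  A
$k$-window spanning one edge uses at most $k-1$ bases of either endpoint,
so the recipient now contains every window that crossed the removed edge.
The degree preconditions are what keep extension *sound*: with
`in(v) = 1`, every window entering $v$ arrived through $(u,v)$, so the
prepended flank never fabricates an unobserved junction.  When both
directions are legal either covers the same windows; the implementation
fixes prefix for determinism.

**Duplicate** (`duplicate_node`) resolves nodes where neither verb
applies.  A through-traversed node $u$ is replaced by one copy per
haplotype-supported in/out edge pair — $\delta$ copies, where $\delta$
counts pairs with intersecting haplotype sets.  Each haplotype enters and
leaves $u$ along exactly one pair, so $\delta \le h$, against the
$\mathrm{in}(u)\times\mathrm{out}(u)$ copies an unconstrained split would
need.  Haplotypes that terminate (or originate) at $u$ — possible with
partial GFA paths, never with VCF-built graphs — get one extra copy per
corresponding edge.  Copies inherit sequence and provenance verbatim, so
spellings are preserved; pair copies have degree 1/1 and become
collapsible.

## Scheduling and determinism

The published description leaves the operation order open (observing no
significant outcome differences between orders).  This implementation
fixes it so that two runs on identical input are byte-identical:

* collapse to fixpoint, then extend; any extension may re-enable
  collapsing, so the pair iterates to a joint fixpoint;
* if edges remain, every one of them is blocked, and at least one endpoint
  of any blocked edge has `in > 1` or `out > 1`; among those candidates
  the node earliest in a stable topological order (Kahn's algorithm,
  C-locale id tie-break) is duplicated — one duplication per round;
* edge iteration everywhere follows C-locale sorted edge keys, copy ids
  are `node.0, node.1, ...` in supported-pair order, and collapse
  survivors keep the smaller id.

Duplicating the topologically earliest candidate resolves blockages from
the sources downstream; a safety cap (`max_rounds`, scaling with graph
size) turns any scheduling bug into an error instead of a hang.  One
duplication per round (rather than all at once) is the simpler rule to
reason about and keeps candidate choice deterministic.

### Finalisation

A node can end up edge-free yet shorter than $k$ when all its incident
edges were resolved by donating flanks (it must then be exactly $k-1$ long
or an isolated leftover copy); such nodes contain no $k$-window and every
window that involved their sequence already lives in a neighbour, so they
are dropped.  Haplotypes *shorter* than $k$ have no $k$-mers at all; their
full spelling is re-added as a node (id `short.<hap>`) unless already
contained in a surviving node, so short genomes stay mappable.  The
resulting mixed case (a sub-$k$ node next to $\ge k$ nodes) is the one
situation where the "every node at least $\min(k,$ longest haplotype$)$"
rule is relaxed in favour of not losing a genome.

## Coordinates, provenance, and projection

All internal coordinates are 0-based half-open; VCF's 1-based positions
are converted at the parser boundary.  Every node carries an ordered list
of provenance segments `(origin, start, end)` into the *input* graph;
collapse concatenates them, extension prepends/appends flank segments
trimmed to exactly $k-1$ bases, duplication copies them.  Contiguous
same-origin segments are merged, which guarantees that consecutive
segments always correspond to edges of the input graph — a projected
alignment is therefore a connected path.

The FASTA emitted by `write_index_fasta()` stores provenance in the record
description (`>{id} {origin}:{start}-{end};...`); aligners ignore text
after the first whitespace, so no sidecar file is needed.  Projection
walks the segments across the reference-consumed interval of a SAM record
(CIGAR `M/D/N/=/X`; soft clips excluded), yielding the node path with
entry/exit offsets.  Reverse-strand alignments keep the forward-graph path
with the strand flagged.

One nuance the test-suite makes explicit: an error-free read can place
*exactly* at two distinct graph loci that spell identical sequence (for
example a read ending one base into an inserted allele whose first base
equals the next reference base).  Any aligner breaks such ties
arbitrarily.  Projection itself is exact — the round-trip tests assert
that the truth coordinates are always among the projections of a read's
exact placements, and that whenever the primary placement is the truth
locus the projected path and offsets match it exactly.

## Parameters

* `k` (required, $\ge 2$): the indexed substring length, in bp.  Choose
  the read length you intend to align (e.g. 100 for typical short reads):
  error-free reads of length $\le k$ then match within single null nodes.
  Larger `k` grows output sequence roughly linearly and slows flattening;
  there is deliberately no default because `k` is a property of the
  experiment, not of the graph.
* `allow_uncovered` (`read_gfa`): legacy GFA graphs may contain links no
  path covers; every downstream guarantee rests on non-empty edge
  haplotype sets, so such edges are a hard error unless explicitly
  admitted under a synthetic `"unknown"` haplotype.
* `on_overlap` (`build_graph`): records whose reference spans intersect
  have no well-defined joint haplotype spelling; hard error by default,
  optionally drop-with-message for pre-filtered call sets.

## The simulator: what it does and does not emulate

`simulate_population()` reproduces the shape of the simulated-population
experiments: `n_samples` diploid samples each contribute exactly
`variants_per_sample` variants; each draw is taken from a shared pool with
probability `share_p` (the pool grows on half of the shared draws and is
reused otherwise) and is otherwise unique to the sample, giving the
"fraction of variation shared with one or more other samples" knob.
Variant sites sit on a lattice spaced `max_indel + 2` apart — the builder
rejects overlapping records, and the published simulation's spacing policy
is not described, so non-overlap by construction is the conservative
choice.  Substitutions are uniform over the three non-reference bases;
indel lengths uniform on `[1, max_indel]`; genotypes for a carried variant
are `1|0 / 0|1 / 1|1` with probability 0.4/0.4/0.2.  Defaults (2 kb
reference, 5 samples, 20 variants each, `share_p = 0.2`, 90% SNPs) are the
desk scale at which the whole acceptance sweep runs in minutes.

Truth haplotype strings are produced by direct string editing of the
reference — never through the graph — so they are an independent oracle
for both graph construction (spelling fidelity) and flattening (the
$k$-mer set equality checks compare against windows of these strings).

What a green test therefore establishes: the combinatorial contract
(completeness + soundness of the $k$-mer set, spelling preservation,
copy-count bound, exact projection) on error-free, uniformly placed,
non-overlapping SNP/indel variation.  What it does not establish:
behaviour under sequencing errors, quality-aware alignment, structural
variants, overlapping or unphased call sets, or the timing/memory profile
of genome-scale graphs — none of which this package claims.

## Known limitations

* Acyclic, forward-strand graphs only; bidirected or cyclic GFA is
  rejected at load.
* Reads longer than $k+1$, paired-end distance constraints, and long
  reads are out of scope; the index is per-read-length.
* Total output sequence is inflated relative to the input graph (shared
  flanks are copied, haplotype copies repeat shared sequence); no attempt
  is made to minimise it.
* The external alignment step itself is delegated; `align_exact()` is an
  exact-match stand-in for testing, not an aligner.
* Variant calling on projected alignments is downstream of this package.
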