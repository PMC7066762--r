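# hapflat

Haplotype-constrained flattening of variation graphs for linear read
alignment.

## The problem

A variation (population) graph compresses a reference genome plus the
variants of many samples into one directed acyclic sequence graph: nodes
carry DNA, edges carry the set of haplotypes observed to traverse them, and
each phased chromosome copy is a path whose concatenated node sequences
spell that genome.  To align reads to such a graph, an index must answer
substring queries over *k*-length paths — and the number of *k*-paths grows
exponentially with variant density, which is why graph indexers prune,
filter, or cap complex regions.

`hapflat` avoids the explosion instead of pruning it.  Only *k*-paths lying
on an observed haplotype are ever enumerated, so the work in any region of
the graph is bounded by the number of encoded haplotypes *h*, not by the
number of variant combinations.  The graph *G* is transformed into a **null
graph** *G^E* — a graph with no edges — whose isolated node sequences
contain **exactly** the *k*-length substrings of the encoded haplotypes:

* every *k*-mer of every haplotype occurs in some node of *G^E*
  (completeness), and
* every *k*-window of every node of *G^E* is a haplotype *k*-mer
  (soundness: no unobserved variant combinations are ever indexed).

The emitted FASTA can be indexed by any linear aligner (BWA, Bowtie2, ...).
Every emitted sequence carries provenance intervals `origin:start-end` back
into the original graph, so alignments against the FASTA are projected back
onto graph coordinates exactly.

## The transformation

Three edge-elimination verbs are applied with fixed priority until no edge
remains (`flatten()`):

* **collapse** — an edge with `out(u)=1` and `in(v)=1` is a redundant
  traversal; merge the two nodes.
* **extend** — copy the `(k-1)`-length flank of one endpoint across the
  edge (as a prefix of `v` when `in(v)=1` and `|u| >= k-1`, or a suffix of
  `u` when `out(u)=1` and `|v| >= k-1`); the edge can then be removed
  without losing any *k*-mer that spanned it.
* **duplicate** — when neither applies, split a branching node into one
  copy per haplotype-supported (in-edge, out-edge) pair — *δ* copies, where
  *δ* counts pairs whose haplotype sets intersect, never more than *h* —
  instead of the `in(u) × out(u)` copies an unconstrained split would need.

## Worked example

A three-haplotype graph with two nearby variant sites is shipped as
`inst/extdata/threehap_synthetic.gfa` (synthetic example data).  Haplotypes
I/II/III realise three of the four possible site combinations; the missing
combination is exactly what a haplotype-blind indexer would also index.

```r
library(hapflat)
g <- read_gfa(system.file("extdata", "threehap_synthetic.gfa", package = "hapflat"))
g
#> population_graph: 7 nodes, 8 edges, 3 haplotypes
spell_haplotype(g, "II")
#> [1] "TCGCACGG"
haplotype_kmers(g, 4)
#>  [1] "AAGG" "ACGG" "CAAG" "CACG" "CGCA" "CTCA" "GCAA" "GCAC" "TCAC" "TCGC"
#> [11] "TCTC"

ng <- flatten(g, 4)
ng
#> null_graph: 3 nodes, 0 edges, 3 haplotypes
```

The null graph holds one node per observed haplotype — never a node for the
unobserved fourth combination — and `null_windows(ng)` equals
`haplotype_kmers(g, 4)`.  Written as FASTA, each record's description is its
provenance in the original graph:

```
>n1.0 n1:0-2;n2:0-1;n4:0-2;n6:0-1;n7:0-2
TCGCACGG
>n1.1 n1:0-2;n3:0-1;n4:0-2;n6:0-1;n7:0-2
TCTCACGG
>n4.0 n1:0-2;n2:0-1;n4:0-2;n5:0-1;n7:0-2
TCGCAAGG
```

An alignment against record `n1.1` projects back onto the graph:

```r
idx <- read_index(fa)                                   # fa = written index
project_alignment(idx, "read1", "n1.1", pos = 2, cigar = "4M")
#> read1 + n1,n3,n4 entry=1 exit=2 4M
```

i.e. the read covers node `n1` from offset 1, all of `n3`, and node `n4` up
to offset 2 — a path through the original graph, recovered from a plain SAM
record.

## Pipeline

```sh
cli/hapflat build    --ref ref.fa --vcf phased.vcf --out graph.gfa
cli/hapflat index    --gfa graph.gfa -k 101 --out index.fa
bwa index index.fa && bwa mem index.fa reads.fq > aln.sam   # any linear aligner
cli/hapflat project  --index index.fa --sam aln.sam --out aln.tsv
```

`-k` is chosen to match the read length (reads of length at most `k` that
are error-free samplings of an encoded haplotype match a node exactly).
The same steps are available programmatically: `build_graph()` /
`read_gfa()` → `flatten()` → `write_index_fasta()` → `project_sam()`.  A
seeded population simulator with truth-tracked reads
(`simulate_population()`, `sample_reads()`) supports end-to-end validation
without any external data.

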