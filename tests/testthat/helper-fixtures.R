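# Fixture builders and independent oracles shared across test files.
# Oracles deliberately avoid the code paths they check: k-mer sets come from
# string-edited truth sequences, never from graph traversal.

# all k-windows of a string, brute force; full string if shorter than k
oracle_windows <- function(s, k) {
  n <- nchar(s)
  if (n <= k) return(s)
  vapply(seq_len(n - k + 1L), function(i) substr(s, i, i + k - 1L), character(1L))
}

oracle_kmers <- function(strings, k) {
  sort(unique(unlist(lapply(strings, oracle_windows, k = k))), method = "radix")
}

# Fig-9-style subgraph: node d, three in-edges with haplotype sets {1},{2},
# {3}, two out-edges with {1,2},{3}
fig9_graph <- function() {
  population_graph(
    c(u = "A", v = "C", w = "G", d = "T", e = "A", f = "C"),
    edges = data.frame(from = c("u", "v", "w", "d", "d"),
                       to = c("d", "d", "d", "e", "f"),
                       haplotypes = c("1", "2", "3", "1,2", "3")))
}

# three-haplotype example graph (synthetic stand-in; also shipped as
# inst/extdata/threehap_synthetic.gfa): two nearby variant sites, three
# observed site combinations out of four possible
threehap_graph <- function() {
  population_graph(
    c(n1 = "TC", n2 = "G", n3 = "T", n4 = "CA", n5 = "A", n6 = "C", n7 = "GG"),
    paths = list(I = c("n1", "n2", "n4", "n5", "n7"),
                 II = c("n1", "n2", "n4", "n6", "n7"),
                 III = c("n1", "n3", "n4", "n6", "n7")))
}

# seeded random population: simulation + built graph + truth strings
make_population <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_population(cfg)
  g <- build_graph(sim$reference, sim$variants)
  list(cfg = cfg, sim = sim, g = g)
}

# per-node sequence map, for graph-equality assertions
node_seq_map <- function(g) {
  ids <- graph_node_ids(g)
  stats::setNames(vapply(ids, function(id) node_seq(g, id), character(1L)), ids)
}

# serialize a graph (nodes + provenance + edges) for determinism checks
graph_signature <- function(g) {
  list(nodes = node_seq_map(g),
       prov = lapply(graph_node_ids(g), node_provenance, g = g),
       edges = graph_edges(g))
}

expect_valid <- function(g) expect_identical(validate_graph(g), character(0L))
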