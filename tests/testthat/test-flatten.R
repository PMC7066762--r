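# collapse / extend / duplicate and the flatten scheduler

test_that("collapse merges a chain edge, keeping sequence, provenance, id order", {
  g <- population_graph(c(A = "AC", B = "GT"), paths = list(ref = c("A", "B")))
  m <- collapse_edge(g, "A", "B")
  expect_identical(m, "A")  # lexicographically smaller id survives
  expect_identical(node_seq(g, "A"), "ACGT")
  expect_identical(node_provenance(g, "A"),
                   data.frame(origin = c("A", "B"), start = c(0L, 0L),
                              end = c(2L, 2L)))
  expect_identical(nrow(graph_edges(g)), 0L)
  expect_identical(spell_haplotype(g, "ref"), "ACGT")
})

test_that("collapse enforces its degree precondition", {
  g <- threehap_graph()
  expect_error(collapse_edge(g, "n1", "n2"), "out\\(n1\\)=2")
  expect_error(collapse_edge(g, "n2", "n4"), "in\\(n4\\)=2")
})

test_that("exhaustive collapsing preserves every haplotype spelling", {
  for (seed in c(31L, 32L)) {
    pop <- make_population(seed, n_samples = 3L, variants_per_sample = 10L,
                           ref_len = 800L)
    g <- graph_copy(pop$g)
    before <- vapply(graph_haplotypes(g), function(h) spell_haplotype(g, h),
                     character(1L))
    while (hapflat:::collapse_pass(g)) {}
    after <- vapply(graph_haplotypes(g), function(h) spell_haplotype(g, h),
                    character(1L))
    expect_identical(after, before)
    expect_valid(g)
  }
})

test_that("extension copies a k-1 flank and removes the edge", {
  # k=2: flank is a single base
  g <- population_graph(c(u = "A", v = "C", w = "G"),
                        paths = list(h1 = c("u", "v"), h2 = c("u", "w")))
  expect_identical(extend_edge(g, "u", "v", 2L), "prefix")
  expect_identical(node_seq(g, "v"), "AC")
  expect_identical(node_provenance(g, "v"),
                   data.frame(origin = c("u", "v"), start = c(0L, 0L),
                              end = c(1L, 1L)))
  expect_false(hapflat:::g_has_edge(g, "u", "v"))

  # k=4, |u|=5: exactly the last 3 characters are prepended
  g2 <- population_graph(c(u = "ACGTT", v = "CCCC", w = "G"),
                         paths = list(h1 = c("u", "v"), h2 = c("u", "w")))
  extend_edge(g2, "u", "v", 4L)
  expect_identical(node_seq(g2, "v"), paste0("GTT", "CCCC"))

  # suffix direction: left flank of v appended to u
  g3 <- population_graph(c(u = "AA", v = "CGTT", w = "G"),
                         paths = list(h1 = c("u", "v"), h2 = c("w", "v")))
  expect_identical(extend_edge(g3, "u", "v", 3L), "suffix")
  expect_identical(node_seq(g3, "u"), "AACG")

  # neither direction legal -> blocked
  g4 <- population_graph(c(u = "AA", v = "CC", w = "G", x = "T"),
                         paths = list(h1 = c("u", "v"), h2 = c("u", "x"),
                                      h3 = c("w", "v")))
  expect_error(extend_edge(g4, "u", "v", 4L), "extension blocked")
})

test_that("extension covers every k-mer that crossed the removed edge", {
  for (seed in c(41L, 42L)) {
    k <- 8L
    pop <- make_population(seed, n_samples = 1L, variants_per_sample = 6L,
                           ref_len = 400L)
    g <- graph_copy(pop$g)
    spelled <- vapply(graph_haplotypes(g), function(h) spell_haplotype(g, h),
                      character(1L))
    # find an extendible edge
    e <- graph_edges(g)
    for (i in seq_len(nrow(e))) {
      u <- e$from[[i]]; v <- e$to[[i]]
      if (hapflat:::g_in(g, v) == 1L && nchar(node_seq(g, u)) >= k - 1L &&
          !(hapflat:::g_out(g, u) == 1L)) {
        crossing <- oracle_kmers(spelled, k)
        crossing <- crossing[vapply(crossing, function(km)
          grepl(km, paste0(node_seq(g, u), node_seq(g, v)), fixed = TRUE) &&
            !grepl(km, node_seq(g, u), fixed = TRUE) &&
            !grepl(km, node_seq(g, v), fixed = TRUE), logical(1L))]
        extend_edge(g, u, v, k)
        windows_after <- oracle_windows(node_seq(g, v), k)
        expect_true(all(crossing %in% windows_after),
                    label = sprintf("seed %d edge (%s,%s)", seed, u, v))
        break
      }
    }
  }
})

test_that("supported_pairs and delta match the Fig-9 configuration", {
  g <- fig9_graph()
  sp <- supported_pairs(g, "d")
  expect_identical(sp,
                   data.frame(in_from = c("u", "v", "w"),
                              out_to = c("e", "e", "f"),
                              haplotypes = c("1", "2", "3")))
  expect_identical(hap_delta(g, "d"), 3L)   # constrained from in x out = 6
  expect_identical(hap_delta(g, "e"), 0L)   # sink: no pairs

  g1 <- population_graph(c(a = "A", b = "C", c = "G"),
                         paths = list(h = c("a", "b", "c")))
  expect_identical(hap_delta(g1, "b"), 1L)
})

test_that("delta equals the path-traversal count on random graphs", {
  for (seed in c(51L, 52L)) {
    pop <- make_population(seed, n_samples = 4L, variants_per_sample = 8L,
                           ref_len = 700L)
    g <- pop$g
    h <- length(graph_haplotypes(g))
    for (u in graph_node_ids(g)) {
      # oracle: distinct (pred, succ) pairs used by haplotype paths through u
      pairs <- unique(do.call(rbind, lapply(graph_haplotypes(g), function(hh) {
        p <- haplotype_path(g, hh)
        i <- match(u, p)
        if (is.na(i) || i == 1L || i == length(p)) return(NULL)
        data.frame(from = p[[i - 1L]], to = p[[i + 1L]])
      })))
      delta <- hap_delta(g, u)
      expect_identical(delta, if (is.null(pairs)) 0L else nrow(pairs),
                       label = sprintf("seed %d node %s", seed, u))
      expect_lte(delta, min(hapflat:::g_in(g, u) * hapflat:::g_out(g, u), h))
    }
  }
})

test_that("duplication splits the Fig-9 node into 3 copies, not 6", {
  g <- fig9_graph()
  ids <- duplicate_node(g, "d")
  expect_identical(length(ids), 3L)
  expect_false("d" %in% graph_node_ids(g))
  e <- graph_edges(g)
  expect_identical(nrow(e), 6L)  # 3 in + 3 out, each copy 1-in/1-out
  for (id in ids) {
    expect_identical(hapflat:::g_in(g, id), 1L)
    expect_identical(hapflat:::g_out(g, id), 1L)
    expect_identical(node_seq(g, id), "T")
  }
  # each copy's two edges carry the same single haplotype
  for (id in ids) {
    hin <- hapflat:::g_edge_haps(g, hapflat:::g_preds(g, id), id)
    hout <- hapflat:::g_edge_haps(g, id, hapflat:::g_succs(g, id))
    expect_identical(hin, hout)
  }
  # and the copies' in-edges (u,d), (v,d'), (w,d'') are now collapsible
  for (id in ids) {
    p <- hapflat:::g_preds(g, id)
    m <- collapse_edge(g, p, id)
    expect_identical(nchar(node_seq(g, m)), 2L)
  }
})

test_that("degenerate duplication of a 1-in/1-out node is an isomorphism", {
  g <- population_graph(c(a = "A", b = "C", c = "G"),
                        paths = list(h = c("a", "b", "c")))
  ids <- duplicate_node(g, "b")
  expect_identical(length(ids), 1L)
  expect_identical(spell_haplotype(g, "h"), "ACG")
  expect_valid(g)
})

test_that("duplication preserves spellings and respects the haplotype bound", {
  for (seed in c(61L, 62L)) {
    pop <- make_population(seed, n_samples = 3L, variants_per_sample = 8L,
                           ref_len = 700L)
    g <- graph_copy(pop$g)
    h <- length(graph_haplotypes(g))
    before <- vapply(graph_haplotypes(g), function(hh) spell_haplotype(g, hh),
                     character(1L))
    # duplicate every branching node present in the input
    for (u in graph_node_ids(g)) {
      if (hapflat:::g_in(g, u) > 1L || hapflat:::g_out(g, u) > 1L) {
        ids <- duplicate_node(g, u)
        expect_lte(length(ids), h)
      }
    }
    after <- vapply(graph_haplotypes(g), function(hh) spell_haplotype(g, hh),
                    character(1L))
    expect_identical(after, before)
    expect_valid(g)
  }
})

test_that("flatten leaves an already-null graph unchanged", {
  g <- population_graph(c(A = "ACGTACGT"), paths = list(ref = "A"))
  ng <- flatten(g, 4L)
  expect_true(is_null_graph(ng))
  expect_identical(node_seq_map(ng), c(A = "ACGTACGT"))
})

test_that("flatten rejects bad inputs", {
  g <- population_graph(c(A = "AC", B = "GT"), paths = list(ref = c("A", "B")),
                        validate = FALSE)
  hapflat:::g_add_edge(g, "B", "A", "ref")
  expect_error(flatten(g, 4L), "cycl|invalid")
  g2 <- threehap_graph()
  expect_error(flatten(g2, 1L), "k must be")
})

test_that("the three-haplotype example graph flattens to 3 nodes at k=4", {
  g <- threehap_graph()
  ng <- flatten(g, 4L)
  expect_identical(length(graph_node_ids(ng)), 3L)
  expect_identical(null_windows(ng), haplotype_kmers(g, 4L))
  # one node per observed haplotype, none for unobserved site combinations
  expect_setequal(unname(node_seq_map(ng)),
                  vapply(c("I", "II", "III"), function(h) spell_haplotype(g, h),
                         character(1L)))
})

test_that("k-mer set equality holds on seeded random populations", {
  for (seed in c(71L, 72L, 73L)) {
    pop <- make_population(seed)
    for (k in c(8L, 16L, 32L)) {
      ng <- flatten(pop$g, k)
      expect_identical(null_windows(ng), oracle_kmers(pop$sim$truth, k),
                       label = sprintf("seed %d k %d", seed, k))
      expect_true(all(nchar(node_seq_map(ng)) >=
                        min(k, max(nchar(pop$sim$truth)))))
    }
  }
})

test_that("null-node provenance spells the node and walks a path in the input graph", {
  pop <- make_population(81L, n_samples = 3L, variants_per_sample = 10L,
                         ref_len = 800L)
  ng <- flatten(pop$g, 12L)
  for (id in graph_node_ids(ng)) {
    p <- node_provenance(ng, id)
    spelled <- paste(vapply(seq_len(nrow(p)), function(i)
      substr(node_seq(pop$g, p$origin[[i]]), p$start[[i]] + 1L, p$end[[i]]),
      character(1L)), collapse = "")
    expect_identical(spelled, node_seq(ng, id))
    # consecutive origins must be connected in the input graph
    if (nrow(p) > 1L) {
      for (i in seq_len(nrow(p) - 1L)) {
        expect_true(hapflat:::g_has_edge(pop$g, p$origin[[i]], p$origin[[i + 1L]]),
                    label = sprintf("node %s step %d", id, i))
      }
      # interior segments cover whole origin nodes; ends may be trimmed
      for (i in seq(2L, nrow(p) - 1L, length.out = max(0L, nrow(p) - 2L))) {
        expect_identical(p$end[[i]] - p$start[[i]],
                         nchar(node_seq(pop$g, p$origin[[i]])))
      }
    }
  }
})

test_that("flatten is deterministic", {
  pop <- make_population(91L, n_samples = 3L, variants_per_sample = 10L,
                         ref_len = 600L)
  s1 <- graph_signature(flatten(pop$g, 16L))
  s2 <- graph_signature(flatten(pop$g, 16L))
  expect_identical(s1, s2)
})

test_that("flatten terminates on many tiny seeded graphs", {
  # wide sweep of small populations; failures here would be infinite loops
  # caught by the scheduler's round cap
  for (seed in 1:60) {
    pop <- make_population(1000L + seed, n_samples = 2L,
                           variants_per_sample = 4L, ref_len = 250L,
                           max_indel = 3L)
    for (k in c(4L, 9L)) {
      ng <- flatten(pop$g, k)
      expect_true(is_null_graph(ng))
      expect_identical(null_windows(ng), oracle_kmers(pop$sim$truth, k),
                       label = sprintf("seed %d k %d", seed, k))
    }
  }
})

test_that("haplotypes shorter than k keep their full spelling", {
  g <- population_graph(c(A = "AC", B = "GT"), paths = list(ref = c("A", "B")))
  ng <- flatten(g, 8L)
  expect_identical(unname(node_seq_map(ng)), "ACGT")
  expect_identical(null_windows(ng), "ACGT")
})
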