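# Deterministic scheduler turning a population graph into a null graph.

collapse_pass <- function(g) {
  any_applied <- FALSE
  for (key in env_keys(g$edges)) {
    if (!exists(key, envir = g$edges, inherits = FALSE)) next  # stale key
    uv <- edge_unkey(key)
    if (g_out(g, uv[1L]) == 1L && g_in(g, uv[2L]) == 1L) {
      collapse_edge(g, uv[1L], uv[2L])
      any_applied <- TRUE
    }
  }
  any_applied
}

extend_pass <- function(g, k) {
  any_applied <- FALSE
  for (key in env_keys(g$edges)) {
    if (!exists(key, envir = g$edges, inherits = FALSE)) next
    uv <- edge_unkey(key)
    u <- uv[1L]; v <- uv[2L]
    if (g_out(g, u) == 1L && g_in(g, v) == 1L) next  # collapse has priority
    nu_len <- nchar(g_node(g, u)$seq)
    nv_len <- nchar(g_node(g, v)$seq)
    if ((g_in(g, v) == 1L && nu_len >= k - 1L) ||
        (g_out(g, u) == 1L && nv_len >= k - 1L)) {
      extend_edge(g, u, v, k)
      any_applied <- TRUE
    }
  }
  any_applied
}

# collapse to fixpoint, then extend; any extension can re-enable collapsing
simplify_to_fixpoint <- function(g, k) {
  repeat {
    while (collapse_pass(g)) {}
    if (!extend_pass(g, k)) break
  }
}

# duplication candidate: endpoint of a remaining (hence blocked) edge with
# in > 1 or out > 1, earliest in a stable topological order (ties by id)
pick_duplication_candidate <- function(g) {
  keys <- env_keys(g$edges)
  ends <- unique(unlist(edge_unkey(keys)))
  cand <- ends[vapply(ends, function(v) g_in(g, v) > 1L || g_out(g, v) > 1L,
                      logical(1L))]
  if (!length(cand)) {
    stopf("internal error: blocked edges remain but no duplication candidate exists")
  }
  topo <- topo_order(g)
  topo[min(match(cand, topo))]
}

#' Flatten a population graph into a null graph
#'
#' Applies collapse, extend, and duplicate until no edges remain, using the
#' fixed priority collapse > extend > duplicate with one duplication per
#' round, which makes the output a deterministic function of the input.  The
#' result is an edge-free graph whose node sequences cover *exactly* the
#' k-length substrings of the encoded haplotypes: every haplotype k-mer
#' occurs in some node, and every k-window of every node is a haplotype
#' k-mer.  Each node carries provenance intervals mapping its sequence onto
#' a path through the input graph.
#'
#' Finalisation drops edge-free leftovers shorter than `k` (such nodes
#' contain no k-window; their flanks were donated to neighbours), then
#' re-adds the full spelling of any haplotype shorter than `k` that is not
#' already contained in a surviving node, so short genomes stay mappable.
#'
#' @param g a valid acyclic `population_graph`; it is not modified
#' @param k target substring length (>= 2); reads up to this length aligned
#'   against the emitted sequences can be projected back onto the graph
#' @param max_rounds safety cap on duplication rounds (default scales with
#'   graph size)
#' @param trace optional callback invoked after every duplication round as
#'   `trace(graph, node, copies)` with the working graph, the id of the
#'   duplicated node and the copy ids; used by invariant-checking tests
#' @return a `null_graph` (a `population_graph` with an empty edge set and a
#'   `k` field)
#' @export
flatten <- function(g, k, max_rounds = NULL, trace = NULL) {
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  k <- as.integer(k)
  viol <- validate_graph(g)
  if (length(viol)) stopf("refusing to flatten an invalid graph:\n  %s",
                          paste(viol, collapse = "\n  "))
  if (is.null(topo_order(g))) stopf("input graph is cyclic")

  # spellings of haplotypes shorter than k, needed again at finalisation
  tracked <- env_keys(g$paths)
  spelled <- vapply(tracked, function(h) spell_haplotype(g, h), character(1L))
  shorts <- spelled[nchar(spelled) < k]

  w <- graph_copy(g)
  max_rounds <- max_rounds %||% (10L * length(graph_node_ids(g)) +
                                   10L * length(env_keys(g$edges)) + 1000L)
  rounds <- 0L
  repeat {
    simplify_to_fixpoint(w, k)
    if (!length(env_keys(w$edges))) break
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      stopf("flattening did not terminate within %d duplication rounds", max_rounds)
    }
    target <- pick_duplication_candidate(w)
    copies <- duplicate_node(w, target)
    if (!is.null(trace)) trace(w, target, copies)
  }

  # finalisation: drop <k leftovers, restore short-haplotype spellings
  for (id in graph_node_ids(w)) {
    if (nchar(g_node(w, id)$seq) < k) g_rm_node(w, id)
  }
  if (length(shorts)) {
    remaining <- vapply(graph_node_ids(w), function(id) g_node(w, id)$seq, character(1L))
    for (h in names(shorts)) {
      s <- shorts[[h]]
      if (!any(vapply(remaining, function(r) grepl(s, r, fixed = TRUE), logical(1L)))) {
        prov <- list()
        for (id in get(h, envir = g$paths)) {
          prov <- prov_concat(prov, list(prov_seg(id, 0L, nchar(g_node(g, id)$seq))))
        }
        g_add_node(w, sprintf("short.%s", h), s, prov)
      }
    }
  }
  rm(list = env_keys(w$paths), envir = w$paths)
  w$k <- k
  class(w) <- c("null_graph", "population_graph")
  w
}

#' Test for / assert the null-graph contract
#'
#' @param g object
#' @return `is_null_graph`: `TRUE` when `g` is an edge-free
#'   `population_graph`
#' @export
is_null_graph <- function(g) {
  inherits(g, "population_graph") && length(env_keys(g$edges)) == 0L
}

#' k-window set of a null graph's node sequences
#'
#' The set this package's central guarantee is stated over: for a null graph
#' produced by [flatten()] with parameter `k`, `null_windows(ng)` equals
#' `haplotype_kmers(g, k)` of the input graph.
#'
#' @param ng a `null_graph`
#' @param k window length; defaults to the `k` the graph was produced with
#' @return character vector of distinct windows, C-locale sorted
#' @export
null_windows <- function(ng, k = NULL) {
  k <- k %||% ng$k
  if (is.null(k)) stopf("k not recorded on graph; pass it explicitly")
  node_window_set(ng, k)
}
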