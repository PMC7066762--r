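#' Haplotype-annotated population graphs
#'
#' A population graph is a directed acyclic graph whose nodes carry DNA
#' sequences and whose edges carry the non-empty set of haplotypes observed to
#' traverse them.  Each encoded haplotype is a path through the graph; the
#' concatenation of node sequences along the path spells that haplotype.
#' Nodes additionally carry an ordered provenance list of `(origin, start,
#' end)` intervals into the *original* input graph, which is what makes
#' alignments against flattened sequences projectable back onto the graph.
#'
#' Graphs use reference semantics (they are environments, in the spirit of
#' `data.table`): the transformation verbs in this package modify their input
#' in place and return it invisibly.  Use [graph_copy()] to keep the original.
#'
#' @param nodes named character vector of node sequences over `{A,C,G,T,N}`;
#'   names are node ids (no whitespace).
#' @param paths named list of haplotype paths, each a character vector of node
#'   ids; names are haplotype ids.  Edge haplotype sets are derived from the
#'   paths.  May be `NULL` when `edges` carries explicit haplotype sets.
#' @param edges optional `data.frame` with columns `from`, `to`, `haplotypes`
#'   (comma-separated haplotype ids).  Needed only for graphs stated directly
#'   in terms of edge haplotype sets; when `paths` are given too, path-derived
#'   sets are unioned in and must be consistent.
#' @param haplotypes optional character vector registering haplotype ids in
#'   addition to those appearing in `paths`/`edges`.
#' @param validate check invariants on construction (default `TRUE`).
#' @return an object of class `population_graph`.
#' @examples
#' g <- population_graph(c(A = "AC", B = "GT"), paths = list(ref = c("A", "B")))
#' spell_haplotype(g, "ref")
#' @export
population_graph <- function(nodes, paths = NULL, edges = NULL,
                             haplotypes = NULL, validate = TRUE) {
  if (is.null(names(nodes)) || anyNA(names(nodes)) || any(names(nodes) == "")) {
    stopf("nodes must be a named character vector (names are node ids)")
  }
  if (anyDuplicated(names(nodes))) stopf("duplicate node ids")
  if (any(grepl("[[:space:]]", names(nodes)))) stopf("node ids must not contain whitespace")
  check_dna(nodes, "node sequence")
  if (any(nchar(nodes) < 1L)) stopf("node sequences must be non-empty")

  g <- new.env(parent = emptyenv())
  class(g) <- "population_graph"
  g$nodes <- new_env()
  g$edges <- new_env()
  g$in_adj <- new_env()
  g$out_adj <- new_env()
  g$paths <- new_env()
  g$haps <- character(0L)

  for (id in names(nodes)) {
    seq <- unname(nodes[[id]])
    g_add_node(g, id, seq, list(prov_seg(id, 0L, nchar(seq))))
  }

  hap_ids <- character(0L)
  if (!is.null(paths)) {
    if (is.null(names(paths))) stopf("paths must be a named list (names are haplotype ids)")
    hap_ids <- c(hap_ids, names(paths))
  }
  if (!is.null(edges) && nrow(edges) > 0L) {
    hsets <- strsplit(as.character(edges$haplotypes), ",", fixed = TRUE)
    hap_ids <- c(hap_ids, unlist(hsets))
  }
  hap_ids <- sortc(unique(c(hap_ids, haplotypes)))
  if (length(hap_ids) < 1L) stopf("at least one haplotype must be registered")
  g$haps <- hap_ids

  if (!is.null(edges) && nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      g_add_edge(g, as.character(edges$from[i]), as.character(edges$to[i]),
                 strsplit(as.character(edges$haplotypes[i]), ",", fixed = TRUE)[[1L]])
    }
  }
  if (!is.null(paths)) {
    for (h in names(paths)) {
      p <- as.character(paths[[h]])
      if (length(p) == 0L) stopf("haplotype '%s' has an empty path", h)
      assign(h, p, envir = g$paths)
      if (length(p) > 1L) {
        for (i in seq_len(length(p) - 1L)) g_add_edge(g, p[i], p[i + 1L], h)
      }
    }
  }

  if (validate) {
    viol <- validate_graph(g)
    if (length(viol)) stopf("invalid population graph:\n  %s", paste(viol, collapse = "\n  "))
  }
  g
}

# ---- low-level mutators (internal; do not validate) -------------------------

g_add_node <- function(g, id, seq, prov) {
  assign(id, list(seq = seq, prov = prov), envir = g$nodes)
  assign(id, character(0L), envir = g$in_adj)
  assign(id, character(0L), envir = g$out_adj)
  invisible(g)
}

g_has_node <- function(g, id) exists(id, envir = g$nodes, inherits = FALSE)

g_node <- function(g, id) {
  if (!g_has_node(g, id)) stopf("unknown node '%s'", id)
  get(id, envir = g$nodes, inherits = FALSE)
}

g_rm_node <- function(g, id) {
  for (u in get(id, envir = g$in_adj)) g_rm_edge(g, u, id)
  for (v in get(id, envir = g$out_adj)) g_rm_edge(g, id, v)
  rm(list = id, envir = g$nodes)
  rm(list = id, envir = g$in_adj)
  rm(list = id, envir = g$out_adj)
  invisible(g)
}

g_add_edge <- function(g, u, v, haps) {
  if (!g_has_node(g, u)) stopf("edge endpoint '%s' is not a node", u)
  if (!g_has_node(g, v)) stopf("edge endpoint '%s' is not a node", v)
  if (identical(u, v)) stopf("self-loop on node '%s' not permitted", u)
  key <- edge_key(u, v)
  if (exists(key, envir = g$edges, inherits = FALSE)) {
    haps <- union(get(key, envir = g$edges), haps)
  } else {
    assign(u, c(get(u, envir = g$out_adj), v), envir = g$out_adj)
    assign(v, c(get(v, envir = g$in_adj), u), envir = g$in_adj)
  }
  assign(key, sortc(unique(haps)), envir = g$edges)
  invisible(g)
}

g_has_edge <- function(g, u, v) exists(edge_key(u, v), envir = g$edges, inherits = FALSE)

g_edge_haps <- function(g, u, v) {
  key <- edge_key(u, v)
  if (!exists(key, envir = g$edges, inherits = FALSE)) stopf("no edge (%s,%s)", u, v)
  get(key, envir = g$edges)
}

g_rm_edge <- function(g, u, v) {
  key <- edge_key(u, v)
  if (!exists(key, envir = g$edges, inherits = FALSE)) return(invisible(g))
  rm(list = key, envir = g$edges)
  assign(u, setdiff(get(u, envir = g$out_adj), v), envir = g$out_adj)
  assign(v, setdiff(get(v, envir = g$in_adj), u), envir = g$in_adj)
  invisible(g)
}

g_in <- function(g, v) length(get(v, envir = g$in_adj, inherits = FALSE))
g_out <- function(g, v) length(get(v, envir = g$out_adj, inherits = FALSE))
g_preds <- function(g, v) get(v, envir = g$in_adj, inherits = FALSE)
g_succs <- function(g, v) get(v, envir = g$out_adj, inherits = FALSE)

# ---- public accessors -------------------------------------------------------

#' Node ids of a graph
#' @param g a `population_graph`
#' @return character vector, C-locale sorted
#' @export
graph_node_ids <- function(g) env_keys(g$nodes)

#' Node sequence / provenance lookup
#' @param g a `population_graph`
#' @param id node id
#' @return `node_seq`: the node's DNA string. `node_provenance`: a
#'   `data.frame` with columns `origin`, `start`, `end` (0-based half-open).
#' @export
node_seq <- function(g, id) g_node(g, id)$seq

#' @rdname node_seq
#' @export
node_provenance <- function(g, id) {
  p <- g_node(g, id)$prov
  data.frame(origin = vapply(p, `[[`, character(1L), "origin"),
             start = vapply(p, `[[`, integer(1L), "start"),
             end = vapply(p, `[[`, integer(1L), "end"))
}

#' Edge table of a graph
#' @param g a `population_graph`
#' @return `data.frame` with columns `from`, `to`, `haplotypes`
#'   (comma-separated), sorted by (from, to)
#' @export
graph_edges <- function(g) {
  keys <- env_keys(g$edges)
  if (length(keys) == 0L) {
    return(data.frame(from = character(0L), to = character(0L),
                      haplotypes = character(0L)))
  }
  uv <- matrix(unlist(edge_unkey(keys)), ncol = 2L, byrow = TRUE)
  data.frame(from = uv[, 1L], to = uv[, 2L],
             haplotypes = vapply(keys, function(k)
               paste(get(k, envir = g$edges), collapse = ","), character(1L),
               USE.NAMES = FALSE))
}

#' Registered haplotype ids
#' @param g a `population_graph`
#' @return character vector
#' @export
graph_haplotypes <- function(g) g$haps

#' Haplotype path lookup
#' @param g a `population_graph`
#' @param hap haplotype id
#' @return character vector of node ids, or `NULL` if the path is not tracked
#'   (e.g. after extension operations have rewritten the graph)
#' @export
haplotype_path <- function(g, hap) {
  if (!hap %in% g$haps) stopf("unknown haplotype '%s'", hap)
  if (exists(hap, envir = g$paths, inherits = FALSE)) {
    get(hap, envir = g$paths, inherits = FALSE)
  } else NULL
}

#' Deep copy of a graph
#'
#' Transformation verbs mutate in place; copy first when the input must
#' survive.
#' @param g a `population_graph`
#' @return an independent `population_graph`
#' @export
graph_copy <- function(g) {
  h <- new.env(parent = emptyenv())
  class(h) <- class(g)
  h$nodes <- as.environment(as.list(g$nodes, all.names = TRUE))
  h$edges <- as.environment(as.list(g$edges, all.names = TRUE))
  h$in_adj <- as.environment(as.list(g$in_adj, all.names = TRUE))
  h$out_adj <- as.environment(as.list(g$out_adj, all.names = TRUE))
  h$paths <- as.environment(as.list(g$paths, all.names = TRUE))
  parent.env(h$nodes) <- emptyenv(); parent.env(h$edges) <- emptyenv()
  parent.env(h$in_adj) <- emptyenv(); parent.env(h$out_adj) <- emptyenv()
  parent.env(h$paths) <- emptyenv()
  h$haps <- g$haps
  h
}

#' @export
print.population_graph <- function(x, ...) {
  cat(sprintf("%s: %d nodes, %d edges, %d haplotypes\n",
              if (inherits(x, "null_graph")) "null_graph" else "population_graph",
              length(graph_node_ids(x)), length(env_keys(x$edges)),
              length(x$haps)))
  invisible(x)
}

# ---- topology ---------------------------------------------------------------

# Kahn's algorithm with lexicographic (C-locale) tie-break; NULL on cycle.
topo_order <- function(g) {
  ids <- graph_node_ids(g)
  indeg <- vapply(ids, function(v) g_in(g, v), integer(1L))
  ready <- sortc(ids[indeg == 0L])
  names(indeg) <- ids
  out <- character(0L)
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, v)
    added <- character(0L)
    for (w in g_succs(g, v)) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) added <- c(added, w)
    }
    if (length(added)) ready <- sortc(c(ready, added))
  }
  if (length(out) != length(ids)) NULL else out
}

# ---- validation -------------------------------------------------------------

#' Validate population-graph invariants
#'
#' Checks the structural contract: DAG-ness, non-empty sequences and edge
#' haplotype sets, provenance consistency, haplotype paths that are connected
#' and supported by their edges, and edge haplotype sets that agree with the
#' registered paths.
#'
#' @param g a `population_graph`
#' @return character vector of human-readable violations; empty when valid
#' @export
validate_graph <- function(g) {
  viol <- character(0L)
  ids <- graph_node_ids(g)

  for (id in ids) {
    n <- g_node(g, id)
    if (nchar(n$seq) < 1L) viol <- c(viol, sprintf("empty sequence on node %s", id))
    if (prov_len(n$prov) != nchar(n$seq)) {
      viol <- c(viol, sprintf("provenance length %d != sequence length %d on node %s",
                              prov_len(n$prov), nchar(n$seq), id))
    }
  }

  for (key in env_keys(g$edges)) {
    uv <- edge_unkey(key)
    hs <- get(key, envir = g$edges)
    if (length(hs) == 0L) {
      viol <- c(viol, sprintf("empty haplotype set on (%s,%s)", uv[1L], uv[2L]))
    }
    if (!all(hs %in% g$haps)) {
      viol <- c(viol, sprintf("unregistered haplotypes {%s} on (%s,%s)",
                              paste(setdiff(hs, g$haps), collapse = ","), uv[1L], uv[2L]))
    }
  }

  if (is.null(topo_order(g))) viol <- c(viol, "cycle detected")

  # haplotype paths must be connected and supported; where all paths are
  # tracked, edge sets must equal exactly the haplotypes whose paths use them
  tracked <- env_keys(g$paths)
  path_edges <- new_env()
  for (h in tracked) {
    p <- get(h, envir = g$paths)
    if (!all(p %in% ids)) {
      viol <- c(viol, sprintf("haplotype %s path names missing node(s) %s", h,
                              paste(setdiff(p, ids), collapse = ",")))
      next
    }
    if (length(p) > 1L) {
      for (i in seq_len(length(p) - 1L)) {
        if (!g_has_edge(g, p[i], p[i + 1L])) {
          viol <- c(viol, sprintf("haplotype %s path breaks at (%s,%s): no such edge",
                                  h, p[i], p[i + 1L]))
        } else {
          if (!h %in% g_edge_haps(g, p[i], p[i + 1L])) {
            viol <- c(viol, sprintf("edge (%s,%s) lacks traversing haplotype %s",
                                    p[i], p[i + 1L], h))
          }
          key <- edge_key(p[i], p[i + 1L])
          assign(key, c(if (exists(key, envir = path_edges, inherits = FALSE))
            get(key, envir = path_edges) else character(0L), h), envir = path_edges)
        }
      }
    }
  }
  if (setequal(tracked, g$haps) && length(tracked)) {
    for (key in env_keys(g$edges)) {
      uv <- edge_unkey(key)
      stored <- get(key, envir = g$edges)
      fromp <- if (exists(key, envir = path_edges, inherits = FALSE))
        sortc(unique(get(key, envir = path_edges))) else character(0L)
      if (!identical(stored, fromp)) {
        viol <- c(viol, sprintf(
          "edge (%s,%s) haplotype set {%s} differs from path-derived {%s}",
          uv[1L], uv[2L], paste(stored, collapse = ","), paste(fromp, collapse = ",")))
      }
    }
  }
  viol
}

# ---- spelling and k-mers ----------------------------------------------------

#' Spell a haplotype
#'
#' Concatenates the node sequences along the haplotype's path.
#'
#' @param g a `population_graph`
#' @param hap haplotype id
#' @return DNA string
#' @export
spell_haplotype <- function(g, hap) {
  p <- haplotype_path(g, hap)
  if (is.null(p)) stopf("path for haplotype '%s' is not tracked in this graph", hap)
  paste(vapply(p, function(id) g_node(g, id)$seq, character(1L)), collapse = "")
}

# all k-windows of a single string; the full string when shorter than k
str_windows <- function(s, k) {
  n <- nchar(s)
  if (n <= k) return(s)
  substring(s, 1:(n - k + 1L), k:n)
}

#' Haplotype k-mer set
#'
#' The union over all registered haplotypes of every length-`k` substring of
#' their spelled sequences.  A haplotype shorter than `k` contributes its full
#' sequence, so short genomes remain representable.
#'
#' @param g a `population_graph` with tracked haplotype paths
#' @param k window length (>= 1)
#' @return character vector of distinct substrings, C-locale sorted
#' @export
haplotype_kmers <- function(g, k) {
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  sortc(unique(unlist(lapply(g$haps, function(h)
    str_windows(spell_haplotype(g, h), as.integer(k))))))
}

# k-window set of the node sequences themselves (used against null graphs)
node_window_set <- function(g, k) {
  sortc(unique(unlist(lapply(graph_node_ids(g), function(id)
    str_windows(g_node(g, id)$seq, as.integer(k))))))
}
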