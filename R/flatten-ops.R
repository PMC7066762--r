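# The three edge-elimination verbs: collapse, extend, duplicate.
# All of them mutate the graph in place (reference semantics).

# ---- path bookkeeping -------------------------------------------------------

# Haplotype-path tracking survives collapse and duplicate exactly; extension
# rewrites sequences in a way that no longer corresponds to a node path, so
# affected haplotypes simply stop being tracked (their spelling is frozen in
# the k-mer contract, not in the path table).
drop_path <- function(g, hap) {
  if (exists(hap, envir = g$paths, inherits = FALSE)) rm(list = hap, envir = g$paths)
}

#' Collapse an edge
#'
#' Merges `v` into `u` (or vice versa) along an edge with `out(u) = 1` and
#' `in(v) = 1`: such an edge is a redundant traversal, since every path
#' through `u` continues into `v`.  The merged node spells `u` then `v`,
#' concatenates their provenance, keeps the lexicographically smaller of the
#' two ids, and inherits the remaining edges of both endpoints with their
#' haplotype sets unchanged.  Haplotype spellings are preserved.
#'
#' @param g a `population_graph` (modified in place)
#' @param u,v edge endpoints
#' @return the surviving node id
#' @export
collapse_edge <- function(g, u, v) {
  if (!g_has_edge(g, u, v)) stopf("no edge (%s,%s)", u, v)
  if (g_out(g, u) != 1L || g_in(g, v) != 1L) {
    stopf("collapse requires out(u)=1 and in(v)=1; got out(%s)=%d, in(%s)=%d",
          u, g_out(g, u), v, g_in(g, v))
  }
  nu <- g_node(g, u)
  nv <- g_node(g, v)
  m <- sortc(c(u, v))[1L]
  seq <- paste0(nu$seq, nv$seq)
  prov <- prov_concat(nu$prov, nv$prov)

  ins <- lapply(g_preds(g, u), function(x) list(x, g_edge_haps(g, x, u)))
  outs <- lapply(g_succs(g, v), function(y) list(y, g_edge_haps(g, v, y)))

  g_rm_edge(g, u, v)
  g_rm_node(g, u)
  g_rm_node(g, v)
  g_add_node(g, m, seq, prov)
  for (e in ins) g_add_edge(g, e[[1L]], m, e[[2L]])
  for (e in outs) g_add_edge(g, m, e[[1L]], e[[2L]])

  for (h in env_keys(g$paths)) {
    p <- get(h, envir = g$paths)
    iu <- match(u, p)
    if (!is.na(iu) && iu < length(p) && p[[iu + 1L]] == v) {
      assign(h, c(p[seq_len(iu - 1L)], m, p[seq(iu + 2L, length.out = length(p) - iu - 1L)]),
             envir = g$paths)
    } else if ((!is.na(iu)) || v %in% p) {
      # path enters or leaves mid-merge (possible only with partial GFA
      # paths); its spelling would change, so stop tracking it
      drop_path(g, h)
    }
  }
  m
}

#' Extend across an edge
#'
#' Copies a `(k-1)`-length flank across the edge `(u,v)` so the edge can be
#' deleted without losing any k-length substring that spanned it: in the
#' prefix direction the right-hand flank of `u` is prepended to `v` (legal
#' when `in(v) = 1` and `|u| >= k-1`); in the suffix direction the left-hand
#' flank of `v` is appended to `u` (legal when `out(u) = 1` and
#' `|v| >= k-1`).  Flank provenance is carried along, trimmed to exactly
#' `k-1` bases.
#'
#' @param g a `population_graph` (modified in place)
#' @param u,v edge endpoints
#' @param k target substring length (>= 2)
#' @param direction `"auto"` (prefer prefix when both are legal), `"prefix"`,
#'   or `"suffix"`
#' @return the direction applied, `"prefix"` or `"suffix"`
#' @export
extend_edge <- function(g, u, v, k, direction = c("auto", "prefix", "suffix")) {
  direction <- match.arg(direction)
  if (!g_has_edge(g, u, v)) stopf("no edge (%s,%s)", u, v)
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  k <- as.integer(k)
  nu <- g_node(g, u)
  nv <- g_node(g, v)
  prefix_ok <- g_in(g, v) == 1L && nchar(nu$seq) >= k - 1L
  suffix_ok <- g_out(g, u) == 1L && nchar(nv$seq) >= k - 1L
  dir <- switch(direction,
    auto = if (prefix_ok) "prefix" else if (suffix_ok) "suffix" else NA_character_,
    prefix = if (prefix_ok) "prefix" else NA_character_,
    suffix = if (suffix_ok) "suffix" else NA_character_)
  if (is.na(dir)) {
    stopf(paste0("extension blocked on (%s,%s): needs in(v)=1 with |u_S|>=k-1 ",
                 "or out(u)=1 with |v_S|>=k-1 (resolve a neighbouring edge first)"), u, v)
  }

  stale <- vapply(env_keys(g$paths), function(h) {
    p <- get(h, envir = g$paths)
    iu <- match(u, p)
    (!is.na(iu) && iu < length(p) && p[[iu + 1L]] == v) ||
      (dir == "prefix" && p[[1L]] == v) ||
      (dir == "suffix" && p[[length(p)]] == u)
  }, logical(1L))
  for (h in names(stale)[stale]) drop_path(g, h)

  if (dir == "prefix") {
    flank <- substr(nu$seq, nchar(nu$seq) - k + 2L, nchar(nu$seq))
    assign(v, list(seq = paste0(flank, nv$seq),
                   prov = prov_concat(prov_suffix(nu$prov, k - 1L), nv$prov)),
           envir = g$nodes)
  } else {
    flank <- substr(nv$seq, 1L, k - 1L)
    assign(u, list(seq = paste0(nu$seq, flank),
                   prov = prov_concat(nu$prov, prov_prefix(nv$prov, k - 1L))),
           envir = g$nodes)
  }
  g_rm_edge(g, u, v)
  dir
}

#' Haplotype-supported in/out edge pairs of a node
#'
#' A pair of an incoming and an outgoing edge of `u` is *supported* when
#' their haplotype sets intersect, i.e. at least one encoded haplotype
#' actually traverses that in-out combination.  `hap_delta()` counts the
#' supported pairs; it is the number of copies the haplotype-constrained
#' duplicate operation produces for a through-traversed node, and is bounded
#' by the number of haplotypes (each haplotype crosses `u` along exactly one
#' pair).
#'
#' @param g a `population_graph`
#' @param u node id
#' @return `supported_pairs`: a `data.frame` with columns `in_from`,
#'   `out_to`, `haplotypes` (comma-separated shared set), ordered by
#'   (`in_from`, `out_to`).  `hap_delta`: the number of such pairs.
#' @export
supported_pairs <- function(g, u) {
  if (!g_has_node(g, u)) stopf("unknown node '%s'", u)
  preds <- sortc(g_preds(g, u))
  succs <- sortc(g_succs(g, u))
  res <- list()
  for (x in preds) {
    hi <- g_edge_haps(g, x, u)
    for (y in succs) {
      shared <- intersect(hi, g_edge_haps(g, u, y))
      if (length(shared)) {
        res[[length(res) + 1L]] <- data.frame(
          in_from = x, out_to = y, haplotypes = paste(sortc(shared), collapse = ","))
      }
    }
  }
  if (!length(res)) {
    return(data.frame(in_from = character(0L), out_to = character(0L),
                      haplotypes = character(0L)))
  }
  do.call(rbind, res)
}

#' @rdname supported_pairs
#' @export
hap_delta <- function(g, u) nrow(supported_pairs(g, u))

#' Duplicate a node, splitting its edges by haplotype
#'
#' Replaces `u` by one copy per haplotype-supported (in-edge, out-edge)
#' pair; the copy receives that pair's two edges, each carrying exactly the
#' pair's shared haplotype set, and inherits `u`'s sequence and provenance
#' verbatim.  Haplotypes whose path terminates at `u` yield one extra copy
#' per incoming edge that carries them (with that in-edge only), and
#' symmetrically for haplotypes originating at `u`.  Unsupported in-out
#' combinations -- paths no encoded haplotype takes -- are never
#' materialised, which is what bounds the copy count by the number of
#' haplotypes rather than by `in(u) * out(u)`.
#'
#' @param g a `population_graph` (modified in place)
#' @param u node id with at least one incident edge
#' @return character vector of the copy ids created
#' @export
duplicate_node <- function(g, u) {
  if (!g_has_node(g, u)) stopf("unknown node '%s'", u)
  preds <- sortc(g_preds(g, u))
  succs <- sortc(g_succs(g, u))
  if (length(preds) + length(succs) < 1L) stopf("node '%s' has no incident edges", u)

  in_haps <- lapply(stats::setNames(preds, preds), function(x) g_edge_haps(g, x, u))
  out_haps <- lapply(stats::setNames(succs, succs), function(y) g_edge_haps(g, u, y))
  all_in <- unique(unlist(in_haps))
  all_out <- unique(unlist(out_haps))

  copies <- list()  # list of list(in_from=, out_to=, haps=)
  for (x in preds) for (y in succs) {
    shared <- intersect(in_haps[[x]], out_haps[[y]])
    if (length(shared)) copies[[length(copies) + 1L]] <-
      list(in_from = x, out_to = NA_character_, haps = sortc(shared), out = y)
  }
  n_pairs <- length(copies)
  for (x in preds) {  # haplotypes that end at u
    term <- setdiff(in_haps[[x]], all_out)
    if (length(term)) copies[[length(copies) + 1L]] <-
      list(in_from = x, out_to = NA_character_, haps = sortc(term), out = NA_character_)
  }
  for (y in succs) {  # haplotypes that start at u
    orig <- setdiff(out_haps[[y]], all_in)
    if (length(orig)) copies[[length(copies) + 1L]] <-
      list(in_from = NA_character_, out_to = NA_character_, haps = sortc(orig), out = y)
  }
  # haplotypes whose whole tracked path is [u] (degenerate; partial GFA input)
  lone <- Filter(function(h) identical(get(h, envir = g$paths), u), env_keys(g$paths))
  for (h in lone) copies[[length(copies) + 1L]] <-
    list(in_from = NA_character_, out_to = NA_character_, haps = h, out = NA_character_)

  # fresh, collision-free copy ids u.0, u.1, ...
  n <- length(copies)
  start <- 0L
  repeat {
    ids <- sprintf("%s.%d", u, start + seq_len(n) - 1L)
    if (!any(vapply(ids, g_has_node, logical(1L), g = g))) break
    start <- start + n
  }

  node_u <- g_node(g, u)
  g_rm_node(g, u)
  for (i in seq_len(n)) {
    g_add_node(g, ids[[i]], node_u$seq, node_u$prov)
    ci <- copies[[i]]
    if (!is.na(ci$in_from)) g_add_edge(g, ci$in_from, ids[[i]], ci$haps)
    if (!is.na(ci$out)) g_add_edge(g, ids[[i]], ci$out, ci$haps)
  }

  # re-point tracked haplotype paths at the copy that carries them
  for (h in env_keys(g$paths)) {
    p <- get(h, envir = g$paths)
    iu <- match(u, p)
    if (is.na(iu)) next
    xp <- if (iu > 1L) p[[iu - 1L]] else NA_character_
    xs <- if (iu < length(p)) p[[iu + 1L]] else NA_character_
    hit <- which(vapply(seq_len(n), function(i) {
      ci <- copies[[i]]
      h %in% ci$haps && identical(ci$in_from, xp) &&
        identical(if (is.na(ci$out)) NA_character_ else ci$out, xs)
    }, logical(1L)))
    if (length(hit) == 1L) {
      p[[iu]] <- ids[[hit]]
      assign(h, p, envir = g$paths)
    } else {
      drop_path(g, h)  # inconsistent bookkeeping; stop tracking
    }
  }
  ids
}
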