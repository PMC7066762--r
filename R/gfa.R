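#' Read / write haplotype-annotated graphs as GFA1
#'
#' The supported dialect is forward-strand GFA1: `S` lines carry node
#' sequences, `L` lines carry edges and must have a `0M` overlap, and `P`
#' lines name haplotype paths (the path name is the haplotype id; overlaps
#' `*` or `0M` lists are accepted).  Reverse (`-`) orientations are rejected:
#' the model is a directed graph of forward-strand sequences.  Edge haplotype
#' sets are reconstructed from the `P` lines; an `L` line traversed by no
#' path is an error unless `allow_uncovered = TRUE`, in which case it is
#' assigned the synthetic haplotype `"unknown"` so legacy graphs stay
#' loadable.
#'
#' @param path file path
#' @param allow_uncovered admit edges with no covering path (default `FALSE`)
#' @return `read_gfa`: a `population_graph`.  `write_gfa`: the path,
#'   invisibly.
#' @export
read_gfa <- function(path, allow_uncovered = FALSE) {
  check_file(path)
  lines <- readLines(path)
  seqs <- character(0L)
  llines <- list()
  plines <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "H")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    rec <- f[[1L]]
    if (rec == "S") {
      if (length(f) < 3L) stopf("line %d: malformed S line", i)
      if (f[[3L]] == "*") stopf("line %d: S line without stored sequence", i)
      seqs[[f[[2L]]]] <- toupper(f[[3L]])
    } else if (rec == "L") {
      if (length(f) < 6L) stopf("line %d: malformed L line", i)
      if (f[[3L]] != "+" || f[[5L]] != "+") {
        stopf("line %d: reverse-complement orientations not supported", i)
      }
      if (f[[6L]] != "0M") stopf("line %d: only 0M overlaps supported", i)
      llines[[length(llines) + 1L]] <- c(f[[2L]], f[[4L]])
    } else if (rec == "P") {
      if (length(f) < 3L) stopf("line %d: malformed P line", i)
      ov <- if (length(f) >= 4L) f[[4L]] else "*"
      if (!(ov == "*" || all(strsplit(ov, ",", fixed = TRUE)[[1L]] %in% c("0M", "*")))) {
        stopf("line %d: only 0M overlaps supported", i)
      }
      steps <- strsplit(f[[3L]], ",", fixed = TRUE)[[1L]]
      if (any(endsWith(steps, "-"))) {
        stopf("line %d: reverse-complement orientations not supported", i)
      }
      plines[[f[[2L]]]] <- sub("\\+$", "", steps)
    }
  }
  if (length(seqs) == 0L) stopf("no S lines in %s", path)
  for (h in names(plines)) {
    missing <- setdiff(plines[[h]], names(seqs))
    if (length(missing)) {
      stopf("path %s names segment(s) with no S line: %s", h,
            paste(missing, collapse = ","))
    }
  }

  # edges traversed by paths
  pe <- new_env()
  for (h in names(plines)) {
    p <- plines[[h]]
    if (length(p) > 1L) for (j in seq_len(length(p) - 1L)) {
      key <- edge_key(p[j], p[j + 1L])
      cur <- if (exists(key, envir = pe, inherits = FALSE)) get(key, envir = pe) else character(0L)
      assign(key, c(cur, h), envir = pe)
    }
  }
  lkeys <- unique(vapply(llines, function(uv) edge_key(uv[1L], uv[2L]), character(1L)))
  uncovered <- setdiff(lkeys, env_keys(pe))
  extra <- setdiff(env_keys(pe), lkeys)
  if (length(extra)) {
    uv <- edge_unkey(extra[[1L]])
    stopf("path traverses (%s,%s) but no such L line exists", uv[1L], uv[2L])
  }
  edges <- NULL
  if (length(uncovered)) {
    if (!allow_uncovered) {
      uvs <- vapply(uncovered, function(k) {
        uv <- edge_unkey(k); sprintf("(%s,%s)", uv[1L], uv[2L])
      }, character(1L))
      stopf("edge(s) covered by no P line: %s (use allow_uncovered = TRUE to assign 'unknown')",
            paste(uvs, collapse = ", "))
    }
    uv <- matrix(unlist(edge_unkey(uncovered)), ncol = 2L, byrow = TRUE)
    edges <- data.frame(from = uv[, 1L], to = uv[, 2L], haplotypes = "unknown")
  }
  population_graph(seqs, paths = plines, edges = edges)
}

#' @param g a `population_graph` whose haplotype paths are tracked
#' @rdname read_gfa
#' @export
write_gfa <- function(g, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  emit <- function(...) writeLines(paste(..., sep = "\t"), con, sep = "\n")
  emit("H", "VN:Z:1.0")
  for (id in graph_node_ids(g)) emit("S", id, g_node(g, id)$seq)
  keys <- env_keys(g$edges)
  if (length(keys)) {
    uv <- matrix(unlist(edge_unkey(keys)), ncol = 2L, byrow = TRUE)
    for (i in seq_along(keys)) emit("L", uv[i, 1L], "+", uv[i, 2L], "+", "0M")
  }
  for (h in sortc(env_keys(g$paths))) {
    p <- get(h, envir = g$paths)
    emit("P", h, paste0(p, "+", collapse = ","), "*")
  }
  invisible(path)
}
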