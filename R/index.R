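#' Serialize a null graph as an aligner-ready FASTA index
#'
#' One FASTA record per node, sorted by id, 60-column wrapped.  The header
#' carries the node's provenance in the grammar
#' `>{id} {origin}:{start}-{end}(;{origin}:{start}-{end})*` with 0-based
#' half-open intervals; linear aligners ignore everything after the first
#' whitespace, so record ids stay clean reference names while the projection
#' machinery can recover graph coordinates from the description.  Two
#' serializations of the same null graph are byte-identical.
#'
#' @param ng a `null_graph` (no edges)
#' @param path output FASTA path
#' @return number of records written, invisibly
#' @export
write_index_fasta <- function(ng, path) {
  if (!is_null_graph(ng)) stopf("graph still has edges; flatten it first")
  ids <- graph_node_ids(ng)
  if (any(grepl("[[:space:]]", ids))) stopf("node ids must not contain whitespace")
  seqs <- vapply(ids, function(id) g_node(ng, id)$seq, character(1L))
  headers <- vapply(ids, function(id) prov_format(g_node(ng, id)$prov), character(1L))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste(ids, headers)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(length(ids))
}

#' Load a provenance-annotated FASTA index
#'
#' Parses the header grammar written by [write_index_fasta()] and builds the
#' cumulative-offset tables used for coordinate lookup.  A record whose
#' declared provenance lengths do not sum to its sequence length is a
#' corrupt index and raises an error.
#'
#' @param path FASTA produced by [write_index_fasta()]
#' @return a `null_index`: list with `ids`, `len` (named lengths), `seq`
#'   (named sequences), and per-record provenance tables
#' @export
read_index <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  headers <- names(x)
  sp <- regexpr(" ", headers, fixed = TRUE)
  if (length(headers) && any(sp < 0L)) {
    stopf("malformed header (no provenance) in record '%s'",
          headers[which(sp < 0L)[1L]])
  }
  ids <- substr(headers, 1L, sp - 1L)
  desc <- substr(headers, sp + 1L, nchar(headers))
  recs <- vector("list", length(ids))
  names(recs) <- ids
  for (i in seq_along(ids)) {
    segs <- strsplit(desc[[i]], ";", fixed = TRUE)[[1L]]
    m <- regmatches(segs, regexec("^(.+):([0-9]+)-([0-9]+)$", segs))
    bad <- vapply(m, length, integer(1L)) != 4L
    if (any(bad)) stopf("malformed provenance segment '%s' in record %s",
                        segs[bad][1L], ids[[i]])
    origin <- vapply(m, `[[`, character(1L), 2L)
    s <- as.integer(vapply(m, `[[`, character(1L), 3L))
    e <- as.integer(vapply(m, `[[`, character(1L), 4L))
    if (any(e <= s)) stopf("empty provenance interval in record %s", ids[[i]])
    w <- e - s
    slen <- Biostrings::width(x)[[i]]
    if (sum(w) != slen) {
      stopf("provenance length %d != sequence length %d in record %s",
            sum(w), slen, ids[[i]])
    }
    recs[[i]] <- list(origin = origin, start = s, end = e,
                      cum = c(0L, cumsum(w)))  # strictly increasing from 0
  }
  structure(list(ids = ids,
                 len = stats::setNames(Biostrings::width(x), ids),
                 seq = stats::setNames(as.character(x), ids),
                 records = recs),
            class = "null_index")
}

#' @export
print.null_index <- function(x, ...) {
  cat(sprintf("null_index: %d records, %d bp\n", length(x$ids), sum(x$len)))
  invisible(x)
}

#' Trace an index coordinate back to the original graph
#'
#' @param index a `null_index`
#' @param id record (null-graph node) id
#' @param offset 0-based base offset within the record
#' @return list with `origin` (input-graph node id) and `offset` (0-based
#'   offset within that node)
#' @export
locate <- function(index, id, offset) {
  rec <- index$records[[id]]
  if (is.null(rec)) stopf("unknown record '%s'", id)
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L || offset >= index$len[[id]]) {
    stopf("offset %d out of range [0,%d) for record %s", offset, index$len[[id]], id)
  }
  i <- findInterval(offset, rec$cum, rightmost.closed = FALSE)
  list(origin = rec$origin[[i]], offset = rec$start[[i]] + (offset - rec$cum[[i]]))
}
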