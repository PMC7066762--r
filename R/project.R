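# Back-projection of linear alignments (SAM against the null-graph FASTA)
# onto paths through the original population graph.

# reference-consumed length of a CIGAR string (M/D/=/X/N advance the
# reference; I/S/H/P do not)
cigar_ref_len <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cigar)) {
    stopf("malformed CIGAR '%s'", cigar)
  }
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- substr(ops, nchar(ops), nchar(ops))
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Project one alignment onto the original graph
#'
#' Walks the provenance segments of the aligned record across the
#' reference-consumed interval `[pos, pos + reflen)` and emits the ordered
#' path of original-graph nodes together with the entry offset in the first
#' node and the (exclusive) exit offset in the last.  Reverse-strand
#' alignments keep the forward-graph path, with the strand flagged.
#'
#' @param index a `null_index`
#' @param qname read id
#' @param rname aligned-to record id (null-graph node)
#' @param pos 1-based leftmost aligned reference position (SAM POS)
#' @param cigar SAM CIGAR string
#' @param strand `"+"` or `"-"`
#' @param mapq mapping quality
#' @return a `graph_alignment`: list with `qname`, `strand`, `path`
#'   (character vector of original-graph node ids), `entry`, `exit`
#'   (0-based; `exit` exclusive in the last node), `mapq`, `cigar`
#' @export
project_alignment <- function(index, qname, rname, pos, cigar, strand = "+",
                              mapq = 60L) {
  rec <- index$records[[rname]]
  if (is.null(rec)) stopf("reference '%s' not present in the index", rname)
  reflen <- cigar_ref_len(cigar)
  if (reflen < 1L) stopf("alignment of read %s consumes no reference", qname)
  a <- as.integer(pos) - 1L            # 0-based start
  b <- a + reflen                      # exclusive end
  if (a < 0L || b > index$len[[rname]]) {
    stopf("alignment [%d,%d) of read %s overruns record %s (length %d)",
          a, b, qname, rname, index$len[[rname]])
  }
  i <- findInterval(a, rec$cum, rightmost.closed = FALSE)
  j <- findInterval(b - 1L, rec$cum, rightmost.closed = FALSE)
  path <- rec$origin[i:j]
  entry <- rec$start[[i]] + (a - rec$cum[[i]])
  exit <- rec$start[[j]] + (b - rec$cum[[j]])
  structure(list(qname = qname, strand = strand, path = path,
                 entry = entry, exit = exit, mapq = as.integer(mapq),
                 cigar = cigar),
            class = "graph_alignment")
}

#' @export
print.graph_alignment <- function(x, ...) {
  cat(sprintf("%s %s %s entry=%d exit=%d %s\n", x$qname, x$strand,
              paste(x$path, collapse = ","), x$entry, x$exit, x$cigar))
  invisible(x)
}

parse_sam_line <- function(ln, i) {
  f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 11L) stopf("SAM record %d: fewer than 11 fields", i)
  list(qname = f[[1L]], flag = as.integer(f[[2L]]), rname = f[[3L]],
       pos = as.integer(f[[4L]]), mapq = as.integer(f[[5L]]), cigar = f[[6L]])
}

#' Project a SAM file of alignments against the index
#'
#' Primary mapped records are projected one line each; unmapped records and
#' (by default) secondary/supplementary records are skipped and counted,
#' mirroring a primary-alignments-only evaluation.
#'
#' TSV columns: `read_id`, `strand`, `path` (comma-joined node ids),
#' `entry_offset`, `exit_offset`, `mapq`, `cigar`.  GAF output uses the
#' `>node` path syntax with path-space coordinates.
#'
#' @param index a `null_index`
#' @param sam path to a SAM file (plain text)
#' @param out output path
#' @param format `"tsv"` (default) or `"gaf"`
#' @param keep_secondary also project secondary/supplementary records
#' @return counts: list with `projected`, `unmapped_skipped`,
#'   `secondary_skipped`
#' @export
project_sam <- function(index, sam, out, format = c("tsv", "gaf"),
                        keep_secondary = FALSE) {
  format <- match.arg(format)
  check_file(sam)
  lines <- readLines(sam)
  lines <- lines[!startsWith(lines, "@")]
  con <- file(out, open = "wb")
  on.exit(close(con))
  projected <- 0L; unmapped <- 0L; secondary <- 0L
  for (i in seq_along(lines)) {
    if (lines[[i]] == "") next
    r <- parse_sam_line(lines[[i]], i)
    if (bitwAnd(r$flag, 4L) != 0L) { unmapped <- unmapped + 1L; next }
    if (!keep_secondary && bitwAnd(r$flag, 256L + 2048L) != 0L) {
      secondary <- secondary + 1L; next
    }
    strand <- if (bitwAnd(r$flag, 16L) != 0L) "-" else "+"
    ga <- tryCatch(
      project_alignment(index, r$qname, r$rname, r$pos, r$cigar, strand, r$mapq),
      error = function(e) stopf("SAM record %d: %s", i, conditionMessage(e)))
    if (format == "tsv") {
      writeLines(paste(ga$qname, ga$strand, paste(ga$path, collapse = ","),
                       ga$entry, ga$exit, ga$mapq, ga$cigar, sep = "\t"), con)
    } else {
      plen <- ga$exit - ga$entry  # path-space span actually covered
      writeLines(paste(ga$qname, plen, 0L, plen, ga$strand,
                       paste0(">", ga$path, collapse = ""), plen, 0L, plen,
                       plen, plen, ga$mapq, sep = "\t"), con)
    }
    projected <- projected + 1L
  }
  list(projected = projected, unmapped_skipped = unmapped,
       secondary_skipped = secondary)
}

#' Exact-match reads against an index (testing aligner)
#'
#' A deliberately simple stand-in for an external linear aligner, used by
#' the test-suite and the acceptance pipeline: each read is matched exactly
#' (forward strand) against the index sequences; its first occurrence in the
#' first matching record (records scanned in id order) is reported as the
#' primary SAM line.  A read can place exactly at several graph loci (for
#' instance when an inserted allele happens to spell the same bases as the
#' reference it sits next to); with `all_hits = TRUE` every further
#' occurrence is emitted as a secondary (flag 256) record, which is how an
#' aligner would expose the tie.  Reads with no exact occurrence are
#' reported unmapped.
#'
#' @param reads named character vector (names are read ids)
#' @param index a `null_index`
#' @param sam output SAM path
#' @param all_hits also emit secondary records for every further exact
#'   occurrence (default: primary only)
#' @return number of mapped reads, invisibly
#' @export
align_exact <- function(reads, index, sam, all_hits = FALSE) {
  con <- file(sam, open = "wb")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (id in index$ids) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", id, index$len[[id]]), con)
  }
  mapped <- 0L
  for (q in names(reads)) {
    hits <- list()
    for (id in index$ids) {
      ps <- gregexpr(reads[[q]], index$seq[[id]], fixed = TRUE)[[1L]]
      if (ps[[1L]] > 0L) {
        for (p in as.integer(ps)) hits[[length(hits) + 1L]] <- list(id = id, pos = p)
      }
      if (length(hits) && !all_hits) break
    }
    if (!length(hits)) {
      writeLines(paste(q, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, reads[[q]], "*",
                       sep = "\t"), con)
    } else {
      if (!all_hits) hits <- hits[1L]
      for (i in seq_along(hits)) {
        flag <- if (i == 1L) 0L else 256L
        writeLines(paste(q, flag, hits[[i]]$id, hits[[i]]$pos, 60L,
                         sprintf("%dM", nchar(reads[[q]])), "*", 0L, 0L,
                         reads[[q]], "*", sep = "\t"), con)
      }
      mapped <- mapped + 1L
    }
  }
  invisible(mapped)
}
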