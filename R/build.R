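#' Build a population graph from a reference and phased variants
#'
#' Splits the reference at variant breakpoints into backbone nodes, adds one
#' node per distinct *used* alternate allele (deletions become a direct edge
#' skipping reference sequence), and threads one haplotype path per phased
#' chromosome copy: the `REF` haplotype plus `sample#1`/`sample#2` for each
#' diploid sample (haploid samples contribute a single path named after the
#' sample).  Every edge's haplotype set is derived from the paths, so it is
#' non-empty by construction, and alleles carried by no haplotype produce no
#' nodes.
#'
#' Allele normalisation follows the VCF anchor-base convention: one shared
#' leading base between REF and ALT is stripped, so an insertion node carries
#' only the inserted bases.  Backbone node ids are `contig:start-end`
#' (0-based half-open); alternate node ids are `contig:pos:altIndex` (VCF
#' coordinates).
#'
#' @param reference reference sequence: a string, a [Biostrings::DNAString],
#'   or a `DNAStringSet` (with `contig` selecting the entry; defaults to the
#'   first)
#' @param variants a [variant_records] table, position-sorted, whose REF
#'   alleles match `reference`
#' @param samples samples to thread (default: all samples in `variants`)
#' @param on_overlap `"error"` (default) aborts when two records' reference
#'   spans intersect; `"drop"` drops the later record with a message
#' @param contig contig name for node ids (default: the records' `chrom`, or
#'   `"ref"` when there are no records)
#' @return a `population_graph`
#' @export
build_graph <- function(reference, variants = NULL, samples = NULL,
                        on_overlap = c("error", "drop"), contig = NULL) {
  on_overlap <- match.arg(on_overlap)
  if (methods::is(reference, "DNAStringSet")) {
    nm <- if (is.null(contig)) 1L else contig
    if (is.null(contig)) contig <- names(reference)[1L]
    reference <- as.character(reference[[nm]])
  } else {
    reference <- as.character(reference)
  }
  reference <- toupper(reference)
  check_dna(reference, "reference")
  reflen <- nchar(reference)

  if (is.null(variants) || nrow(variants) == 0L) {
    contig <- contig %||% "ref"
    return(population_graph(
      stats::setNames(reference, sprintf("%s:0-%d", contig, reflen)),
      paths = list(REF = sprintf("%s:0-%d", contig, reflen))))
  }
  contig <- contig %||% variants$chrom[[1L]]
  gt <- attr(variants, "gt")
  samples <- samples %||% attr(variants, "samples")
  gt <- gt[, samples, drop = FALSE]

  if (is.unsorted(variants$pos)) stopf("variants must be sorted by position")

  # per-sample ploidy, consistent across records
  ploidy <- vapply(samples, function(s) {
    n <- unique(lengths(lapply(gt[, s], gt_alleles)))
    if (length(n) != 1L) stopf("sample %s mixes ploidies across records", s)
    as.integer(n)
  }, integer(1L))
  if (any(!ploidy %in% 1:2)) stopf("only haploid or diploid genotypes supported")

  haps <- c("REF", unlist(lapply(samples, function(s)
    if (ploidy[[s]] == 2L) paste0(s, "#", 1:2) else s)))

  # normalise each (record, alt) into a 0-based half-open ref span + insert
  nrec <- nrow(variants)
  spans <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    pos <- variants$pos[[i]]
    ref <- variants$ref[[i]]
    if (pos < 1L || pos + nchar(ref) - 1L > reflen) {
      stopf("variant at pos %d out of reference bounds", pos)
    }
    if (substr(reference, pos, pos + nchar(ref) - 1L) != ref) {
      stopf("REF allele mismatch at pos %d: VCF says '%s', reference has '%s'",
            pos, ref, substr(reference, pos, pos + nchar(ref) - 1L))
    }
    spans[[i]] <- lapply(variants$alt[[i]], function(a) {
      s <- pos - 1L; r <- ref
      if (nchar(r) > 0L && nchar(a) > 0L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
        s <- s + 1L; r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
      }
      list(s = s, e = s + nchar(r), ins = a)
    })
  }

  # record-level reference footprints; reject or drop overlaps
  rs <- variants$pos - 1L
  re <- rs + nchar(variants$ref)
  keep <- rep(TRUE, nrec)
  hi <- re[1L]
  if (nrec > 1L) for (i in 2:nrec) {
    if (rs[[i]] < hi) {
      if (on_overlap == "error") {
        stopf("overlapping variant records at pos %d and pos %d",
              variants$pos[[i - 1L]], variants$pos[[i]])
      }
      message(sprintf("dropping overlapping variant record at pos %d", variants$pos[[i]]))
      keep[[i]] <- FALSE
    } else hi <- max(hi, re[[i]])
  }

  # haplotype -> chosen (record index, alt index); hom-ref everywhere uses none
  hap_alleles <- lapply(stats::setNames(haps, haps), function(h) integer(0L))
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    al <- lapply(gt[, s], gt_alleles)
    for (c_i in seq_len(ploidy[[s]])) {
      h <- if (ploidy[[s]] == 2L) paste0(s, "#", c_i) else s
      picks <- vapply(al, `[[`, integer(1L), c_i)
      idx <- which(keep & picks > 0L)
      hap_alleles[[h]] <- as.numeric(idx) * 10000 + picks[idx]
    }
  }
  # encoded choice: record = x %/% 10000, alt index = x %% 10000
  if (any(lengths(variants$alt) >= 10000L)) stopf("too many alternate alleles")

  used <- unique(unlist(hap_alleles))
  used_by_rec <- split(as.integer(used %% 10000), as.integer(used %/% 10000))

  # breakpoints from used alt spans only
  bp <- c(0L, reflen)
  for (ri in as.integer(names(used_by_rec))) {
    for (ai in used_by_rec[[as.character(ri)]]) {
      sp <- spans[[ri]][[ai]]
      bp <- c(bp, sp$s, sp$e)
    }
  }
  bp <- sort(unique(as.integer(bp)))
  bs <- bp[-length(bp)]
  be <- bp[-1L]
  nonempty <- be > bs
  bs <- bs[nonempty]; be <- be[nonempty]
  backbone_id <- sprintf("%s:%d-%d", contig, bs, be)
  backbone_seq <- substring(reference, bs + 1L, be)

  nodes <- stats::setNames(backbone_seq, backbone_id)
  alt_id <- function(ri, ai) sprintf("%s:%d:%d", contig, variants$pos[[ri]], ai)
  for (ri in as.integer(names(used_by_rec))) {
    for (ai in used_by_rec[[as.character(ri)]]) {
      sp <- spans[[ri]][[ai]]
      if (nchar(sp$ins) > 0L) nodes[[alt_id(ri, ai)]] <- sp$ins
    }
  }

  # walk each haplotype: backbone between variant spans, alt nodes inside
  backbone_between <- function(from, to) backbone_id[bs >= from & be <= to]
  paths <- lapply(hap_alleles, function(choice) {
    p <- character(0L)
    cur <- 0L
    for (x in choice) {
      ri <- as.integer(x %/% 10000); ai <- as.integer(x %% 10000)
      sp <- spans[[ri]][[ai]]
      p <- c(p, backbone_between(cur, sp$s))
      if (nchar(sp$ins) > 0L) p <- c(p, alt_id(ri, ai))
      cur <- sp$e
    }
    c(p, backbone_between(cur, reflen))
  })
  paths[["REF"]] <- backbone_id

  population_graph(nodes, paths = paths)
}
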