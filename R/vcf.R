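#' Variant record tables
#'
#' Variants are held in a plain `data.frame` with columns `chrom`, `pos`
#' (1-based reference position of the VCF record), `ref`, and a list-column
#' `alt` of alternate alleles, plus two attributes: `samples` (sample names)
#' and `gt`, a records x samples character matrix of genotype strings
#' (`"0|1"` for phased diploids, `"1"` for haploids).
#'
#' @param chrom,pos,ref vectors describing each record
#' @param alt list of character vectors (one per record)
#' @param gt character matrix, records x samples
#' @param samples sample names (column names of `gt`)
#' @return a `data.frame` of class `variant_records`
#' @export
variant_records <- function(chrom, pos, ref, alt, gt, samples) {
  n <- length(pos)
  gt <- matrix(as.character(gt), nrow = n, dimnames = list(NULL, samples))
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)))
  df$alt <- lapply(alt, toupper)
  check_dna(df$ref, "REF allele")
  check_dna(unlist(df$alt), "ALT allele")
  attr(df, "gt") <- gt
  attr(df, "samples") <- samples
  class(df) <- c("variant_records", class(df))
  df
}

# genotype strings must be phased ("|") unless homozygous or haploid
check_genotype <- function(gt, sample, pos) {
  if (grepl("/", gt, fixed = TRUE)) {
    al <- strsplit(gt, "/", fixed = TRUE)[[1L]]
    if (length(al) != 2L || al[1L] != al[2L]) {
      stopf("unphased genotype '%s' for sample %s at pos %d", gt, sample, pos)
    }
  }
}

# "0|1" -> c(0L, 1L); "1" -> 1L; missing alleles count as reference
gt_alleles <- function(gt) {
  al <- strsplit(gt, "[|/]")[[1L]]
  al[al == "."] <- "0"
  as.integer(al)
}

#' Parse a (possibly gzipped) VCF file
#'
#' Supports the dialect this package builds graphs from: single-allele or
#' multi-allelic SNP/indel records with per-sample `GT` genotypes.  Phasing
#' is required for heterozygous diploid genotypes; unphased homozygotes are
#' accepted and treated as phased.  Symbolic alleles (`<...>`) and breakends
#' are skipped; the number skipped is recorded in the `"skipped_symbolic"`
#' attribute of the result.  Missing genotypes (`.`) are read as reference.
#'
#' @param path VCF file (plain text or gzip/bgzip)
#' @param region optional `"chrom"` or `"chrom:start-end"` (1-based,
#'   inclusive) filter
#' @return a [variant_records] table, ordered by position
#' @export
parse_vcf <- function(path, region = NULL) {
  check_file(path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L) stopf("no #CHROM header line in %s", path)
  cols <- strsplit(lines[[hdr]], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) stopf("VCF has no sample columns")
  samples <- cols[10:length(cols)]

  rchrom <- rstart <- rend <- NULL
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1L]]
    if (length(m) == 0L) stopf("malformed region '%s'", region)
    rchrom <- m[[2L]]
    if (m[[4L]] != "") { rstart <- as.integer(m[[4L]]); rend <- as.integer(m[[5L]]) }
  }

  chrom <- character(0L); pos <- integer(0L); ref <- character(0L)
  alt <- list(); gts <- list()
  skipped <- 0L
  for (i in seq((hdr + 1L), length.out = length(lines) - hdr)) {
    ln <- lines[[i]]
    if (ln == "") next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L + length(samples)) stopf("line %d: truncated VCF record", i)
    p <- suppressWarnings(as.integer(f[[2L]]))
    if (is.na(p)) stopf("line %d: non-numeric POS '%s'", i, f[[2L]])
    if (!is.null(rchrom)) {
      if (f[[1L]] != rchrom) next
      if (!is.null(rstart) && (p < rstart || p > rend)) next
    }
    alts <- strsplit(f[[5L]], ",", fixed = TRUE)[[1L]]
    if (any(grepl("[][<>]", alts)) || any(alts == "*")) {
      skipped <- skipped + 1L
      next
    }
    fmt <- strsplit(f[[9L]], ":", fixed = TRUE)[[1L]]
    gti <- match("GT", fmt)
    if (is.na(gti)) stopf("line %d: no GT in FORMAT", i)
    sgt <- vapply(f[10:(9L + length(samples))], function(s)
      strsplit(s, ":", fixed = TRUE)[[1L]][[gti]], character(1L), USE.NAMES = FALSE)
    for (j in seq_along(samples)) check_genotype(sgt[[j]], samples[[j]], p)
    sgt <- gsub("/", "|", sgt, fixed = TRUE)
    chrom <- c(chrom, f[[1L]]); pos <- c(pos, p); ref <- c(ref, f[[4L]])
    alt[[length(alt) + 1L]] <- alts
    gts[[length(gts) + 1L]] <- sgt
  }
  ord <- order(pos)
  gtm <- if (length(gts)) do.call(rbind, gts) else matrix(character(0L), 0L, length(samples))
  v <- variant_records(chrom[ord], pos[ord], ref[ord], alt[ord],
                       gtm[ord, , drop = FALSE], samples)
  attr(v, "skipped_symbolic") <- skipped
  v
}
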