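#' Simulation configuration
#'
#' Describes a simulated population in which every sample contributes a
#' fixed number of variants to the graph and a stated fraction of each
#' sample's variation is drawn from a pool shared with other samples (the
#' rest being unique to the sample), with diploid phasing.  Defaults are the
#' desk-scale population used throughout the test-suite: 5 diploid samples,
#' 20 variants each, a 2 kb reference and a 20% sharing probability.
#'
#' @param ref_len reference length, bp
#' @param n_samples number of samples
#' @param variants_per_sample variants contributed by each sample
#' @param share_p probability that a sample's variant is drawn from the
#'   shared pool rather than created unique to the sample, in `[0,1]`
#' @param snp_frac fraction of created variants that are SNPs (the rest are
#'   indels, insertion or deletion with equal probability)
#' @param max_indel maximum indel length, bp; also sets the inter-site
#'   spacing that keeps records non-overlapping
#' @param ploidy 1 or 2
#' @param seed RNG seed (integer)
#' @param read_len read length for [sample_reads()], bp; keep at or below
#'   the `k` the graph will be flattened with
#' @param reads_per_hap reads sampled per haplotype
#' @return a `sim_config` list
#' @export
sim_config <- function(ref_len = 2000L, n_samples = 5L,
                       variants_per_sample = 20L, share_p = 0.2,
                       snp_frac = 0.9, max_indel = 6L, ploidy = 2L,
                       seed = 1L, read_len = 100L, reads_per_hap = 10L) {
  cfg <- list(ref_len = as.integer(ref_len), n_samples = as.integer(n_samples),
              variants_per_sample = as.integer(variants_per_sample),
              share_p = share_p, snp_frac = snp_frac,
              max_indel = as.integer(max_indel), ploidy = as.integer(ploidy),
              seed = as.integer(seed), read_len = as.integer(read_len),
              reads_per_hap = as.integer(reads_per_hap))
  stopifnot(cfg$ref_len >= 10L, cfg$n_samples >= 1L,
            cfg$variants_per_sample >= 1L,
            cfg$share_p >= 0, cfg$share_p <= 1,
            cfg$snp_frac >= 0, cfg$snp_frac <= 1,
            cfg$max_indel >= 1L, cfg$ploidy %in% 1:2,
            cfg$read_len >= 1L, cfg$reads_per_hap >= 1L)
  class(cfg) <- "sim_config"
  cfg
}

# apply (pos, ref, alt) edits to a reference string, right-to-left; this is
# the independent string-editing oracle the graph builder is tested against
apply_variants_string <- function(reference, pos, ref, alt) {
  ord <- order(pos, decreasing = TRUE)
  s <- reference
  for (i in ord) {
    s <- paste0(substr(s, 1L, pos[[i]] - 1L), alt[[i]],
                substr(s, pos[[i]] + nchar(ref[[i]]), nchar(s)))
  }
  s
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulate a phased population
#'
#' Draws `variants_per_sample` variants per sample; with probability
#' `share_p` a draw comes from a shared pool (growing it half of the time,
#' reusing an existing entry otherwise), else it is unique to the sample.
#' Variant sites sit on a lattice with `max_indel + 2` spacing so records
#' never overlap.  Truth haplotype strings are produced by direct string
#' editing of the reference -- independently of any graph code -- and genome
#' files are written when `dir` is given.
#'
#' @param cfg a [sim_config]
#' @param dir if non-`NULL`, write `ref.fa` and `variants.vcf` here
#' @return list with `reference` (string), `contig`, `variants` (a
#'   [variant_records]), `truth` (named character: haplotype id ->
#'   spelling), `share_flags` (logical, one per draw, `TRUE` when the draw
#'   used the shared pool), `samples`, and -- when `dir` is given --
#'   `fasta`, `vcf` file paths
#' @export
simulate_population <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  contig <- "sim"
  reference <- rand_dna(cfg$ref_len)
  spacing <- cfg$max_indel + 2L
  sites <- seq(2L, cfg$ref_len - cfg$max_indel - 1L, by = spacing)
  max_needed <- cfg$n_samples * cfg$variants_per_sample
  if (length(sites) < max_needed) {
    stopf("infeasible config: %d variant sites available, up to %d needed",
          length(sites), max_needed)
  }
  sites <- sample(sites)  # consumed in random order as variants are created
  next_site <- 0L

  samples <- sprintf("s%02d", seq_len(cfg$n_samples))
  pool <- integer(0L)     # indices into the variant list, shared entries only
  vpos <- integer(0L); vref <- character(0L); valt <- character(0L)
  carriers <- list()      # per variant: named character of sample -> gt
  share_flags <- logical(0L)

  new_variant <- function() {
    next_site <<- next_site + 1L
    p <- sites[[next_site]]
    rb <- substr(reference, p, p)
    if (stats::runif(1L) < cfg$snp_frac) {
      ref_a <- rb
      alt_a <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
    } else if (stats::runif(1L) < 0.5) {  # insertion after anchor base
      ref_a <- rb
      alt_a <- paste0(rb, rand_dna(sample.int(cfg$max_indel, 1L)))
    } else {                              # deletion after anchor base
      len <- sample.int(cfg$max_indel, 1L)
      ref_a <- substr(reference, p, p + len)
      alt_a <- rb
    }
    vpos <<- c(vpos, p); vref <<- c(vref, ref_a); valt <<- c(valt, alt_a)
    carriers[[length(vpos)]] <<- character(0L)
    length(vpos)
  }
  rand_gt <- function() {
    if (cfg$ploidy == 1L) "1"
    else sample(c("1|0", "0|1", "1|1"), 1L, prob = c(0.4, 0.4, 0.2))
  }

  for (s in samples) {
    for (d in seq_len(cfg$variants_per_sample)) {
      shared <- stats::runif(1L) < cfg$share_p
      share_flags <- c(share_flags, shared)
      if (shared) {
        avail <- pool[!vapply(pool, function(i) s %in% names(carriers[[i]]),
                              logical(1L))]
        if (length(avail) && stats::runif(1L) >= 0.5) {
          vi <- if (length(avail) == 1L) avail else sample(avail, 1L)
        } else {
          vi <- new_variant()
          pool <- c(pool, vi)
        }
      } else {
        vi <- new_variant()
      }
      carriers[[vi]][[s]] <- rand_gt()
    }
  }

  hom_ref <- if (cfg$ploidy == 2L) "0|0" else "0"
  gt <- matrix(hom_ref, nrow = length(vpos), ncol = length(samples),
               dimnames = list(NULL, samples))
  for (i in seq_along(carriers)) {
    for (s in names(carriers[[i]])) gt[i, s] <- carriers[[i]][[s]]
  }
  ord <- order(vpos)
  variants <- variant_records(rep(contig, length(vpos))[ord], vpos[ord],
                              vref[ord], as.list(valt[ord]),
                              gt[ord, , drop = FALSE], samples)

  # truth spellings by string editing
  haps <- c("REF", unlist(lapply(samples, function(s)
    if (cfg$ploidy == 2L) paste0(s, "#", 1:2) else s)))
  truth <- vapply(haps, function(h) {
    if (h == "REF") return(reference)
    s <- sub("#[12]$", "", h)
    copy <- if (cfg$ploidy == 2L) as.integer(sub("^.*#", "", h)) else 1L
    use <- vapply(seq_len(nrow(variants)), function(i)
      gt_alleles(attr(variants, "gt")[i, s])[[copy]] > 0L, logical(1L))
    apply_variants_string(reference, variants$pos[use], variants$ref[use],
                          unlist(lapply(variants$alt[use], `[[`, 1L)))
  }, character(1L))

  out <- list(reference = reference, contig = contig, variants = variants,
              truth = truth, share_flags = share_flags, samples = samples)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, "ref.fa")
    x <- Biostrings::DNAStringSet(reference)
    names(x) <- contig
    Biostrings::writeXStringSet(x, fasta, width = 60L)
    vcf <- file.path(dir, "variants.vcf")
    write_vcf(variants, vcf, contig_len = cfg$ref_len)
    out$fasta <- fasta
    out$vcf <- vcf
  }
  out
}

# minimal phased-GT VCF writer for simulated populations
write_vcf <- function(variants, path, contig_len) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  gt <- attr(variants, "gt")
  samples <- attr(variants, "samples")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", variants$chrom[1L], contig_len),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (i in seq_len(nrow(variants))) {
    writeLines(paste(c(variants$chrom[[i]], variants$pos[[i]], ".",
                       variants$ref[[i]],
                       paste(variants$alt[[i]], collapse = ","), ".", "PASS",
                       ".", "GT", gt[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Truth graph coordinates of a haplotype substring
#'
#' Maps a 0-based interval of a haplotype's spelled sequence onto the
#' haplotype's node path: the sub-path covered plus entry/exit offsets.
#' This is what a correct back-projection of an error-free read must
#' reproduce.
#'
#' @param g a `population_graph` with the haplotype's path tracked
#' @param hap haplotype id
#' @param start 0-based start in the spelled haplotype
#' @param len interval length, bp
#' @return list with `path`, `entry`, `exit` (exit exclusive, in the last
#'   node)
#' @export
truth_path <- function(g, hap, start, len) {
  p <- haplotype_path(g, hap)
  if (is.null(p)) stopf("path for haplotype '%s' is not tracked", hap)
  w <- vapply(p, function(id) nchar(g_node(g, id)$seq), integer(1L))
  cum <- c(0L, cumsum(w))
  if (start < 0L || start + len > cum[[length(cum)]]) {
    stopf("interval [%d,%d) outside haplotype %s (length %d)",
          start, start + len, hap, cum[[length(cum)]])
  }
  i <- findInterval(start, cum, rightmost.closed = FALSE)
  j <- findInterval(start + len - 1L, cum, rightmost.closed = FALSE)
  list(path = p[i:j], entry = start - cum[[i]],
       exit = start + len - cum[[j]])
}

#' Sample error-free truth reads from simulated haplotypes
#'
#' Error-free substrings of the truth haplotype strings with recorded
#' coordinates in string space and -- when the built graph is supplied --
#' in graph-path space.
#'
#' @param sim result of [simulate_population()]
#' @param cfg the [sim_config] used (supplies `read_len`, `reads_per_hap`,
#'   and the read-sampling seed `seed + 1`)
#' @param graph optional `population_graph` built from the same population,
#'   used to attach truth paths
#' @param fastq optional path; when given, reads are written as FASTQ
#' @return list with `reads` (named character) and `truth` (`data.frame`:
#'   `read_id`, `hap`, `start`, and with a graph also `path`, `entry`,
#'   `exit`)
#' @export
sample_reads <- function(sim, cfg, graph = NULL, fastq = NULL) {
  set.seed(cfg$seed + 1L)
  reads <- character(0L)
  rows <- list()
  for (h in names(sim$truth)) {
    s <- sim$truth[[h]]
    if (nchar(s) < cfg$read_len) {
      stopf("haplotype %s (length %d) shorter than read length %d",
            h, nchar(s), cfg$read_len)
    }
    starts <- sample.int(nchar(s) - cfg$read_len + 1L, cfg$reads_per_hap,
                         replace = TRUE) - 1L
    for (ri in seq_along(starts)) {
      id <- sprintf("%s_r%03d", gsub("#", "c", h, fixed = TRUE), ri)
      reads[[id]] <- substr(s, starts[[ri]] + 1L, starts[[ri]] + cfg$read_len)
      row <- data.frame(read_id = id, hap = h, start = starts[[ri]])
      if (!is.null(graph)) {
        tp <- truth_path(graph, h, starts[[ri]], cfg$read_len)
        row$path <- paste(tp$path, collapse = ",")
        row$entry <- tp$entry
        row$exit <- tp$exit
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!is.null(fastq)) {
    con <- file(fastq, open = "wb")
    on.exit(close(con))
    for (id in names(reads)) {
      writeLines(c(paste0("@", id), reads[[id]], "+",
                   strrep("I", nchar(reads[[id]]))), con)
    }
  }
  list(reads = reads, truth = do.call(rbind, rows))
}
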