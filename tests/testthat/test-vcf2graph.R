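sample_gt <- function(...) {
  gts <- c(...)
  matrix(gts, nrow = length(gts), dimnames = list(NULL, "s"))
}

test_that("a single SNP splits the reference into the expected subgraph", {
  v <- variant_records("c", 3L, "G", list("C"), sample_gt("1|0"), "s")
  g <- build_graph("ACGTA", v)
  expect_identical(node_seq_map(g),
                   c(`c:0-2` = "AC", `c:2-3` = "G", `c:3-5` = "TA", `c:3:1` = "C"))
  e <- graph_edges(g)
  expect_identical(e$haplotypes[e$from == "c:0-2" & e$to == "c:2-3"], "REF,s#2")
  expect_identical(e$haplotypes[e$from == "c:0-2" & e$to == "c:3:1"], "s#1")
  expect_identical(e$haplotypes[e$from == "c:3:1" & e$to == "c:3-5"], "s#1")
  expect_valid(g)
})

test_that("deletions become skipping edges; insertions carry only inserted bases", {
  v <- variant_records("c", 2L, "CG", list("C"), sample_gt("1|1"), "s")
  g <- build_graph("ACGTA", v)
  expect_identical(spell_haplotype(g, "s#1"), "ACTA")
  expect_identical(spell_haplotype(g, "s#2"), "ACTA")
  expect_identical(spell_haplotype(g, "REF"), "ACGTA")

  vi <- variant_records("c", 2L, "C", list("CTT"), sample_gt("0|1"), "s")
  gi <- build_graph("ACGTA", vi)
  expect_identical(node_seq(gi, "c:2:1"), "TT")  # anchor base stripped
  expect_identical(spell_haplotype(gi, "s#2"), "ACTTGTA")
})

test_that("multi-allelic records route haplotypes by allele index", {
  v <- variant_records("c", 3L, "G", list(c("C", "T")),
                       matrix(c("1|2", "0|2"), nrow = 1,
                              dimnames = list(NULL, c("sa", "sb"))),
                       c("sa", "sb"))
  g <- build_graph("ACGTA", v)
  expect_identical(spell_haplotype(g, "sa#1"), "ACCTA")
  expect_identical(spell_haplotype(g, "sa#2"), "ACTTA")
  expect_identical(spell_haplotype(g, "sb#1"), "ACGTA")
  expect_identical(spell_haplotype(g, "sb#2"), "ACTTA")
  expect_valid(g)
})

test_that("unused alleles and hom-ref samples leave no trace", {
  # allele 2 never carried: no node for it
  v <- variant_records("c", 3L, "G", list(c("C", "T")), sample_gt("1|1"), "s")
  g <- build_graph("ACGTA", v)
  expect_false("c:3:2" %in% graph_node_ids(g))

  # an everywhere-hom-ref sample contributes paths identical to REF
  v2 <- variant_records("c", 3L, "G", list("C"),
                        matrix(c("1|1", "0|0"), nrow = 1,
                               dimnames = list(NULL, c("sa", "sb"))),
                        c("sa", "sb"))
  g2 <- build_graph("ACGTA", v2)
  expect_identical(spell_haplotype(g2, "sb#1"), "ACGTA")
  ref_only <- build_graph("ACGTA", NULL)
  expect_identical(length(graph_node_ids(ref_only)), 1L)
})

test_that("error conditions: ref mismatch, overlap, bounds", {
  v <- variant_records("c", 3L, "T", list("C"), sample_gt("1|0"), "s")
  expect_error(build_graph("ACGTA", v), "mismatch at pos 3")

  v2 <- variant_records("c", c(2L, 3L), c("CG", "G"), list("C", "A"),
                        sample_gt("1|0", "0|1"), "s")
  expect_error(build_graph("ACGTA", v2), "overlapping .* pos 2 and pos 3")
  expect_message(g <- build_graph("ACGTA", v2, on_overlap = "drop"), "dropping")
  expect_identical(spell_haplotype(g, "s#1"), "ACTA")

  v3 <- variant_records("c", 5L, "AG", list("A"), sample_gt("1|0"), "s")
  expect_error(build_graph("ACGTA", v3), "bounds")
})

test_that("adjacent variants link alt nodes directly, no empty backbone", {
  v <- variant_records("c", c(2L, 3L), c("C", "G"), list("A", "T"),
                       sample_gt("1|1", "1|1"), "s")
  g <- build_graph("ACGTA", v)
  expect_true(all(nchar(node_seq_map(g)) >= 1L))
  expect_true(hapflat:::g_has_edge(g, "c:2:1", "c:3:1"))
  expect_identical(spell_haplotype(g, "s#1"), "AATTA")
  expect_valid(g)
})

test_that("haploid genotypes give one path per sample", {
  v <- variant_records("c", 3L, "G", list("C"),
                       matrix("1", 1, 1, dimnames = list(NULL, "mtb1")), "mtb1")
  g <- build_graph("ACGTA", v)
  expect_setequal(graph_haplotypes(g), c("REF", "mtb1"))
  expect_identical(spell_haplotype(g, "mtb1"), "ACCTA")
})

test_that("spelling fidelity holds against the string-editing oracle on random populations", {
  for (seed in c(101L, 202L)) {
    pop <- make_population(seed, n_samples = 4L, variants_per_sample = 12L,
                           ref_len = 1500L)
    for (h in names(pop$sim$truth)) {
      expect_identical(spell_haplotype(pop$g, h), unname(pop$sim$truth[[h]]),
                       label = sprintf("seed %d hap %s", seed, h))
    }
    expect_valid(pop$g)
    # size sanity: connected DAG spanning one contig
    e <- graph_edges(pop$g)
    expect_gte(nrow(e), length(graph_node_ids(pop$g)) - 1L)
  }
})

test_that("parse_vcf handles the dialect and rejects unphased heterozygotes", {
  f <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=c,length=5>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts")

  writeLines(c(hdr, "c\t3\t.\tG\tC\t.\tPASS\t.\tGT\t1|0"), f)
  v <- parse_vcf(f)
  expect_identical(nrow(v), 1L)
  expect_identical(v$pos, 3L)
  expect_identical(unname(attr(v, "gt")[1, "s"]), "1|0")

  writeLines(c(hdr, "c\t3\t.\tG\t<INS>\t.\tPASS\t.\tGT\t1|0",
               "c\t4\t.\tT\tA\t.\tPASS\t.\tGT\t0|1"), f)
  v2 <- parse_vcf(f)
  expect_identical(attr(v2, "skipped_symbolic"), 1L)
  expect_identical(nrow(v2), 1L)

  writeLines(c(hdr, "c\t3\t.\tG\tC\t.\tPASS\t.\tGT\t0/1"), f)
  expect_error(parse_vcf(f), "unphased genotype '0/1' for sample s at pos 3")

  # unphased homozygote is tolerated
  writeLines(c(hdr, "c\t3\t.\tG\tC\t.\tPASS\t.\tGT\t1/1"), f)
  expect_identical(unname(attr(parse_vcf(f), "gt")[1, "s"]), "1|1")

  writeLines(c(hdr, "c\t3\t.\tG\tC\t.\tPASS\t."), f)
  expect_error(parse_vcf(f), "line 5")
})

test_that("simulator VCF files round trip through parse_vcf", {
  cfg <- sim_config(seed = 5L, n_samples = 3L, variants_per_sample = 10L,
                    ref_len = 1000L)
  dir <- withr::local_tempdir()
  sim <- simulate_population(cfg, dir = dir)
  v <- parse_vcf(sim$vcf)
  expect_identical(v$pos, sim$variants$pos)
  expect_identical(v$ref, sim$variants$ref)
  expect_identical(attr(v, "gt"), attr(sim$variants, "gt"))
  g <- build_graph(Biostrings::readDNAStringSet(sim$fasta), v)
  for (h in names(sim$truth)) {
    expect_identical(spell_haplotype(g, h), unname(sim$truth[[h]]))
  }
})
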