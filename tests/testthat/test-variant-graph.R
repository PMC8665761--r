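# Variant graph construction, aligned positions, haplotype paths and the
# reference-guided MSA.

test_that("graph node set and alternative edges match hand enumeration", {
  tg <- table1_graph()
  g <- tg$graph
  expect_equal(g$nodes, c(1L, 2L, 4L, 5L, 6L, 7L, 12L, 16L, 17L, 18L, 19L))
  alt <- g$edges[g$edges$kind == "alternative", ]
  expect_equal(
    paste(alt$from, alt$to, alt$label),
    c("1 2 TAA", "4 7 AAAAAA", "5 6 CC", "12 17 T", "16 18 A", "16 18 T"))
  ## reference edges concatenate to the reference
  re <- g$edges[g$edges$kind == "reference", ]
  expect_equal(paste(re$label, collapse = ""), tg$fixture$reference)
  ## node count bound: at most 2v + 2
  expect_lte(length(g$nodes), 2L * length(tg$fixture$variants$pos) + 2L)
})

test_that("duplicate alternative edges are merged, not duplicated", {
  ref <- "ACGTACGT"
  geno <- matrix(c(1L, 0L, 0L, 1L), nrow = 2L,
                 dimnames = list(NULL, c("h1", "h2")))
  vs <- variant_set(c(2L, 2L), c("x", "y"), c("C", "C"),
                    list("T", "T"), geno, ref)
  g <- build_variant_graph(ref, vs)
  alt <- g$edges[g$edges$kind == "alternative", ]
  expect_equal(nrow(alt), 1L)
  expect_equal(haplotype_sequence(g, "h1"), "ATGTACGT")
  expect_equal(haplotype_sequence(g, "h2"), "ATGTACGT")
})

test_that("degenerate graphs: no variants, single SNP", {
  ref <- "ACGT"
  empty <- variant_set(integer(0), character(0), character(0), list(),
                       matrix(integer(0), 0, 1,
                              dimnames = list(NULL, "h1")), ref)
  g0 <- build_variant_graph(ref, empty)
  expect_equal(g0$nodes, c(1L, 5L))
  expect_equal(g0$edges$label, "ACGT")
  expect_equal(unname(g0$aligned_pos[["5"]]), 5L)
  expect_equal(msa_width(g0), 4L)

  vs <- variant_set(2L, "s", "C", list("A"),
                    matrix(1L, 1, 1, dimnames = list(NULL, "h1")), ref)
  g1 <- build_variant_graph(ref, vs)
  expect_equal(g1$nodes, c(1L, 2L, 3L, 5L))
  alt <- g1$edges[g1$edges$kind == "alternative", ]
  expect_equal(c(alt$from, alt$to), c(2L, 3L))
})

test_that("aligned positions equal the frozen worked-example values and the
           exhaustive longest-path oracle", {
  tg <- table1_graph()
  ap <- aligned_positions(tg$graph)
  expect_equal(
    ap,
    setNames(c(1L, 4L, 6L, 7L, 9L, 12L, 17L, 21L, 22L, 23L, 24L),
             c("1", "2", "4", "5", "6", "7", "12", "16", "17", "18", "19")))
  expect_equal(msa_width(tg$graph), 23L)
  expect_equal(ap, oracle_aligned_positions(tg$graph))
})

test_that("aligned positions match exhaustive enumeration on random graphs", {
  for (seed in 1:8) {
    ref <- random_reference(60L, seed)
    vs <- random_variant_set(ref, 6L, seed + 100L)
    g <- build_variant_graph(ref, vs)
    expect_equal(aligned_positions(g), oracle_aligned_positions(g),
                 info = paste("seed", seed))
  }
  ## single insertion of k bases widens the MSA by exactly k
  ref <- "ACGTACGT"
  vs <- variant_set(3L, "i", "G", list("GTTTT"),
                    matrix(1L, 1, 1, dimnames = list(NULL, "h1")), ref)
  g <- build_variant_graph(ref, vs)
  expect_equal(msa_width(g), nchar(ref) + 4L)
})

test_that("haplotype sequences equal direct variant application", {
  tg <- table1_graph()
  expect_equal(haplotype_sequence(tg$graph, "s1"), "TTCAAAAAAGAGGCAGTTACC")
  expect_equal(haplotype_sequence(tg$graph, "s4"), "TAATCTCCGGAGGCTCC")
  expect_equal(haplotype_sequence(tg$graph, "REF"), tg$fixture$reference)
  for (seed in 1:10) {
    ref <- random_reference(120L, seed + 20L)
    vs <- random_variant_set(ref, 12L, seed + 300L)
    g <- build_variant_graph(ref, vs)
    for (h in vs$labels) {
      expect_equal(haplotype_sequence(g, h), oracle_splice(ref, vs, h),
                   info = paste("seed", seed, "hap", h))
    }
  }
})

test_that("MSA rows are equal width and ungap to the haplotype sequences", {
  tg <- table1_graph()
  msa <- emit_msa(tg$graph)
  expect_equal(msa$width, 23L)
  expect_true(all(nchar(msa$rows) == 23L))
  expect_equal(unname(msa$rows[["REF"]]), "T--TCTG-G--GAGGCAGTTACC")
  expect_equal(unname(msa$rows[["s3"]]), "TAATCTCCG--GAGGCAGTTA-C")
  expect_equal(ungap(msa$rows[["REF"]]), tg$fixture$reference)
  for (seed in 1:6) {
    ref <- random_reference(100L, seed + 40L)
    vs <- random_variant_set(ref, 10L, seed + 500L)
    g <- build_variant_graph(ref, vs)
    msa <- emit_msa(g)
    expect_equal(length(unique(nchar(msa$rows))), 1L)
    for (h in vs$labels)
      expect_equal(ungap(msa$rows[[h]]), oracle_splice(ref, vs, h))
    expect_equal(ungap(msa$rows[["REF"]]), ref)
  }
  ## no variants: single-row MSA equal to the reference, no gaps
  ref <- "ACGTAC"
  empty <- variant_set(integer(0), character(0), character(0), list(),
                       matrix(integer(0), 0, 0), ref)
  msa0 <- emit_msa(build_variant_graph(ref, empty), haplotypes = character(0))
  expect_equal(unname(msa0$rows), ref)
})

test_that("overlapping variants on one haplotype error, or drop with a flag", {
  ref <- "ACGTACGT"
  geno <- matrix(c(1L, 1L), nrow = 2L, dimnames = list(NULL, "h1"))
  vs <- variant_set(c(2L, 3L), c("x", "y"), c("CGT", "G"),
                    list("C", "A"), geno, ref)
  g <- build_variant_graph(ref, vs)
  expect_error(haplotype_sequence(g, "h1"), "overlapping")
  expect_warning(s <- haplotype_sequence(g, "h1", drop_conflicts = TRUE),
                 "dropping")
  expect_equal(s, "ACACGT")  # keeps the earlier-starting record only
})

test_that("VCF parsing reproduces the packaged fixture and applies phasing", {
  fa <- system.file("extdata", "table1.fa", package = "founderpan")
  vcf <- system.file("extdata", "table1.vcf", package = "founderpan")
  vs <- read_vcf_haplotypes(vcf, "example", fa)
  fx <- table1_fixture()
  expect_equal(vs$pos, fx$variants$pos)
  expect_equal(vs$ref, fx$variants$ref)
  expect_equal(vs$alt, fx$variants$alt)
  expect_equal(unname(vs$geno), unname(fx$variants$geno))
  ## s3 carries a, c and allele 2 of e
  expect_equal(unname(vs$geno[, "s3"]), c(1L, 0L, 1L, 0L, 2L))

  ## diploid phasing: "1|0" -> copy 1 carries allele 1, copy 2 the reference
  dip <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=8>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "d1", sep = "\t"),
    paste("c1", 2, "b", "C", "T", ".", "PASS", ".", "GT", "1|0", sep = "\t")),
    dip)
  vd <- read_vcf_haplotypes(dip, "c1", "ACGTACGT")
  expect_equal(vd$labels, c("d1.1", "d1.2"))
  expect_equal(unname(vd$geno[1L, ]), c(1L, 0L))
})

test_that("VCF parsing surfaces unphased, symbolic and mismatching records", {
  mk <- function(line) {
    f <- tempfile(fileext = ".vcf")
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##contig=<ID=c1,length=8>",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "d1", sep = "\t"),
      line), f)
    f
  }
  unphased <- mk(paste("c1", 2, "b", "C", "T", ".", "PASS", ".", "GT", "1/0",
                       sep = "\t"))
  expect_error(read_vcf_haplotypes(unphased, "c1", "ACGTACGT"), "unphased")
  expect_warning(
    v <- read_vcf_haplotypes(unphased, "c1", "ACGTACGT",
                             strict_phasing = FALSE),
    "unphased")
  expect_equal(unname(v$geno[1L, ]), c(1L, 0L))

  symbolic <- mk(paste("c1", 2, "b", "C", "<DEL>", ".", "PASS", ".", "GT",
                       "1|0", sep = "\t"))
  expect_error(read_vcf_haplotypes(symbolic, "c1", "ACGTACGT"),
               "unsupported allele")

  mismatch <- mk(paste("c1", 2, "b", "G", "T", ".", "PASS", ".", "GT", "1|0",
                       sep = "\t"))
  expect_error(read_vcf_haplotypes(mismatch, "c1", "ACGTACGT"),
               "mismatch")
})

test_that("a VCF with zero data lines yields an empty variant set", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=8>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "d1", sep = "\t")), f)
  vs <- read_vcf_haplotypes(f, "c1", "ACGTACGT")
  expect_equal(length(vs$pos), 0L)
  expect_equal(vs$reference, "ACGTACGT")
})
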