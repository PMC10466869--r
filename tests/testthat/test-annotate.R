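# tiny explicit coding gene: TTT ATG GAG TAA TTT, CDS 4-12 on the + strand
coding_toy <- function() {
  list(genome = list(chrC = "TTTATGGAGTAATTT"),
       model = gene_model("geneC", "chrC", "+", start = 4L, end = 12L))
}

test_that("genic categories follow the documented precedence", {
  m <- toy_gene()
  cat_at <- function(pos) classify_site("chrA", pos, "A", "C",
                                        list(m))$category
  expect_equal(cat_at(130), "exonic")
  expect_equal(cat_at(161), "splicing") # 1 bp past an internal exon end
  expect_equal(cat_at(162), "splicing")
  expect_equal(cat_at(163), "intronic")
  expect_equal(cat_at(199), "splicing")
  expect_equal(cat_at(95), "UTR5")
  expect_equal(cat_at(100), "UTR5")   # adjacent to CDS start, not a splice
  expect_equal(cat_at(245), "UTR3")
  expect_equal(cat_at(50), "upstream")   # within 1 kb of the gene 5' end
  expect_equal(cat_at(300), "downstream")
  expect_equal(classify_site("chrB", 100, "A", "C", list(m))$category,
               "intergenic")
  expect_error(classify_site("chrA", 130, "N", "C", list(m)), "A/C/G/T")
})

test_that("coding consequences are translated from the affected codon", {
  toy <- coding_toy()
  cs <- function(pos, ref, alt) {
    classify_site("chrC", pos, ref, alt, list(toy$model), toy$genome)
  }
  non_syn <- cs(9, "G", "T") # GAG -> GAT, E -> D
  expect_equal(non_syn$consequence, "non-synonymous")
  expect_equal(non_syn$aa_change, "E/D")
  expect_equal(cs(9, "G", "A")$consequence, "synonymous") # GAG -> GAA
  expect_equal(cs(7, "G", "T")$consequence, "stop-gain")  # GAG -> TAG
  expect_equal(cs(12, "A", "C")$consequence, "stop-loss") # TAA -> TAC
  expect_equal(cs(12, "A", "C")$aa_change, "*/Y")
})

test_that("consequences are invariant under mirroring to the minus strand", {
  toy <- coding_toy()
  L <- nchar(toy$genome$chrC)
  mg <- mirror_genome(toy$genome)
  mm <- mirror_model(toy$model, L)
  cases <- list(c(9, "G", "T"), c(9, "G", "A"), c(7, "G", "T"),
                c(12, "A", "C"))
  for (cc in cases) {
    pos <- as.integer(cc[1])
    fwd <- classify_site("chrC", pos, cc[2], cc[3],
                         list(toy$model), toy$genome)
    rev <- classify_site("chrC", L - pos + 1L,
                         comp_base(cc[2]), comp_base(cc[3]),
                         list(mm), mg)
    expect_equal(rev$consequence, fwd$consequence,
                 info = paste("pos", pos))
    expect_equal(rev$aa_change, fwd$aa_change, info = paste("pos", pos))
  }
})

test_that("a multi-exon minus-strand gene translates in transcript order", {
  # + strand CDS TTT[ATGGA]T[GTAA]TT: exons 4-8 and 10-13 -> ATGGAGTAA
  genome <- list(chrD = "TTTATGGATGTAATT")
  # mirror everything to build the equivalent minus-strand gene
  L <- nchar(genome$chrD)
  m_plus <- gene_model("geneD", "chrD", "+", start = 4L, end = 13L,
                       exons = rbind(c(4L, 8L), c(10L, 13L)))
  a <- classify_site("chrD", 8, "A", "T", list(m_plus), genome)
  # 5th CDS base = codon 2 position 2: GAG -> GTG, E -> V
  expect_equal(a$aa_change, "E/V")
  mg <- mirror_genome(genome)
  mm <- mirror_model(m_plus, L)
  b <- classify_site("chrD", L - 8 + 1L, "T", "A", list(mm), mg)
  expect_equal(b$aa_change, "E/V")
})

test_that("annotate_sites derives alt alleles and tabulates categories", {
  toy <- coding_toy()
  sites <- one_site(c(2, 0, 0, 18), c(15, 0, 5, 0), chrom = "chrC",
                    pos = 9L, ref = "G")
  sites <- rbind(sites,
                 one_site(c(20, 5, 0, 0), c(18, 7, 0, 0), chrom = "chrC",
                          pos = 2L, ref = "A"))
  ann <- annotate_sites(sites, list(toy$model), toy$genome)
  expect_equal(ann$category, c("exonic", "upstream"))
  row9 <- ann[ann$pos == 9, ]
  expect_equal(row9$alt, "T") # highest non-reference mutant count
  expect_equal(row9$consequence, "non-synonymous")
  expect_true(is.na(ann$consequence[ann$pos == 2]))
})
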