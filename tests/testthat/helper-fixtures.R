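options(edbsa.quiet = TRUE)

# single-site count table builder: cm/cw are length-4 A,C,G,T vectors
one_site <- function(cm, cw, chrom = "chr1", pos = 100L, ref = "A") {
  pooled_counts(chrom, pos, ref, matrix(cm, 1), matrix(cw, 1))
}

# multi-site builder from a list of list(cm, cw[, ref])
sites_from <- function(rows, chrom = "chr1") {
  n <- length(rows)
  cm <- t(vapply(rows, function(r) r[[1]], numeric(4)))
  cw <- t(vapply(rows, function(r) r[[2]], numeric(4)))
  ref <- vapply(rows, function(r) if (length(r) >= 3) r[[3]] else "A", "")
  pooled_counts(rep(chrom, n), seq_len(n) * 1000L, ref, cm, cw)
}

# six-site toy designed to lose exactly one site per filter stage
toy_cascade_sites <- function() {
  sites_from(list(
    list(c(5, 5, 5, 0), c(10, 0, 0, 0)),   # triallelic -> stage 1
    list(c(10, 10, 0, 0), c(19, 1, 0, 0)), # wt A at 95% -> stage 2
    list(c(5, 4, 0, 0), c(20, 20, 0, 0)),  # mut depth 9 -> stage 3
    list(c(12, 8, 0, 0), c(10, 10, 0, 0)),
    list(c(0, 15, 0, 15), c(0, 20, 0, 5), "C"),
    list(c(30, 0, 10, 0), c(25, 0, 20, 0))
  ))
}

# toy genome + one-gene model for annotation tests
# gene: + strand, CDS exons 101-160 and 201-240 (100 codons shy; 60+40 = 100bp)
toy_genome <- function() {
  set.seed(42)
  # exon1 starts with ATG; splice the rest randomly but fixed
  s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  substr(s, 101, 103) <- "ATG"
  list(chrA = s)
}

toy_gene <- function() {
  gene_model("gene1", "chrA", "+", start = 101L, end = 240L,
             exons = rbind(c(101L, 160L), c(201L, 240L)),
             utr5 = rbind(c(81L, 100L)), utr3 = rbind(c(241L, 260L)))
}

# mirror a genome + model to the minus strand: pos' = L - pos + 1
mirror_genome <- function(genome) {
  lapply(genome, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  })
}

mirror_model <- function(m, L) {
  flip <- function(iv) {
    if (is.null(iv)) return(NULL)
    out <- cbind(L - iv[, 2] + 1L, L - iv[, 1] + 1L)
    out[order(out[, 1]), , drop = FALSE]
  }
  gene_model(m$gene_id, m$chrom, if (m$strand == "+") "-" else "+",
             start = L - m$end + 1L, end = L - m$start + 1L,
             exons = flip(m$exons), utr5 = flip(m$utr5), utr3 = flip(m$utr3))
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

# minimal two-sample VCF with AD; rows = character vector of data lines
write_toy_vcf <- function(rows, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tmutpool\twtpool"
  )
  writeLines(c(header, rows), path)
  path
}

# exhaustive hypergeometric upper tail by enumeration over all draws
enum_hyper_p <- function(m, M, n, N) {
  # enumerate the count distribution directly from binomial coefficients
  ms <- max(0, n - (N - M)):min(M, n)
  probs <- choose(M, ms) * choose(N - M, n - ms) / choose(N, n)
  sum(probs[ms >= m])
}
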