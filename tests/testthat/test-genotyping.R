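test_that("genotype calls follow the depth, frequency and read-support rules", {
  expect_equal(call_genotype(2, 2)$state, "missing")     # depth 4 < 5X
  expect_equal(call_genotype(1, 9)$state, "homozygous")  # freq 0.9
  expect_equal(call_genotype(1, 9)$allele_pair, c("A", "A"))
  expect_equal(call_genotype(9, 1)$allele_pair, c("R", "R"))
  expect_equal(call_genotype(7, 3)$state, "missing")     # alt support 3 < 4
  g <- call_genotype(5, 5)
  expect_equal(g$state, "heterozygous")
  expect_equal(g$allele_pair, c("R", "A"))
  # boundaries are inclusive for the homozygous rule
  expect_equal(call_genotype(2, 8)$state, "homozygous")  # exactly 0.8
  expect_equal(call_genotype(8, 2)$state, "homozygous")  # exactly 0.2
  expect_equal(call_genotype(0, 0)$state, "missing")
  expect_error(call_genotype(-1, 3), ">= 0")
})

test_that("genotype calling is total and deterministic over a count grid", {
  oracle <- function(r, a) {
    if (r + a < 5) return("missing")
    f <- a / (r + a)
    if (f >= 0.8 || f <= 0.2) return("homozygous")
    if (min(r, a) >= 4) return("heterozygous")
    "missing"
  }
  for (r in 0:30) for (a in 0:30) {
    got <- call_genotype(r, a)$state
    expect_identical(got, oracle(r, a),
                     info = sprintf("ref=%d alt=%d", r, a))
  }
})

test_that("the pre-filter cascade removes sites stage by stage", {
  res <- prefilter_sites(toy_cascade_sites())
  expect_equal(unlist(res$accounting, use.names = FALSE), c(6L, 5L, 4L, 3L))
  expect_equal(res$sites$pos, c(4000L, 5000L, 6000L))
})

test_that("single-stage removals match the documented rules", {
  # three observed bases -> stage 1
  res <- prefilter_sites(one_site(c(5, 5, 5, 0), c(30, 0, 0, 0)))
  expect_equal(res$accounting$biallelic, 0L)
  # wild-type base at exactly 95% -> stage 2 (inclusive)
  res <- prefilter_sites(one_site(c(10, 10, 0, 0), c(19, 1, 0, 0)))
  expect_equal(res$accounting$biallelic, 1L)
  expect_equal(res$accounting$frequency, 0L)
  # just below 95% survives stage 2
  res <- prefilter_sites(one_site(c(10, 10, 0, 0), c(18, 2, 0, 0)))
  expect_equal(res$accounting$frequency, 1L)
  # pool depth 9 -> stage 3
  res <- prefilter_sites(one_site(c(5, 4, 0, 0), c(20, 20, 0, 0)))
  expect_equal(res$accounting$frequency, 1L)
  expect_equal(res$accounting$depth, 0L)
  # mutant-pool fixation only filtered when requested
  mut_fixed <- one_site(c(19, 1, 0, 0), c(10, 10, 0, 0))
  expect_equal(prefilter_sites(mut_fixed)$accounting$depth, 1L)
  expect_equal(prefilter_sites(mut_fixed,
                               apply_to_mut = TRUE)$accounting$frequency, 0L)
})

test_that("pre-filter output is a consistent subset with monotone accounting", {
  set.seed(21)
  n <- 300
  counts <- pooled_counts(
    rep("chr1", n), seq_len(n), sample(c("A", "C", "G", "T"), n, TRUE),
    matrix(rpois(4 * n, 4), n), matrix(rpois(4 * n, 4), n)
  )
  res <- prefilter_sites(counts)
  acc <- unlist(res$accounting)
  expect_true(all(diff(acc) <= 0))
  expect_equal(nrow(res$sites), unname(acc["depth"]))
  key <- function(x) paste(x$chrom, x$pos)
  expect_true(all(key(res$sites) %in% key(counts)))
  # survivors actually satisfy the stage rules
  d <- list(mut = rowSums(res$sites[, paste0("mut_", c("A", "C", "G", "T"))]),
            wt = rowSums(res$sites[, paste0("wt_", c("A", "C", "G", "T"))]))
  expect_true(all(d$mut >= 10 & d$wt >= 10))
})

test_that("filter accounting exports with the standard column names", {
  res <- prefilter_sites(toy_cascade_sites())
  path <- tempfile(fileext = ".tsv")
  write_filter_accounting(res$accounting, path)
  header <- strsplit(readLines(path)[1], "\t")[[1]]
  expect_equal(header, c("Total", "Biallelic", "Frequency", "NA"))
})
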