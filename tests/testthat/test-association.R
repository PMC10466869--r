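test_that("noiseless genotype effects are recovered exactly", {
  ph <- simulate_phenotypes(60, c(AA = 0, AB = 2), noise_sd = 0,
                            mu = 1, seed = 13)
  a <- fit_association(ph, "site1")
  expect_true(a$testable)
  expect_equal(unname(a$genotype_means["AB"] - a$genotype_means["AA"]), 2,
               tolerance = 1e-12)
  expect_equal(unname(a$G["AB"] - a$G["AA"]), 2, tolerance = 1e-10)
  expect_lt(a$genotype_p, 1e-6)
  expect_true(a$significant)
})

test_that("with a single age level the test reduces to one-way ANOVA", {
  set.seed(15)
  ph <- simulate_phenotypes(50, c(AA = 0, AB = 1.5), noise_sd = 1,
                            age_effects = c(adult = 0), seed = 15)
  a <- fit_association(ph, "site1")
  # classical one-way F from group means and within-group variance
  sp <- split(ph$melatonin, ph$site1)
  k <- length(sp); n <- length(ph$melatonin)
  gm <- mean(ph$melatonin)
  ssb <- sum(vapply(sp, function(x) length(x) * (mean(x) - gm)^2, 0))
  ssw <- sum(vapply(sp, function(x) sum((x - mean(x))^2), 0))
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  p_oracle <- pf(f_oracle, k - 1, n - k, lower.tail = FALSE)
  expect_equal(a$f_stat, f_oracle, tolerance = 1e-9)
  expect_equal(a$genotype_p, p_oracle, tolerance = 1e-9)
})

test_that("model residuals sum to zero and p is invariant to relabeling", {
  ph <- simulate_phenotypes(80, c(AA = 0, AB = 1, BB = 2), noise_sd = 0.5,
                            age_effects = c(y1 = 0, y2 = 0.4), seed = 17)
  a <- fit_association(ph, "site1")
  expect_lt(abs(sum(a$residuals)), 1e-9)
  expect_equal(sum(a$G), 0, tolerance = 1e-10) # sum-to-zero constraint
  relab <- ph
  relab$site1 <- c(AA = "zz", AB = "qq", BB = "mm")[ph$site1]
  b <- fit_association(relab, "site1")
  expect_equal(a$genotype_p, b$genotype_p, tolerance = 1e-10)
})

test_that("age effects are absorbed before testing genotype", {
  # phenotype driven by age only: genotype must not appear significant
  set.seed(19)
  n <- 120
  age <- sample(c("y1", "y2"), n, replace = TRUE)
  geno <- sample(c("AA", "AB"), n, replace = TRUE)
  ph <- data.frame(
    sample = sprintf("S%03d", 1:n),
    melatonin = 1 + 2 * (age == "y2") + abs(rnorm(n, 0, 0.3)),
    age = age, site1 = geno, stringsAsFactors = FALSE
  )
  a <- fit_association(ph, "site1")
  # age variance is huge; after absorbing it the genotype F is small
  expect_gt(a$genotype_p, 0.01)
  expect_equal(sum(a$P), 0, tolerance = 1e-10)
})

test_that("small classes are dropped and degenerate sites flagged", {
  ph <- simulate_phenotypes(30, c(AA = 0, AB = 1), noise_sd = 0.3, seed = 23)
  ph$site1[1] <- "RARE" # singleton class
  a <- fit_association(ph, "site1")
  expect_false("RARE" %in% names(a$genotype_counts))
  ph$site1 <- "AA"
  b <- fit_association(ph, "site1")
  expect_false(b$testable)
  expect_true(is.na(b$genotype_p))
})

test_that("associate_all_sites scans every typed column", {
  ph <- simulate_phenotypes(60, c(AA = 0, AB = 2), noise_sd = 0.2, seed = 29)
  ph$site2 <- sample(c("GG", "GT"), 60, replace = TRUE) # unlinked
  res <- associate_all_sites(ph)
  expect_equal(res$site, c("site1", "site2"))
  expect_true(res$significant[res$site == "site1"])
})

test_that("phenotype bins are left-closed with one-decimal percentages", {
  vals <- c(rep(0.2, 100), rep(0.7, 42), rep(1.5, 53))
  b <- summarize_bins(vals, c(0, 0.5, 1))
  expect_equal(b$count, c(100L, 42L, 53L))
  expect_equal(b$percent, c(51.3, 21.5, 27.2))
  # a value exactly at an interior edge goes to the right-hand bin
  b2 <- summarize_bins(c(0.1, 0.5), c(0, 0.5, 1))
  expect_equal(b2$count, c(1L, 1L, 0L))
  # all values in one bin
  b3 <- summarize_bins(rep(2, 5), c(0, 0.5, 1))
  expect_equal(b3$percent, c(0, 0, 100))
  expect_error(summarize_bins(numeric(0)), "no values")
  expect_error(summarize_bins(c(1, 2), c(1, 0.5)), "strictly increasing")
})
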