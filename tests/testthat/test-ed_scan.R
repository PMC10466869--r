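test_that("ED matches closed-form values at canonical sites", {
  # identical pools -> 0
  r <- compute_ed(one_site(c(7, 3, 2, 0), c(7, 3, 2, 0)))
  expect_equal(r$ed, 0)
  expect_equal(r$ed4, 0)
  # oppositely fixed pools -> sqrt(2)
  r <- compute_ed(one_site(c(10, 0, 0, 0), c(0, 0, 0, 10)))
  expect_equal(r$ed, sqrt(2))
  # hand-evaluated intermediate case
  r <- compute_ed(one_site(c(15, 5, 0, 0), c(5, 15, 0, 0)))
  expect_equal(r$ed, sqrt(0.5))
  expect_equal(r$ed4, 0.25)
  # mutation frequency is the non-reference fraction in the mutant pool
  expect_equal(r$mut_freq, 5 / 20)
  expect_error(compute_ed(one_site(c(1, 0, 0, 0), c(0, 0, 0, 0))),
               "zero-depth")
})

test_that("ED is pool-swap symmetric, bounded by sqrt(2), with ed4 = ed^4", {
  set.seed(31)
  for (i in 1:50) {
    cm <- rpois(4, 6) * rbinom(4, 1, 0.6)
    cw <- rpois(4, 6) * rbinom(4, 1, 0.6)
    if (sum(cm) == 0 || sum(cw) == 0) next
    a <- compute_ed(one_site(cm, cw))
    b <- compute_ed(one_site(cw, cm))
    expect_equal(a$ed, b$ed)
    expect_equal(a$ed4, a$ed^4)
    expect_lte(a$ed, sqrt(2) + 1e-12)
  }
})

test_that("the smoother reproduces constants and straight lines", {
  n <- 60
  rec <- data.frame(chrom = "chr1", pos = sort(sample.int(1e6, n)),
                    ed4 = 0.7)
  f <- fit_scan(rec)
  expect_equal(f$fitted, rep(0.7, n), tolerance = 1e-9)
  # degree-1 local regression reproduces a linear ramp exactly
  rec$ed4 <- 2e-7 * rec$pos + 0.1
  f <- fit_scan(rec)
  expect_equal(f$fitted, rec$ed4, tolerance = 1e-7)
})

test_that("a single spike is attenuated and spread by smoothing", {
  n <- 50
  rec <- data.frame(chrom = "chr1", pos = seq_len(n) * 1000L, ed4 = 0)
  rec$ed4[25] <- 10
  f <- fit_scan(rec, scan_config(span = 0.2))
  expect_lt(f$fitted[25], 10)
  expect_gt(sum(f$fitted > 0.01), 1) # mass spread over the window
})

test_that("smoothed values agree with per-site weighted least squares", {
  set.seed(33)
  n <- 200
  pos <- sort(sample.int(5e6, n))
  rec <- data.frame(chrom = "chr1", pos = pos, ed4 = runif(n)^4)
  span <- 0.15
  f <- fit_scan(rec, scan_config(span = span))
  q <- ceiling(span * n)
  oracle <- vapply(seq_len(n), function(i) {
    d <- abs(pos - pos[i])
    h <- sort(d)[q]
    sel <- d <= h
    w <- pmax(0, (1 - (d[sel] / h)^3))^3
    fit <- lm(y ~ x, data = data.frame(x = pos[sel] - pos[i],
                                       y = rec$ed4[sel]), weights = w)
    max(0, unname(predict(fit, newdata = data.frame(x = 0))))
  }, 0)
  expect_equal(f$fitted, oracle, tolerance = 1e-9)
})

test_that("chromosomes with fewer than 10 sites fall back to raw values", {
  rec <- data.frame(chrom = "chrS", pos = 1:5 * 100L, ed4 = c(1, 2, 3, 4, 5))
  expect_warning(f <- fit_scan(rec), "< 10 sites")
  expect_equal(f$fitted, rec$ed4)
})

test_that("the association threshold is median + k * sample SD", {
  expect_equal(association_threshold(c(1, 1, 1, 1)), 1)
  expect_equal(association_threshold(c(0, 0, 0, 0, 10)), 3 * sqrt(20))
  # translation equivariance
  set.seed(35)
  x <- rexp(200)
  expect_equal(association_threshold(x + 5.3),
               association_threshold(x) + 5.3, tolerance = 1e-9)
  expect_error(association_threshold(1), "at least 2")
})

test_that("regions are maximal runs above threshold, split by any gap", {
  rec <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                    fitted = c(0, 5, 5, 0))
  reg <- call_regions(rec, 1)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 200L)
  expect_equal(reg$end, 300L)
  expect_equal(reg$n_sites, 2L)

  rec$fitted <- c(5, 0, 5, 0)
  reg <- call_regions(rec, 1)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$n_sites, c(1L, 1L))

  # a run never crosses a chromosome boundary
  rec2 <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                     pos = c(100L, 200L, 100L, 200L),
                     fitted = c(5, 5, 5, 5))
  reg <- call_regions(rec2, 1)
  expect_equal(reg$chrom, c("chr1", "chr2"))

  expect_equal(nrow(call_regions(rec, 100)), 0L)
})

test_that("candidate selection applies strict thresholds inside regions only", {
  rec <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    mut_freq = c(0.80, 0.75, 0.90, 0.90),
    ed = c(0.71, 0.71, 0.4, 1.0),
    fitted = c(5, 5, 5, 0)
  )
  reg <- call_regions(rec, 1)
  out <- select_candidates(rec, reg)
  expect_equal(out$candidate, c(TRUE, FALSE, FALSE, FALSE))
  # site 2: frequency exactly 0.75 fails the strict rule
  # site 3: ed 0.4 fails; site 4: outside the region despite high values
  expect_equal(out$in_region, c(TRUE, TRUE, TRUE, FALSE))
})
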