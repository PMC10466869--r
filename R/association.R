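#' Genotype-phenotype association at one typed site
#'
#' Fits the two-factor fixed-effects model
#' `melatonin = mu + genotype + age + error` by ordinary least squares
#' with sum-to-zero contrasts, and tests the genotype factor with a
#' partial F-test (type-II sums of squares: genotype added after age).
#' Genotype classes with fewer than `min_class_n` observations are
#' dropped with a notice; if fewer than 2 classes remain the site is
#' flagged untestable. Reported genotype means are raw class means of the
#' phenotype.
#'
#' @param pheno data frame with `melatonin`, `age` and one genotype
#'   column per typed site (see [read_phenotypes()]).
#' @param site name of the genotype column to test.
#' @param min_class_n minimum observations per genotype class (default 2).
#' @param age_numeric treat age as a numeric covariate instead of a
#'   categorical factor.
#' @return list of class `site_association`: `site`, `testable`,
#'   `n_used`, `genotype_counts`, `genotype_means`, `mu`, `G` (genotype
#'   effects, sum-to-zero), `P` (age effects), `genotype_p`, `f_stat`,
#'   `df`, `residuals`, `significant` (p < 0.05), `model` (the lm fit).
#' @export
fit_association <- function(pheno, site, min_class_n = 2,
                            age_numeric = FALSE) {
  if (!site %in% names(pheno)) stopf("no genotype column '%s'", site)
  d <- pheno[!is.na(pheno[[site]]) & !is.na(pheno$age) &
               !is.na(pheno$melatonin), , drop = FALSE]
  d$genotype <- as.character(d[[site]])
  tab <- table(d$genotype)
  small <- names(tab)[tab < min_class_n]
  if (length(small) > 0) {
    ed_log("assoc", site, ": dropping class(es) with < ", min_class_n,
           " observations: ", paste(small, collapse = ", "))
    d <- d[!(d$genotype %in% small), , drop = FALSE]
  }
  counts <- table(d$genotype)
  out <- list(site = site, testable = FALSE, n_used = nrow(d),
              genotype_counts = counts,
              genotype_means = tapply(d$melatonin, d$genotype, mean),
              mu = NA_real_, G = NULL, P = NULL,
              genotype_p = NA_real_, f_stat = NA_real_, df = c(NA, NA),
              residuals = NULL, significant = NA, model = NULL)
  class(out) <- "site_association"
  if (length(counts) < 2) {
    ed_log("assoc", site, ": fewer than 2 genotype classes; untestable")
    return(out)
  }
  d$genotype <- factor(d$genotype)
  d$age <- if (age_numeric) as.numeric(as.character(d$age)) else factor(d$age)
  one_age <- !age_numeric && nlevels(d$age) < 2
  rhs0 <- if (one_age || (age_numeric && stats::var(d$age) == 0)) "1" else "age"
  fit0 <- stats::lm(stats::reformulate(rhs0, "melatonin"), data = d,
                    contrasts = NULL)
  fit1 <- stats::lm(stats::reformulate(c(rhs0, "genotype"), "melatonin"),
                    data = d,
                    contrasts = list(genotype = "contr.sum"))
  an <- stats::anova(fit0, fit1)
  cf <- stats::coef(fit1)
  g_idx <- grep("^genotype", names(cf))
  g_eff <- cf[g_idx]
  G <- c(g_eff, -sum(g_eff))
  names(G) <- levels(d$genotype)
  P <- NULL
  if (rhs0 == "age" && !age_numeric) {
    # refit age with sum contrasts to report its effects on the same scale
    fitP <- stats::lm(melatonin ~ age + genotype, data = d,
                      contrasts = list(age = "contr.sum",
                                       genotype = "contr.sum"))
    cfP <- stats::coef(fitP)
    a_idx <- grep("^age", names(cfP))
    P <- c(cfP[a_idx], -sum(cfP[a_idx]))
    names(P) <- levels(d$age)
    out$mu <- unname(cfP["(Intercept)"])
  } else {
    out$mu <- unname(cf["(Intercept)"])
  }
  out$testable <- TRUE
  out$G <- G
  out$P <- P
  out$genotype_p <- an$`Pr(>F)`[2]
  out$f_stat <- an$F[2]
  out$df <- c(an$Df[2], an$Res.Df[2])
  out$residuals <- stats::residuals(fit1)
  out$significant <- is.finite(out$genotype_p) && out$genotype_p < 0.05
  out$model <- fit1
  out
}

#' Association scan over all typed sites in a phenotype table
#'
#' @param pheno phenotype data frame; every column other than `sample`,
#'   `melatonin`, `age` is treated as a typed site.
#' @param ... passed to [fit_association()].
#' @return data frame with one row per site: `site`, `n_used`,
#'   `n_classes`, `genotype_p`, `significant`, and per-genotype means
#'   collapsed into a `means` string.
#' @export
associate_all_sites <- function(pheno, ...) {
  sites <- setdiff(names(pheno), c("sample", "melatonin", "age"))
  rows <- lapply(sites, function(s) {
    a <- fit_association(pheno, s, ...)
    data.frame(
      site = s, n_used = a$n_used,
      n_classes = length(a$genotype_counts),
      genotype_p = a$genotype_p,
      significant = isTRUE(a$significant),
      means = paste(sprintf("%s=%.3f", names(a$genotype_means),
                            a$genotype_means), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Bin phenotype values and report counts and percentages
#'
#' Intervals are closed on the left and open on the right; the final bin
#' is open above (`[last edge, Inf)`). Percentages are `100 * count /
#' total` rounded to one decimal, the convention of phenotype
#' distribution summaries (e.g. 100/42/53 of 195 animals giving 51.3,
#' 21.5 and 27.2 percent).
#'
#' @param values numeric vector (>= 0).
#' @param bin_edges strictly increasing edges; the first bin is
#'   `[edges[1], edges[2])` and a final open bin `[edges[k], Inf)` is
#'   appended.
#' @return data frame with `bin`, `count`, `percent`.
#' @export
summarize_bins <- function(values, bin_edges = c(0, 0.5, 1)) {
  if (length(values) == 0) stopf("no values to bin")
  if (any(values < 0)) stopf("values must be >= 0")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stopf("bin edges must be strictly increasing")
  }
  edges <- c(bin_edges, Inf)
  idx <- findInterval(values, edges, left.open = FALSE)
  idx[idx == 0] <- NA # below the first edge
  labs <- c(sprintf("[%g, %g)", utils::head(bin_edges, -1), bin_edges[-1]),
            sprintf(">= %g", bin_edges[length(bin_edges)]))
  counts <- tabulate(idx, nbins = length(labs))
  data.frame(
    bin = labs,
    count = counts,
    percent = round(100 * counts / sum(counts), 1)
  )
}
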