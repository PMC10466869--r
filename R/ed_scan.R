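#' Scan configuration
#'
#' Collects the tunable parameters of the ED genome scan.
#'
#' @param power exponent applied to the raw ED statistic before smoothing;
#'   the 4th power suppresses background noise while preserving large
#'   between-pool divergences.
#' @param span smoothing fraction: the tricube local-linear fit at each
#'   site uses the nearest `ceiling(span * n)` sites of its chromosome.
#' @param threshold_sd_mult multiple of the genome-wide SD added to the
#'   median of fitted values to form the association threshold.
#' @param cand_freq_min candidate sites must exceed this mutant-pool
#'   mutation frequency (strict inequality).
#' @param cand_ed_min candidate sites must exceed this raw ED (strict).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(power = 4, span = 0.1, threshold_sd_mult = 3,
                        cand_freq_min = 0.75, cand_ed_min = 0.5) {
  stopifnot(power >= 1, span > 0, span <= 1, threshold_sd_mult >= 0)
  structure(list(power = power, span = span,
                 threshold_sd_mult = threshold_sd_mult,
                 cand_freq_min = cand_freq_min, cand_ed_min = cand_ed_min),
            class = "scan_config")
}

#' Per-site Euclidean distance between pool base frequencies
#'
#' For each site the four base frequencies of each pool are the read
#' counts divided by the pool depth, and
#' \deqn{ED = \sqrt{(A_m-A_w)^2 + (C_m-C_w)^2 + (G_m-G_w)^2 + (T_m-T_w)^2}}
#' where the subscripts denote the mutant (high-phenotype) and wild-type
#' (low-phenotype) pools. `ed4` is `ed^power`. The mutation frequency
#' `mut_freq` is the non-reference allele frequency in the mutant pool.
#'
#' @param counts a [pooled_counts] data frame; both pools must have
#'   positive depth at every site (run [prefilter_sites()] first).
#' @param power exponent for `ed4` (default 4).
#' @return data frame with `chrom`, `pos`, `ref`, the eight pool
#'   frequencies (`fmut_A..fwt_T`), `mut_freq`, `ed` and `ed4`.
#' @export
compute_ed <- function(counts, power = 4) {
  cm <- as.matrix(counts[, MUT_COLS, drop = FALSE])
  cw <- as.matrix(counts[, WT_COLS, drop = FALSE])
  dm <- rowSums(cm)
  dw <- rowSums(cw)
  if (any(dm == 0) || any(dw == 0)) {
    bad <- which(dm == 0 | dw == 0)[1]
    stopf("zero-depth pool at %s:%d; prefilter sites first",
          counts$chrom[bad], counts$pos[bad])
  }
  fm <- cm / dm
  fw <- cw / dw
  ed <- sqrt(rowSums((fm - fw)^2))
  ref_idx <- match(counts$ref, BASES)
  mut_freq <- 1 - fm[cbind(seq_len(nrow(fm)), ref_idx)]
  out <- data.frame(chrom = counts$chrom, pos = counts$pos,
                    ref = counts$ref, stringsAsFactors = FALSE)
  colnames(fm) <- paste0("fmut_", BASES)
  colnames(fw) <- paste0("fwt_", BASES)
  out <- cbind(out, as.data.frame(fm), as.data.frame(fw))
  out$mut_freq <- mut_freq
  out$ed <- ed
  out$ed4 <- ed^power
  out
}

# tricube local-linear regression of y on x evaluated at every x;
# q nearest neighbours define the bandwidth at each point
tricube_local_linear <- function(x, y, q) {
  n <- length(x)
  q <- max(2L, min(n, q))
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    h <- sort(d, partial = q)[q]
    if (h <= 0) { # q-fold ties at the evaluation point
      fitted[i] <- mean(y[d == 0])
      next
    }
    sel <- which(d <= h)
    w <- (1 - (d[sel] / h)^3)^3
    w[w < 0] <- 0
    u <- x[sel] - x[i]
    W <- sum(w); Su <- sum(w * u); Suu <- sum(w * u^2)
    Sy <- sum(w * y[sel]); Suy <- sum(w * u * y[sel])
    den <- W * Suu - Su^2
    if (den <= .Machine$double.eps * W * Suu || W == 0) {
      fitted[i] <- if (W > 0) Sy / W else y[i]
    } else {
      b1 <- (W * Suy - Su * Sy) / den
      fitted[i] <- (Sy - b1 * Su) / W
    }
  }
  fitted
}

#' Smooth the ED^4 signal along each chromosome
#'
#' Fits a degree-1 local polynomial regression (tricube weights, one pass,
#' no robustness iterations) of `ed4` on position, separately per
#' chromosome, with a nearest-neighbour window holding `span` of the
#' chromosome's sites. Fitted values are clipped at 0. Chromosomes with
#' fewer than 10 sites are left unsmoothed (`fitted = ed4`) with a
#' warning.
#'
#' @param records data frame from [compute_ed()].
#' @param config a [scan_config()].
#' @return `records` with a `fitted` column added.
#' @export
fit_scan <- function(records, config = scan_config()) {
  records$fitted <- NA_real_
  for (ch in unique(records$chrom)) {
    idx <- which(records$chrom == ch)
    pos <- records$pos[idx]
    if (is.unsorted(pos, strictly = TRUE)) {
      stopf("positions on %s must be strictly increasing", ch)
    }
    if (length(idx) < 10) {
      warning(sprintf("chromosome %s has %d < 10 sites; fitted = raw ed4",
                      ch, length(idx)), call. = FALSE)
      records$fitted[idx] <- records$ed4[idx]
      next
    }
    q <- ceiling(config$span * length(idx))
    f <- tricube_local_linear(as.numeric(pos), records$ed4[idx], q)
    records$fitted[idx] <- pmax(f, 0)
  }
  records
}

#' Genome-wide association threshold
#'
#' The threshold is the median of all fitted values plus `sd_mult` sample
#' standard deviations (n - 1 denominator), computed genome-wide over
#' every site's fitted value.
#'
#' @param fitted numeric vector of fitted ED^4 values (all chromosomes).
#' @param sd_mult SD multiplier (default 3).
#' @return scalar threshold.
#' @export
association_threshold <- function(fitted, sd_mult = 3) {
  if (length(fitted) < 2) stopf("need at least 2 fitted values")
  stats::median(fitted) + sd_mult * stats::sd(fitted)
}

#' Call associated regions
#'
#' Maximal runs of consecutive sites on one chromosome whose fitted value
#' is at or above the threshold become regions; a single sub-threshold
#' site splits a run. Region bounds are the first and last member
#' positions (1-based inclusive).
#'
#' @param records fitted data frame from [fit_scan()], sorted by
#'   (chrom, pos).
#' @param threshold association threshold from [association_threshold()].
#' @return data frame with `chrom`, `start`, `end`, `n_sites`,
#'   `peak_fitted` plus a `region` index column mapping back into
#'   `records` via [assign_regions()].
#' @export
call_regions <- function(records, threshold) {
  above <- records$fitted >= threshold
  # run starts: above here, and previous site below / other chromosome
  new_chrom <- c(TRUE, records$chrom[-1] != records$chrom[-nrow(records)])
  if (nrow(records) == 0 || !any(above)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      peak_fitted = numeric()))
  }
  run_start <- above & (new_chrom | !c(FALSE, above[-length(above)]))
  run_id <- cumsum(run_start)
  run_id[!above] <- NA
  sp <- split(seq_len(nrow(records)), run_id)
  data.frame(
    chrom = vapply(sp, function(i) records$chrom[i[1]], ""),
    start = vapply(sp, function(i) records$pos[i[1]], 0L),
    end = vapply(sp, function(i) records$pos[i[length(i)]], 0L),
    n_sites = lengths(sp),
    peak_fitted = vapply(sp, function(i) max(records$fitted[i]), 0),
    row.names = NULL
  )
}

#' Map sites to their containing region
#'
#' @param records fitted data frame.
#' @param regions data frame from [call_regions()].
#' @return integer vector: region row index per site, `NA` outside all
#'   regions.
#' @export
assign_regions <- function(records, regions) {
  out <- rep(NA_integer_, nrow(records))
  for (r in seq_len(nrow(regions))) {
    hit <- records$chrom == regions$chrom[r] &
      records$pos >= regions$start[r] & records$pos <= regions$end[r]
    out[hit] <- r
  }
  out
}

#' Select candidate SNPs inside associated regions
#'
#' A member site of a region is a candidate when its mutant-pool mutation
#' frequency exceeds `cand_freq_min` AND its raw ED (not the 4th power)
#' exceeds `cand_ed_min`; both inequalities are strict. Sites outside all
#' regions are never candidates.
#'
#' @param records fitted data frame from [fit_scan()].
#' @param regions data frame from [call_regions()].
#' @param config a [scan_config()].
#' @return `records` with logical columns `in_region` and `candidate` and
#'   an integer `region` column.
#' @export
select_candidates <- function(records, regions, config = scan_config()) {
  records$region <- assign_regions(records, regions)
  records$in_region <- !is.na(records$region)
  records$candidate <- records$in_region &
    records$mut_freq > config$cand_freq_min &
    records$ed > config$cand_ed_min
  records
}

#' Manhattan-style plot of the ED scan
#'
#' Dots show the per-site ED^4 correlation value, the line the fitted
#' curve, the dashed rule the association threshold, and shaded bands the
#' called regions.
#'
#' @param records data frame from [select_candidates()] or [fit_scan()].
#' @param regions optional regions data frame.
#' @param threshold optional threshold to draw.
#' @return a ggplot object.
#' @export
plot_ed_scan <- function(records, regions = NULL, threshold = NULL) {
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ed4),
                        size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(ED^4)) +
    ggplot2::theme_bw()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
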