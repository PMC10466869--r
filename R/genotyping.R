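#' Call a per-sample genotype from ref/alt read counts
#'
#' Implements the read-count genotyping rules used for the per-animal SNP
#' tables:
#' \itemize{
#'   \item total depth below 5X: the site is missing (`NA` in the tables);
#'   \item alternate-allele frequency at or above 0.8: homozygous for the
#'     alternate allele; at or below 0.2: homozygous reference;
#'   \item frequency strictly between 0.2 and 0.8 with at least 4 reads on
#'     each allele: heterozygous;
#'   \item otherwise (an allele with fewer than 4 supporting reads):
#'     missing.
#' }
#' Both boundaries are inclusive for the homozygous calls.
#'
#' @param ref_reads,alt_reads non-negative read counts for the reference
#'   and alternate allele.
#' @param ref_base,alt_base optional allele labels used to fill
#'   `allele_pair`.
#' @return a list with `state` (one of `"missing"`, `"homozygous"`,
#'   `"heterozygous"`), `allele_pair` (two bases, or `NA` when missing)
#'   and `alt_freq`.
#' @export
call_genotype <- function(ref_reads, alt_reads, ref_base = "R", alt_base = "A") {
  if (ref_reads < 0 || alt_reads < 0) stopf("read counts must be >= 0")
  depth <- ref_reads + alt_reads
  if (depth < 5) {
    return(list(state = "missing", allele_pair = c(NA_character_, NA_character_),
                alt_freq = if (depth > 0) alt_reads / depth else NA_real_))
  }
  f <- alt_reads / depth
  if (f >= 0.8) {
    return(list(state = "homozygous", allele_pair = c(alt_base, alt_base),
                alt_freq = f))
  }
  if (f <= 0.2) {
    return(list(state = "homozygous", allele_pair = c(ref_base, ref_base),
                alt_freq = f))
  }
  if (min(ref_reads, alt_reads) >= 4) {
    return(list(state = "heterozygous", allele_pair = c(ref_base, alt_base),
                alt_freq = f))
  }
  list(state = "missing", allele_pair = c(NA_character_, NA_character_),
       alt_freq = f)
}

#' Pre-filter pooled sites before the ED scan
#'
#' Applies the three-stage filter cascade with per-stage accounting:
#' \enumerate{
#'   \item biallelic: keep sites where exactly two bases have non-zero
#'     combined read count across both pools;
#'   \item frequency: drop sites where a single base reaches at least
#'     `fix_threshold` (default 95\%) of the wild-type pool reads — such
#'     sites are effectively fixed in the wild-type pool and carry no
#'     segregating signal (the mutant pool can be screened too via
#'     `apply_to_mut`);
#'   \item depth: drop sites where either pool's total depth is below
#'     `min_depth` (default 10X).
#' }
#'
#' @param counts a [pooled_counts] data frame.
#' @param min_depth minimum per-pool depth (stage 3).
#' @param fix_threshold wild-type pool fixation frequency (stage 2,
#'   inclusive).
#' @param apply_to_mut also apply the fixation screen to the mutant pool.
#' @return list with `sites` (the surviving subset) and `accounting`, a
#'   one-row data frame with columns `total`, `biallelic`, `frequency`,
#'   `depth` counting the sites surviving each stage.
#' @export
prefilter_sites <- function(counts, min_depth = 10, fix_threshold = 0.95,
                            apply_to_mut = FALSE) {
  total <- nrow(counts)
  cm <- as.matrix(counts[, MUT_COLS, drop = FALSE])
  cw <- as.matrix(counts[, WT_COLS, drop = FALSE])

  # stage 1: biallelic — exactly two bases observed across both pools
  nalleles <- rowSums((cm + cw) > 0)
  s1 <- nalleles == 2
  counts1 <- counts[s1, , drop = FALSE]
  cm1 <- cm[s1, , drop = FALSE]
  cw1 <- cw[s1, , drop = FALSE]

  # stage 2: fixation screen on the two retained bases of the wild-type pool
  fixed_in <- function(mat, both) {
    kept <- mat
    kept[!both] <- 0L # only the two segregating bases enter the frequency
    dep <- rowSums(kept)
    mx <- apply(kept, 1L, max)
    dep > 0 & mx / dep >= fix_threshold
  }
  both <- (cm1 + cw1) > 0
  drop2 <- fixed_in(cw1, both)
  if (apply_to_mut) drop2 <- drop2 | fixed_in(cm1, both)
  counts2 <- counts1[!drop2, , drop = FALSE]

  # stage 3: per-pool depth
  d <- pool_depths(counts2)
  s3 <- d$mut >= min_depth & d$wt >= min_depth
  counts3 <- counts2[s3, , drop = FALSE]

  accounting <- data.frame(
    total = total,
    biallelic = nrow(counts1),
    frequency = nrow(counts2),
    depth = nrow(counts3)
  )
  rownames(counts3) <- NULL
  class(counts3) <- class(counts)
  list(sites = counts3, accounting = accounting)
}

#' Export filter accounting as TSV
#'
#' Writes the cascade counts with the column naming used in pool-seq
#' filtering reports (`Total`, `Biallelic`, `Frequency`, `NA`).
#'
#' @param accounting one-row data frame from [prefilter_sites()].
#' @param path output file.
#' @export
write_filter_accounting <- function(accounting, path) {
  out <- accounting
  names(out) <- c("Total", "Biallelic", "Frequency", "NA")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
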