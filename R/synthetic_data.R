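#' Simulation configuration for two-bulk pooled sequencing
#'
#' Describes the generative model behind [simulate_bulks()]: a set of
#' segregating sites scattered over one or more chromosomes, a shared
#' neutral allele frequency per site, and planted QTL at which the two
#' bulks' allele frequencies diverge by `delta` at the peak, decaying
#' linearly to zero over `linkage_window` bp on each side.
#'
#' Defaults mirror the study design the simulator emulates: two bulks of
#' 3 animals each sequenced to ~28X mean depth, with broad linkage blocks
#' as expected from small extreme-phenotype pools.
#'
#' @param chrom_lengths named numeric vector, chromosome name -> length bp.
#' @param n_sites total segregating sites (allocated to chromosomes
#'   proportionally to length).
#' @param qtls data frame with columns `chrom`, `pos`, `delta`
#'   (allele-frequency divergence between pools at the peak, in (0, 1]);
#'   `NULL` for a fully neutral genome.
#' @param linkage_window bp over which `delta` decays linearly to 0.
#' @param depth_mean mean per-pool sequencing depth (Poisson).
#' @param pool_size animals per bulk (kept for overdispersion extensions;
#'   the default read model is binomial in the pool frequency).
#' @param baseline_maf_range interval from which the neutral minor-allele
#'   frequency is drawn uniformly.
#' @param seed integer seed; all draws flow from one RNG seeded once.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 1e8, chr2 = 1e8),
                       n_sites = 5000,
                       qtls = NULL,
                       linkage_window = 1e7,
                       depth_mean = 28,
                       pool_size = 3,
                       baseline_maf_range = c(0.05, 0.5),
                       seed = 1L) {
  stopifnot(depth_mean > 0, n_sites > 0, linkage_window > 0,
            length(baseline_maf_range) == 2,
            baseline_maf_range[1] >= 0, baseline_maf_range[2] <= 1)
  if (!is.null(qtls)) {
    qtls <- as.data.frame(qtls)
    stopifnot(all(c("chrom", "pos", "delta") %in% names(qtls)))
    if (any(qtls$delta <= 0 | qtls$delta > 1)) {
      stopf("qtl delta must be in (0, 1]")
    }
    bad <- !(qtls$chrom %in% names(chrom_lengths)) |
      qtls$pos < 1 | qtls$pos > chrom_lengths[qtls$chrom]
    if (any(bad)) stopf("qtl position outside its chromosome")
  }
  structure(list(chrom_lengths = chrom_lengths, n_sites = n_sites,
                 qtls = qtls, linkage_window = linkage_window,
                 depth_mean = depth_mean, pool_size = pool_size,
                 baseline_maf_range = baseline_maf_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate two-bulk pooled read counts with planted QTL
#'
#' Neutral sites share one population allele frequency `p` drawn
#' uniformly from `baseline_maf_range`; both pools sample reads
#' binomially at `p`. Within `linkage_window` of a QTL the pool
#' frequencies become `p + delta*w/2` (mutant pool) and `p - delta*w/2`
#' (wild-type pool), where `w` is the linear decay weight (1 at the peak,
#' 0 at the window edge); frequencies pushed outside \[0, 1\] are clamped
#' with a notice. Per-site, per-pool depth is Poisson with mean
#' `depth_mean`. Output is byte-identical for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [pooled_counts] data frame) and `truth`
#'   (list: `sites` data frame with true pool frequencies `p_mut`,
#'   `p_wt`; `qtl_regions` data frame with the planted intervals).
#' @export
simulate_bulks <- function(config = sim_config()) {
  set.seed(config$seed)
  lens <- config$chrom_lengths
  n_per <- round(config$n_sites * lens / sum(lens))
  # rounding drift goes to the first chromosome
  n_per[1] <- n_per[1] + (config$n_sites - sum(n_per))
  chrom <- rep(names(lens), n_per)
  pos <- unlist(lapply(names(lens), function(ch) {
    sort(sample.int(lens[[ch]], n_per[[ch]], replace = FALSE))
  }), use.names = FALSE)
  n <- length(pos)
  p <- stats::runif(n, config$baseline_maf_range[1], config$baseline_maf_range[2])

  # QTL divergence: split delta symmetrically between the pools
  shift <- numeric(n)
  if (!is.null(config$qtls)) {
    for (k in seq_len(nrow(config$qtls))) {
      q <- config$qtls[k, ]
      on_ch <- chrom == q$chrom
      w <- pmax(0, 1 - abs(pos - q$pos) / config$linkage_window)
      shift[on_ch] <- pmax(shift[on_ch], (q$delta * w / 2)[on_ch])
    }
  }
  p_mut <- p + shift
  p_wt <- p - shift
  n_clamped <- sum(p_mut > 1 | p_wt < 0)
  if (n_clamped > 0) {
    ed_log("simulate", n_clamped, " site frequency(ies) clamped to [0, 1]")
  }
  p_mut <- pmin(1, pmax(0, p_mut))
  p_wt <- pmin(1, pmax(0, p_wt))

  # assign ref/alt bases, then sample depths and alt reads
  ref_idx <- sample.int(4L, n, replace = TRUE)
  alt_idx <- 1L + (ref_idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L
  dep_mut <- stats::rpois(n, config$depth_mean)
  dep_wt <- stats::rpois(n, config$depth_mean)
  alt_mut <- stats::rbinom(n, dep_mut, p_mut)
  alt_wt <- stats::rbinom(n, dep_wt, p_wt)

  cm <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  cw <- cm
  rows <- seq_len(n)
  cm[cbind(rows, ref_idx)] <- dep_mut - alt_mut
  cm[cbind(rows, alt_idx)] <- alt_mut
  cw[cbind(rows, ref_idx)] <- dep_wt - alt_wt
  cw[cbind(rows, alt_idx)] <- alt_wt

  counts <- pooled_counts(chrom, pos, BASES[ref_idx], cm, cw)
  truth_sites <- data.frame(chrom = chrom, pos = pos,
                            p_mut = p_mut, p_wt = p_wt)
  qtl_regions <- if (is.null(config$qtls)) {
    data.frame(chrom = character(), start = numeric(), end = numeric())
  } else {
    data.frame(
      chrom = config$qtls$chrom,
      start = pmax(1, config$qtls$pos - config$linkage_window),
      end = pmin(config$chrom_lengths[config$qtls$chrom],
                 config$qtls$pos + config$linkage_window)
    )
  }
  list(counts = counts,
       truth = list(sites = truth_sites, qtl_regions = qtl_regions))
}

#' Simulate per-animal melatonin phenotypes under the genotype + age model
#'
#' Generates records following `Y = mu + genotype effect + age effect +
#' Gaussian noise`, with genotypes drawn from stated class frequencies and
#' age classes assigned uniformly.
#'
#' @param n_animals number of animals.
#' @param genotype_effects named numeric vector, genotype label -> mean
#'   shift in ng/mL (at least 2 classes).
#' @param age_effects named numeric vector, age class -> shift in ng/mL.
#' @param noise_sd residual SD (ng/mL), must be >= 0.
#' @param mu overall mean melatonin (ng/mL).
#' @param genotype_freqs class frequencies (defaults to equal); recycled
#'   against `genotype_effects`.
#' @param seed integer seed.
#' @param site label used for the genotype column (default "site1").
#' @return data frame with `sample`, `melatonin`, `age` and one genotype
#'   column named by `site`.
#' @export
simulate_phenotypes <- function(n_animals,
                                genotype_effects,
                                age_effects = c(yearling = 0),
                                noise_sd = 0.5,
                                mu = 1.0,
                                genotype_freqs = NULL,
                                seed = 1L,
                                site = "site1") {
  if (length(genotype_effects) < 2) stopf("need at least 2 genotype classes")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  g_levels <- names(genotype_effects)
  freqs <- genotype_freqs %||% rep(1 / length(g_levels), length(g_levels))
  freqs <- freqs / sum(freqs)
  geno <- sample(g_levels, n_animals, replace = TRUE, prob = freqs)
  age <- sample(names(age_effects), n_animals, replace = TRUE)
  y <- mu + genotype_effects[geno] + age_effects[age] +
    stats::rnorm(n_animals, 0, noise_sd)
  y <- pmax(0, y) # concentrations cannot be negative
  out <- data.frame(
    sample = sprintf("S%03d", seq_len(n_animals)),
    melatonin = unname(y),
    age = age,
    stringsAsFactors = FALSE
  )
  out[[site]] <- geno
  out
}
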