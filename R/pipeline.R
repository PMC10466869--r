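#' Pipeline configuration
#'
#' @param counts path to a count table or VCF, or a [pooled_counts]
#'   data frame already in memory; `NULL` to simulate with `sim`.
#' @param sim a [sim_config()] used when `counts` is `NULL`.
#' @param gene_models path to a GFF3 file or a list of [gene_model()]s;
#'   `NULL` disables annotation.
#' @param genome optional chromosome sequences for codon consequences.
#' @param term_map path or term map list; `NULL` skips enrichment.
#' @param gene_map optional function or named vector mapping a candidate
#'   site to a gene id for enrichment; by default annotation gene ids are
#'   used.
#' @param phenotypes path or data frame for the association stage;
#'   `NULL` skips it.
#' @param scan a [scan_config()].
#' @param min_depth,fix_threshold pre-filter settings.
#' @param q_cutoff enrichment significance cutoff.
#' @param out_dir output directory for stage artifacts.
#' @param make_plots write the scan and enrichment figures.
#' @param seed seed recorded in the manifest and used for simulation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, sim = sim_config(),
                            gene_models = NULL, genome = NULL,
                            term_map = NULL, gene_map = NULL,
                            phenotypes = NULL,
                            scan = scan_config(),
                            min_depth = 10, fix_threshold = 0.95,
                            q_cutoff = 0.05,
                            out_dir = "edbsa_out", make_plots = FALSE,
                            seed = 1L) {
  structure(list(counts = counts, sim = sim, gene_models = gene_models,
                 genome = genome, term_map = term_map, gene_map = gene_map,
                 phenotypes = phenotypes, scan = scan,
                 min_depth = min_depth, fix_threshold = fix_threshold,
                 q_cutoff = q_cutoff, out_dir = out_dir,
                 make_plots = make_plots, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full BSA-ED pipeline
#'
#' Executes pre-filter, ED computation, smoothing, threshold, region
#' calling, candidate selection, then (when inputs are provided)
#' annotation, enrichment and phenotype association; writes every stage
#' artifact under `out_dir` and returns a manifest of stage counts.
#'
#' @param config a [pipeline_config()].
#' @return list (the manifest): `seed`, `threshold`, `accounting`,
#'   `n_regions`, `total_region_bp`, `n_candidates`, `n_candidate_genes`,
#'   plus the stage tables in `$tables`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  # --- input / simulation ------------------------------------------------
  truth <- NULL
  if (is.null(config$counts)) {
    ed_log("simulate", "no counts supplied; simulating two bulks (seed ",
           config$sim$seed, ")")
    simres <- simulate_bulks(config$sim)
    counts <- simres$counts
    truth <- simres$truth
    write_pooled_counts(counts, out("counts.tsv"))
    jsonlite::write_json(truth, out("truth.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  } else if (is.character(config$counts)) {
    counts <- read_pooled_counts(config$counts)
  } else {
    counts <- config$counts
  }

  # --- filter ------------------------------------------------------------
  ed_log("filter", nrow(counts), " sites in")
  flt <- prefilter_sites(counts, min_depth = config$min_depth,
                         fix_threshold = config$fix_threshold)
  write_filter_accounting(flt$accounting, out("filter_accounting.tsv"))
  ed_log("filter", flt$accounting$depth, " sites out")
  if (nrow(flt$sites) == 0) stopf("filter stage: no sites survive")

  # --- scan --------------------------------------------------------------
  rec <- compute_ed(flt$sites, power = config$scan$power)
  rec <- fit_scan(rec, config$scan)
  threshold <- association_threshold(rec$fitted, config$scan$threshold_sd_mult)
  ed_log("scan", sprintf("association threshold %.6g", threshold))
  regions <- call_regions(rec, threshold)
  rec <- select_candidates(rec, regions, config$scan)
  regions$n_candidates <- if (nrow(regions) > 0) {
    vapply(seq_len(nrow(regions)),
           function(r) sum(rec$candidate & rec$region == r, na.rm = TRUE), 0L)
  } else integer(0)
  utils::write.table(rec, out("scan.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_regions_bed(regions, out("regions.bed"))
  cand <- rec[rec$candidate, , drop = FALSE]
  utils::write.table(cand, out("candidates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ed_log("regions", nrow(regions), " region(s), ", nrow(cand), " candidate(s)")

  # --- annotate ----------------------------------------------------------
  annotation <- NULL
  cand_genes <- character()
  if (!is.null(config$gene_models) && nrow(cand) > 0) {
    models <- if (is.character(config$gene_models)) {
      read_gene_models(config$gene_models)
    } else config$gene_models
    ann_in <- flt$sites[match(paste(cand$chrom, cand$pos),
                              paste(flt$sites$chrom, flt$sites$pos)), ]
    annotation <- annotate_sites(ann_in, models, config$genome)
    utils::write.table(annotation, out("annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cand_genes <- unique(annotation$gene_id[!is.na(annotation$gene_id)])
    ed_log("annotate", nrow(annotation), " candidate site(s) annotated, ",
           length(cand_genes), " gene(s)")
  }
  if (!is.null(config$gene_map)) {
    keys <- paste0(cand$chrom, ":", cand$pos)
    mapped <- if (is.function(config$gene_map)) config$gene_map(keys)
    else unname(config$gene_map[keys])
    cand_genes <- unique(c(cand_genes, mapped[!is.na(mapped)]))
  }

  # --- enrich ------------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$term_map) && length(cand_genes) > 0) {
    tm <- if (is.character(config$term_map)) read_term_map(config$term_map)
    else config$term_map
    enrichment <- enrich(cand_genes, tm, q_cutoff = config$q_cutoff)
    write_enrichment(enrichment, out("enrichment.tsv"))
    ed_log("enrich", nrow(enrichment), " term(s) tested, ",
           sum(enrichment$significant), " significant")
  } else if (is.null(config$term_map)) {
    ed_log("enrich", "no term map supplied; enrichment skipped")
  }

  # --- associate ---------------------------------------------------------
  association <- NULL
  if (!is.null(config$phenotypes)) {
    pheno <- if (is.character(config$phenotypes)) {
      read_phenotypes(config$phenotypes)
    } else config$phenotypes
    association <- associate_all_sites(pheno)
    utils::write.table(association, out("association.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ed_log("assoc", nrow(association), " site(s) tested")
  }

  # --- plots -------------------------------------------------------------
  if (isTRUE(config$make_plots)) {
    tryCatch({
      grDevices::png(out("ed_scan.png"), width = 1400, height = 600)
      print(plot_ed_scan(rec, regions, threshold))
      grDevices::dev.off()
      if (!is.null(enrichment) && nrow(enrichment) > 0) {
        grDevices::png(out("enrichment.png"), width = 900, height = 700)
        print(plot_enrichment(enrichment))
        grDevices::dev.off()
      }
    }, error = function(e) {
      ed_log("plot", "figure rendering failed: ", conditionMessage(e))
    })
  }

  manifest <- list(
    seed = config$seed,
    n_sites_in = nrow(counts),
    accounting = as.list(flt$accounting),
    threshold = threshold,
    n_regions = nrow(regions),
    total_region_bp = if (nrow(regions) > 0) {
      sum(regions$end - regions$start + 1)
    } else 0,
    n_candidates = nrow(cand),
    n_candidate_genes = length(cand_genes),
    n_terms_significant = if (!is.null(enrichment)) {
      sum(enrichment$significant)
    } else NA,
    tables = list(scan = rec, regions = regions, candidates = cand,
                  annotation = annotation, enrichment = enrichment,
                  association = association, truth = truth)
  )
  jsonlite::write_json(manifest[setdiff(names(manifest), "tables")],
                       out("manifest.json"), auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  manifest
}

#' One-command synthetic demonstration
#'
#' Simulates two bulks (5,000 sites on two chromosomes, one planted QTL),
#' runs the full scan and reports whether the called regions recover the
#' planted interval.
#'
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param make_plots write figures.
#' @return the pipeline manifest plus `qtl_recovered`.
#' @export
run_demo <- function(seed = 7L, out_dir = tempfile("edbsa_demo"),
                     make_plots = FALSE) {
  cfg <- pipeline_config(
    sim = sim_config(
      qtls = data.frame(chrom = "chr1", pos = 5e7, delta = 0.8),
      depth_mean = 30, seed = seed),
    out_dir = out_dir, make_plots = make_plots, seed = seed)
  man <- run_pipeline(cfg)
  truth_iv <- man$tables$truth$qtl_regions
  reg <- man$tables$regions
  man$qtl_recovered <- nrow(reg) > 0 && any(
    reg$chrom == truth_iv$chrom[1] &
      reg$start <= truth_iv$end[1] & reg$end >= truth_iv$start[1])
  man
}
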