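#' Read pooled allele-depth data
#'
#' Reads per-site base counts for the two bulks either from a tab-separated
#' count table or from a VCF with per-sample allele depths (`AD`).
#'
#' The TSV format has a header line
#' `chrom pos ref mutA mutC mutG mutT wtA wtC wtG wtT` (tab-separated).
#' For VCF input the file must contain exactly two samples carrying the
#' `AD` FORMAT field; the first sample is taken as the high-phenotype
#' (mutant) pool, the second as the low-phenotype (wild-type) pool.
#' Allele depths are mapped onto A/C/G/T counts following REF-then-ALT
#' order; alleles that are not single bases (indels) are ignored with a
#' notice. Records are returned sorted by (chrom, pos); all-zero sites are
#' dropped.
#'
#' @param path input file.
#' @param format `"tsv"`, `"vcf"`, or `"auto"` (by file extension).
#' @return a [pooled_counts] data frame.
#' @export
read_pooled_counts <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") read_counts_tsv(path) else read_counts_vcf(path)
}

read_counts_tsv <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = NA)
  if (nrow(x) == 0) {
    return(pooled_counts(character(), integer(), character(),
                         matrix(0L, 0, 4), matrix(0L, 0, 4)))
  }
  want <- c("chrom", "pos", "ref",
            "mutA", "mutC", "mutG", "mutT", "wtA", "wtC", "wtG", "wtT")
  miss <- setdiff(want, names(x))
  if (length(miss) > 0) {
    stopf("count table %s: missing column(s) %s", path,
          paste(miss, collapse = ", "))
  }
  if (is.unsorted(order(x$chrom, x$pos))) {
    ed_log("io", "input not sorted by (chrom, pos); sorting on load")
  }
  pooled_counts(x$chrom, x$pos, x$ref,
                as.matrix(x[, c("mutA", "mutC", "mutG", "mutT")]),
                as.matrix(x[, c("wtA", "wtC", "wtG", "wtT")]))
}

read_counts_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) != 3L) { # FORMAT + 2 samples
    stopf("VCF %s: exactly two samples required (mutant pool first)", path)
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                        dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    return(pooled_counts(character(), integer(), character(),
                         matrix(0L, 0, 4), matrix(0L, 0, 4)))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  cm <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  cw <- cm
  for (i in seq_len(n)) {
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    for (s in 1:2) {
      ad_i <- ad[i, s]
      if (is.na(ad_i)) {
        stopf("VCF %s: missing AD at %s:%s sample %d",
              path, fix[i, "CHROM"], fix[i, "POS"], s)
      }
      depths <- suppressWarnings(as.integer(strsplit(ad_i, ",", fixed = TRUE)[[1]]))
      for (k in seq_along(alleles)) {
        a <- toupper(alleles[k])
        if (a %in% BASES && k <= length(depths) && !is.na(depths[k])) {
          if (s == 1) cm[i, a] <- cm[i, a] + depths[k]
          else cw[i, a] <- cw[i, a] + depths[k]
        }
      }
    }
  }
  ref <- toupper(fix[, "REF"])
  snv <- ref %in% BASES
  if (!all(snv)) ed_log("io", sum(!snv), " non-SNV record(s) skipped")
  pooled_counts(fix[snv, "CHROM"], as.integer(fix[snv, "POS"]), ref[snv],
                cm[snv, , drop = FALSE], cw[snv, , drop = FALSE])
}

#' Write a pooled count table as TSV
#'
#' Inverse of [read_pooled_counts()] for the TSV format; a write/read
#' round trip reproduces the records exactly.
#'
#' @param counts a [pooled_counts] data frame.
#' @param path output file.
#' @export
write_pooled_counts <- function(counts, path) {
  out <- data.frame(
    chrom = counts$chrom, pos = counts$pos, ref = counts$ref,
    mutA = counts$mut_A, mutC = counts$mut_C,
    mutG = counts$mut_G, mutT = counts$mut_T,
    wtA = counts$wt_A, wtC = counts$wt_C,
    wtG = counts$wt_G, wtT = counts$wt_T
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write associated regions as BED
#'
#' Regions are held internally as 1-based inclusive intervals; on output
#' they are converted to BED's 0-based half-open convention, so the BED
#' interval length equals `end - start + 1` of the internal region. The
#' score column carries the peak fitted ED^4 value.
#'
#' @param regions data frame from [call_regions()].
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  o <- order(regions$chrom, regions$start)
  regions <- regions[o, , drop = FALSE]
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = sprintf("region_%d", seq_len(nrow(regions))),
    score = signif(regions$peak_fitted, 6)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term mapping
#'
#' Accepts either a two-column TSV (`gene<TAB>term`, optional third column
#' = term name) or a GMT-like format (`term<TAB>name<TAB>gene1<TAB>gene2...`).
#' Duplicate gene/term pairs are collapsed.
#'
#' @param path input file.
#' @param format `"auto"`, `"tsv"` or `"gmt"`. `"auto"` treats files whose
#'   every line has two or three fields as gene/term TSV, otherwise GMT.
#' @return a list with `terms` (named list of character gene vectors),
#'   `names` (named character vector of term descriptions) and `genes`
#'   (all genes seen, the annotated universe).
#' @export
read_term_map <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stopf("term map %s: malformed line %d (fewer than 2 fields)",
          path, which(nf < 2)[1])
  }
  if (format == "auto") {
    format <- if (length(nf) > 0 && all(nf <= 3)) "tsv" else "gmt"
  }
  terms <- list()
  term_names <- character()
  if (format == "tsv") {
    gene <- vapply(fields, `[`, "", 1L)
    term <- vapply(fields, `[`, "", 2L)
    for (tt in unique(term)) {
      terms[[tt]] <- sort(unique(gene[term == tt]))
    }
    nm3 <- nf >= 3
    if (any(nm3)) {
      term_names[term[nm3]] <- vapply(fields[nm3], `[`, "", 3L)
    }
  } else {
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 3) {
        stopf("term map %s: malformed GMT line %d (no genes)", path, i)
      }
      terms[[f[1]]] <- sort(unique(c(terms[[f[1]]], f[-(1:2)])))
      term_names[f[1]] <- f[2]
    }
  }
  missing_names <- setdiff(names(terms), names(term_names))
  term_names[missing_names] <- missing_names
  list(terms = terms,
       names = term_names[names(terms)],
       genes = sort(unique(unlist(terms, use.names = FALSE))))
}

#' Read gene models from GFF3
#'
#' Builds single-transcript gene models (coding span, CDS exons, optional
#' UTRs, strand) from a GFF3 file. Exons are taken from `CDS` features
#' linked to each gene through the `Parent` chain; where a gene has several
#' transcripts only the union gene is retained with the CDS of the first
#' transcript encountered.
#'
#' @param path GFF3 file.
#' @return a named list of gene models (see [gene_model()]).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- GenomicRanges::mcols(gr)
  type <- as.character(md$type)
  get_id <- function(i) as.character(md$ID[i])
  get_parent <- function(i) {
    p <- md$Parent[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }
  # map feature ID -> owning gene ID
  gene_idx <- which(type == "gene")
  gene_ids <- vapply(gene_idx, get_id, "")
  tx_of <- character() # transcript ID -> gene ID
  tx_idx <- which(type %in% c("mRNA", "transcript"))
  for (i in tx_idx) tx_of[get_id(i)] <- get_parent(i)
  owner <- function(i) {
    p <- get_parent(i)
    if (is.na(p)) return(NA_character_)
    if (p %in% gene_ids) p else tx_of[p] %||% NA_character_
  }
  models <- list()
  for (k in seq_along(gene_idx)) {
    i <- gene_idx[k]
    gid <- gene_ids[k]
    models[[gid]] <- list(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      strand = as.character(GenomicRanges::strand(gr)[i]),
      start = GenomicRanges::start(gr)[i],
      end = GenomicRanges::end(gr)[i],
      exons = NULL, utr5 = NULL, utr3 = NULL
    )
  }
  add_iv <- function(m, slot, s, e) {
    m[[slot]] <- rbind(m[[slot]], c(s, e))
    m
  }
  for (i in which(type %in% c("CDS", "five_prime_UTR", "three_prime_UTR"))) {
    gid <- owner(i)
    if (is.na(gid) || is.null(models[[gid]])) next
    slot <- switch(type[i], CDS = "exons",
                   five_prime_UTR = "utr5", three_prime_UTR = "utr3")
    models[[gid]] <- add_iv(models[[gid]], slot,
                            GenomicRanges::start(gr)[i],
                            GenomicRanges::end(gr)[i])
  }
  lapply(models, function(m) {
    # the coding span is the CDS range; the gene feature span is the
    # fallback for models without CDS rows
    if (!is.null(m$exons)) {
      m$start <- min(m$exons[, 1])
      m$end <- max(m$exons[, 2])
    }
    do.call(gene_model, c(m[c("gene_id", "chrom", "strand")],
                          list(start = m$start, end = m$end,
                               exons = m$exons, utr5 = m$utr5,
                               utr3 = m$utr3)))
  })
}

#' Read a phenotype table
#'
#' Expects a TSV with columns `sample`, `melatonin` (ng/mL), `age`
#' (categorical class), plus one column per typed site holding genotype
#' strings such as `"GG"` or `"CG"`; empty cells or `NA` mark missing
#' genotypes.
#'
#' @param path input TSV.
#' @return data frame with `sample`, `melatonin` (numeric), `age` (factor)
#'   and the genotype columns as character.
#' @export
read_phenotypes <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), check.names = FALSE)
  need <- c("sample", "melatonin", "age")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("phenotype table %s: missing column(s) %s",
                          path, paste(miss, collapse = ", "))
  x$melatonin <- as.numeric(x$melatonin)
  if (any(!is.finite(x$melatonin))) {
    stopf("phenotype table %s: non-finite melatonin value(s)", path)
  }
  if (any(x$melatonin < 0)) {
    stopf("phenotype table %s: negative melatonin value(s)", path)
  }
  x$age <- factor(x$age)
  x
}

#' Write a phenotype table
#' @param pheno data frame as produced by [simulate_phenotypes()].
#' @param path output TSV.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
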