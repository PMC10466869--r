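#' Construct a single-transcript gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive coding span.
#' @param exons matrix or data frame of CDS exon intervals (start, end),
#'   1-based inclusive; must be sorted and non-overlapping and lie within
#'   `[start, end]`. Defaults to one exon spanning the whole coding span.
#' @param utr5,utr3 optional interval matrices for the untranslated
#'   regions (outside the coding span).
#' @return list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand = "+", start, end,
                       exons = NULL, utr5 = NULL, utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"), start <= end)
  as_iv <- function(x) {
    if (is.null(x) || NROW(x) == 0) return(NULL)
    m <- matrix(as.integer(as.matrix(x)), ncol = 2)
    m[order(m[, 1]), , drop = FALSE]
  }
  exons <- as_iv(exons) %||% matrix(c(start, end), ncol = 2)
  if (any(exons[, 1] > exons[, 2])) stopf("%s: malformed exon interval", gene_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
    stopf("%s: exons overlap or are unsorted", gene_id)
  }
  if (exons[1, 1] < start || exons[nrow(exons), 2] > end) {
    stopf("%s: exons outside the coding span", gene_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 exons = exons, utr5 = as_iv(utr5), utr3 = as_iv(utr3)),
            class = "gene_model")
}

in_any <- function(pos, iv) {
  !is.null(iv) && any(pos >= iv[, 1] & pos <= iv[, 2])
}

# category of `pos` relative to one gene model, ignoring other genes;
# NULL when the site is unrelated to this gene (beyond the flank)
site_category_one <- function(pos, m, flank = 1000L, splice_window = 2L) {
  if (in_any(pos, m$exons)) return("exonic")
  # splicing: intron side of an internal exon boundary, within the window
  k <- nrow(m$exons)
  if (k > 1) {
    donor <- m$exons[-k, 2]   # boundaries followed by an intron
    acceptor <- m$exons[-1, 1] # boundaries preceded by an intron
    if (any(pos > donor & pos - donor <= splice_window) ||
        any(pos < acceptor & acceptor - pos <= splice_window)) {
      return("splicing")
    }
  }
  if (in_any(pos, m$utr5)) return("UTR5")
  if (in_any(pos, m$utr3)) return("UTR3")
  if (pos >= m$start && pos <= m$end) return("intronic")
  iv_col <- function(iv, j) if (is.null(iv)) integer(0) else iv[, j]
  g_start <- min(c(m$start, iv_col(m$utr5, 1), iv_col(m$utr3, 1)))
  g_end <- max(c(m$end, iv_col(m$utr5, 2), iv_col(m$utr3, 2)))
  if (pos < g_start && g_start - pos <= flank) {
    return(if (m$strand == "+") "upstream" else "downstream")
  }
  if (pos > g_end && pos - g_end <= flank) {
    return(if (m$strand == "+") "downstream" else "upstream")
  }
  NULL
}

CATEGORY_ORDER <- c("exonic", "splicing", "UTR5", "UTR3", "intronic",
                    "upstream", "downstream", "intergenic")

#' Classify a SNP by genic context
#'
#' Assigns one of `exonic`, `splicing`, `UTR5`, `UTR3`, `intronic`,
#' `upstream`, `downstream`, `intergenic` with that precedence across all
#' overlapping genes. `splicing` means within 2 bp of an exon-intron
#' boundary on the intron side; `upstream`/`downstream` extend 1 kb from
#' the gene (strand-aware). For exonic sites with a genome sequence
#' available, the affected codon is translated on the transcript strand
#' and the consequence reported as `synonymous`, `non-synonymous`,
#' `stop-gain` or `stop-loss` with the amino-acid change in `"X/Y"` form.
#'
#' @param chrom,pos site coordinates (1-based).
#' @param ref,alt reference and alternate base (A/C/G/T).
#' @param models list of [gene_model()] objects.
#' @param genome optional named list/vector of chromosome sequences (plain
#'   strings or a `Biostrings::DNAStringSet`) used for codon translation.
#' @param flank upstream/downstream window in bp (default 1000).
#' @param splice_window splice-site window in bp (default 2).
#' @return list: `chrom`, `pos`, `category`, `gene_id` (`NA` if
#'   intergenic), `consequence` (`NA` unless exonic with genome),
#'   `aa_change`.
#' @export
classify_site <- function(chrom, pos, ref, alt, models, genome = NULL,
                          flank = 1000L, splice_window = 2L) {
  if (!ref %in% BASES || !alt %in% BASES) {
    stopf("site base must be one of A/C/G/T")
  }
  best_cat <- "intergenic"
  best_gene <- NA_character_
  best_model <- NULL
  for (m in models) {
    if (m$chrom != chrom) next
    cat_m <- site_category_one(pos, m, flank, splice_window)
    if (is.null(cat_m)) next
    if (match(cat_m, CATEGORY_ORDER) < match(best_cat, CATEGORY_ORDER)) {
      best_cat <- cat_m
      best_gene <- m$gene_id
      best_model <- m
    }
  }
  consequence <- NA_character_
  aa_change <- NA_character_
  if (best_cat == "exonic" && !is.null(genome)) {
    cons <- coding_consequence(pos, ref, alt, best_model, genome)
    consequence <- cons$consequence
    aa_change <- cons$aa_change
  }
  list(chrom = chrom, pos = pos, category = best_cat, gene_id = best_gene,
       consequence = consequence, aa_change = aa_change)
}

coding_consequence <- function(pos, ref, alt, m, genome) {
  seq_ch <- as.character(genome[[m$chrom]])
  # CDS position in transcript orientation
  ex <- m$exons
  lens <- ex[, 2] - ex[, 1] + 1L
  hit <- which(pos >= ex[, 1] & pos <= ex[, 2])
  offset_plus <- sum(lens[seq_len(hit - 1)]) + (pos - ex[hit, 1]) + 1L
  cds_len <- sum(lens)
  cds_pos <- if (m$strand == "+") offset_plus else cds_len - offset_plus + 1L
  # assemble CDS sequence
  cds <- paste0(vapply(seq_len(nrow(ex)),
                       function(i) substr(seq_ch, ex[i, 1], ex[i, 2]), ""),
                collapse = "")
  genome_ref <- substr(seq_ch, pos, pos)
  if (toupper(genome_ref) != ref) {
    ed_log("annotate", sprintf("reference mismatch at %s:%d (genome %s, site %s)",
                               m$chrom, pos, genome_ref, ref))
  }
  if (m$strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    alt_tx <- as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  } else {
    alt_tx <- alt
  }
  codon_i <- (cds_pos - 1L) %/% 3L
  within <- (cds_pos - 1L) %% 3L + 1L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3) { # truncated terminal codon: no call
    return(list(consequence = NA_character_, aa_change = NA_character_))
  }
  codon_alt <- codon
  substr(codon_alt, within, within) <- alt_tx
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(codon_alt)))
  consequence <- if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "stop-gain"
  else if (aa_ref == "*") "stop-loss"
  else "non-synonymous"
  list(consequence = consequence,
       aa_change = paste(aa_ref, aa_alt, sep = "/"))
}

#' Annotate a table of sites
#'
#' Vectorized wrapper around [classify_site()]; the alternate allele of a
#' pooled site is taken as the non-reference base with the highest
#' mutant-pool count.
#'
#' @param sites data frame with `chrom`, `pos`, `ref` and either an `alt`
#'   column or the pooled count columns.
#' @param models list of gene models.
#' @param genome optional chromosome sequences for codon consequences.
#' @param ... passed to [classify_site()].
#' @return data frame: site columns plus `category`, `gene_id`,
#'   `consequence`, `aa_change`.
#' @export
annotate_sites <- function(sites, models, genome = NULL, ...) {
  alt <- sites$alt
  if (is.null(alt)) {
    cm <- as.matrix(sites[, MUT_COLS, drop = FALSE])
    alt <- character(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      cand <- setdiff(BASES, sites$ref[i])
      alt[i] <- cand[which.max(cm[i, paste0("mut_", cand)])]
    }
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    a <- classify_site(sites$chrom[i], sites$pos[i], sites$ref[i], alt[i],
                       models, genome, ...)
    data.frame(chrom = a$chrom, pos = a$pos, ref = sites$ref[i],
               alt = alt[i], category = a$category, gene_id = a$gene_id,
               consequence = a$consequence, aa_change = a$aa_change,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
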