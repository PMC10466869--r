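#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

MUT_COLS <- paste0("mut_", BASES)
WT_COLS <- paste0("wt_", BASES)

# stage-tagged message on stderr; suppressible via options(edbsa.quiet = TRUE)
ed_log <- function(stage, ...) {
  if (isTRUE(getOption("edbsa.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Construct a pooled site-count table
#'
#' The central container of the pipeline: one row per segregating site with
#' the A/C/G/T read counts of the high-phenotype ("mutant") pool and the
#' low-phenotype ("wild-type") pool. Coordinates are 1-based.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref reference base, one of "A","C","G","T".
#' @param counts_mut matrix (n x 4) of A,C,G,T read counts in the mutant pool.
#' @param counts_wt matrix (n x 4) of A,C,G,T read counts in the wild-type pool.
#' @return A `data.frame` of class `pooled_counts` with columns
#'   `chrom`, `pos`, `ref`, `mut_A..mut_T`, `wt_A..wt_T`, sorted by
#'   (chrom, pos).
#' @export
pooled_counts <- function(chrom, pos, ref, counts_mut, counts_wt) {
  counts_mut <- as.matrix(counts_mut)
  counts_wt <- as.matrix(counts_wt)
  n <- length(chrom)
  if (length(pos) != n || length(ref) != n ||
      nrow(counts_mut) != n || nrow(counts_wt) != n ||
      ncol(counts_mut) != 4L || ncol(counts_wt) != 4L) {
    stopf("pooled_counts: inconsistent input dimensions")
  }
  if (n > 0 && (any(pos < 1) || any(counts_mut < 0) || any(counts_wt < 0))) {
    stopf("pooled_counts: positions must be >= 1 and counts non-negative")
  }
  if (n > 0 && !all(ref %in% BASES)) {
    stopf("pooled_counts: ref base must be one of A/C/G/T")
  }
  x <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref),
    stringsAsFactors = FALSE
  )
  colnames(counts_mut) <- MUT_COLS
  colnames(counts_wt) <- WT_COLS
  x <- cbind(x, as.data.frame(counts_mut), as.data.frame(counts_wt))
  keep <- rowSums(x[, c(MUT_COLS, WT_COLS), drop = FALSE]) > 0
  if (n > 0 && !all(keep)) {
    ed_log("counts", sum(!keep), " all-zero site(s) dropped")
    x <- x[keep, , drop = FALSE]
  }
  o <- order(x$chrom, x$pos)
  if (is.unsorted(o)) {
    x <- x[o, , drop = FALSE]
  }
  rownames(x) <- NULL
  class(x) <- c("pooled_counts", "data.frame")
  x
}

pool_depths <- function(counts) {
  list(
    mut = rowSums(as.matrix(counts[, MUT_COLS, drop = FALSE])),
    wt = rowSums(as.matrix(counts[, WT_COLS, drop = FALSE]))
  )
}
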