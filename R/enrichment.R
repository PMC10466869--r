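#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `m` annotated genes among `n`
#' candidates drawn without replacement from a universe of `N` genes of
#' which `M` carry the term:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}}
#' Evaluated exactly in log space (no normal approximation); for small
#' p-values the upper tail is summed directly to avoid cancellation.
#'
#' @param m candidate genes carrying the term.
#' @param M background genes carrying the term.
#' @param n annotated candidate genes.
#' @param N background genes with annotation.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_p <- function(m, M, n, N) {
  if (m > min(M, n)) stopf("m (%d) exceeds min(M, n) = %d", m, min(M, n))
  if (M > N || n > N || min(m, M, n, N) < 0) stopf("invalid hypergeometric input")
  if (m == 0) return(1)
  i <- m:min(M, n)
  terms <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  p <- sum(exp(terms))
  min(1, max(0, p))
}

#' Term over-representation analysis
#'
#' Hypergeometric enrichment of a candidate gene set against a background
#' universe for every term of a gene-to-term map, with Benjamini-Hochberg
#' correction across all tested terms. Only genes present in the
#' background enter the test; only background genes that carry at least
#' one term form the annotated universe `N`, matching the convention that
#' `N` counts genes *with* annotation.
#'
#' @param candidates character vector of candidate gene ids.
#' @param term_map list as returned by [read_term_map()] (or a bare named
#'   list of term -> gene id vectors).
#' @param background character vector of background gene ids; defaults to
#'   all annotated genes in the term map.
#' @param q_cutoff significance cutoff on the adjusted p-value.
#' @return data frame with one row per term having `m >= 1`: `term_id`,
#'   `term_name`, `m`, `M`, `n`, `N`, `p_value`, `q_value`,
#'   `rich_factor` (= m/M) and `significant` (q <= `q_cutoff`), sorted by
#'   p-value.
#' @export
enrich <- function(candidates, term_map, background = NULL,
                   q_cutoff = 0.05) {
  if (is.null(term_map$terms)) term_map <- list(terms = term_map)
  terms <- term_map$terms
  term_names <- term_map$names %||%
    stats::setNames(names(terms), names(terms))
  annotated <- unique(unlist(terms, use.names = FALSE))
  background <- unique(background %||% annotated)
  # universe: annotated background genes only
  universe <- intersect(background, annotated)
  candidates <- unique(candidates)
  n_outside <- sum(!(candidates %in% background))
  if (n_outside > 0) {
    ed_log("enrich", n_outside, " candidate gene(s) outside background dropped")
  }
  cand <- intersect(candidates, universe)
  N <- length(universe)
  n <- length(cand)
  empty <- data.frame(term_id = character(), term_name = character(),
                      m = integer(), M = integer(), n = integer(),
                      N = integer(), p_value = numeric(), q_value = numeric(),
                      rich_factor = numeric(), significant = logical())
  if (n == 0 || N == 0) return(empty)
  rows <- lapply(names(terms), function(tt) {
    tg <- intersect(terms[[tt]], universe)
    m <- length(intersect(tg, cand))
    if (m < 1) return(NULL)
    M <- length(tg)
    data.frame(term_id = tt, term_name = unname(term_names[tt]),
               m = m, M = M, n = n, N = N,
               p_value = hypergeom_p(m, M, n, N),
               rich_factor = m / M, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value <= q_cutoff
  res <- res[order(res$p_value, res$term_id),
             c("term_id", "term_name", "m", "M", "n", "N",
               "p_value", "q_value", "rich_factor", "significant")]
  rownames(res) <- NULL
  res
}

#' Write enrichment results as TSV
#' @param results data frame from [enrich()].
#' @param path output file.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bubble chart of enrichment results
#'
#' Rich factor on x, term on y; bubble area scales with the number of
#' candidate genes in the term, colour with the adjusted p-value.
#'
#' @param results data frame from [enrich()].
#' @param top show at most this many terms (by p-value).
#' @return a ggplot object.
#' @export
plot_enrichment <- function(results, top = 20) {
  d <- utils::head(results[order(results$p_value), ], top)
  d$term <- factor(d$term_name, levels = rev(d$term_name))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rich_factor, y = .data$term,
                                  size = .data$m, colour = .data$q_value)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = "rich factor", y = NULL, size = "genes",
                  colour = "Q value") +
    ggplot2::theme_bw()
}
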