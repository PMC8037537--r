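#' Term enrichment of a study gene set
#'
#' One-sided (enrichment-only) testing of every term with at least one study
#' hit: the Fisher exact p-value is the hypergeometric upper tail
#' `P(X >= k)` for `k` study hits out of a study of size `K`, against `n`
#' term genes in a population of size `N`; the EASE score is the conservative
#' DAVID variant computed after removing one study hit (tail at `k - 1`), and
#' Benjamini-Hochberg q-values control the FDR across terms.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of background gene ids.
#' @param term_map data.frame with columns term_id, term_name, gene_id;
#'   genes outside the population are ignored.
#' @return data.frame sorted by p_fisher with columns term_id, term_name, k,
#'   K, n, N, p_fisher, p_ease, q_benjamini.
#' @export
fisher_enrich <- function(study, population, term_map) {
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  missing <- setdiff(study, population)
  if (length(missing) > 0L)
    stop("study gene(s) absent from population: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  stopifnot(all(c("term_id", "gene_id") %in% names(term_map)))
  if (!"term_name" %in% names(term_map)) term_map$term_name <- term_map$term_id
  term_map <- term_map[term_map$gene_id %in% population, , drop = FALSE]
  K <- length(study); N <- length(population)
  empty <- data.frame(term_id = character(0L), term_name = character(0L),
                      k = integer(0L), K = integer(0L), n = integer(0L),
                      N = integer(0L), p_fisher = numeric(0L),
                      p_ease = numeric(0L), q_benjamini = numeric(0L),
                      stringsAsFactors = FALSE)
  if (nrow(term_map) == 0L) return(empty)
  term_map <- term_map[!duplicated(paste(term_map$term_id, term_map$gene_id)), ]
  genes_by_term <- split(term_map$gene_id, term_map$term_id)
  name_by_term <- vapply(split(term_map$term_name, term_map$term_id),
                         `[`, character(1L), 1L)
  rows <- lapply(names(genes_by_term), function(tid) {
    genes <- genes_by_term[[tid]]
    k <- sum(genes %in% study)
    if (k == 0L) return(NULL)
    n <- length(genes)
    data.frame(term_id = tid, term_name = name_by_term[[tid]],
               k = k, K = K, n = n, N = N,
               p_fisher = hyper_upper(k, K, n, N),
               p_ease = ease_p(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out)) return(empty)
  out$q_benjamini <- benjamini_hochberg(out$p_fisher)
  out[order(out$p_fisher, out$term_id), , drop = FALSE]
}

# hypergeometric upper tail P(X >= k)
hyper_upper <- function(k, K, n, N) {
  stats::phyper(k - 1L, n, N - n, K, lower.tail = FALSE)
}

#' EASE score (conservative Fisher variant)
#'
#' The hypergeometric upper tail with one study hit removed (`P(X >= k - 1)`),
#' so that single-gene overlaps are never significant; always >= the Fisher
#' p-value, and defined as 1 when `k` is 0 or 1.
#'
#' @param k study hits; `K` study size; `n` term (population) hits; `N`
#'   population size.
#' @param K,n,N see `k`.
#' @return probability.
#' @export
ease_p <- function(k, K, n, N) {
  stopifnot(k >= 0, k <= K, k <= n, n <= N, K <= N)
  if (k == 0L) return(1)
  hyper_upper(k - 1L, K, n, N)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR control: on sorted p-values, `q_(i) = min_{j >= i}
#' min(1, m p_(j) / j)`, restored to input order. Delegates to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0L))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("benjamini_hochberg: p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Filter enrichment rows at the study thresholds
#'
#' Keeps rows with `p_fisher < p_cut` and `q_benjamini < q_cut` (both 0.05 by
#' default) and `p_ease <= ease_cut` (0.1 by default).
#'
#' @param rows data.frame from [fisher_enrich()].
#' @param p_cut,q_cut,ease_cut thresholds.
#' @return filtered data.frame.
#' @export
filter_significant <- function(rows, p_cut = 0.05, q_cut = 0.05,
                               ease_cut = 0.1) {
  stopifnot(all(c("p_fisher", "q_benjamini", "p_ease") %in% names(rows)))
  rows[rows$p_fisher < p_cut & rows$q_benjamini < q_cut &
         rows$p_ease <= ease_cut, , drop = FALSE]
}
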