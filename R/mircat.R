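#' Extract the seed of a mature miRNA
#'
#' The seed spans nucleotides 2 through 8 of the mature sequence (7 nt), the
#' primary determinant of target recognition; all let-7 family matures share
#' the seed GAGGUAG.
#'
#' @param mature character vector of mature miRNA sequences, each >= 8 nt.
#' @return character vector of 7-nt seeds.
#' @export
#' @examples
#' extract_seed("UGAGGUAGUAGGUUGUAUAGUU")  # "GAGGUAG"
extract_seed <- function(mature) {
  mature <- as_rna(mature)
  if (any(nchar(mature) < 8L))
    stop("extract_seed: mature sequences must be at least 8 nt")
  substr(mature, 2L, 8L)
}

#' Group a miRNA catalogue into seed families
#'
#' Partitions the catalogue by exact seed equality, the grouping under which
#' all let-7 isoforms fall into one family and are expected to share targets.
#'
#' @param catalog data.frame with columns `id` and `seed` (or `mature`, from
#'   which seeds are derived).
#' @return named list mapping each seed to the member ids carrying it, ordered
#'   by seed.
#' @export
seed_families <- function(catalog) {
  stopifnot(is.data.frame(catalog), "id" %in% names(catalog))
  if (!"seed" %in% names(catalog)) {
    if (!"mature" %in% names(catalog))
      stop("catalog needs a 'seed' or 'mature' column")
    catalog$seed <- extract_seed(catalog$mature)
  }
  split(catalog$id, factor(catalog$seed, levels = sort(unique(catalog$seed))))
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman with linear gap penalty (default match +2, mismatch -3,
#' gap -5 per nt, Blastn-like). Co-optimal hits are tie-broken
#' deterministically by lowest subject start, then lowest query start.
#'
#' @param query,subject nucleotide strings.
#' @param match,mismatch,gap scoring parameters.
#' @return list with `score` and 1-based closed `q_start`, `q_end`, `s_start`,
#'   `s_end` (all 0 with score 0 when no positive-scoring hit exists).
#' @export
align_local <- function(query, subject, match = 2, mismatch = -3, gap = -5) {
  query <- as_rna(query); subject <- as_rna(subject)
  if (nchar(query) == 0L || nchar(subject) == 0L)
    stop("align_local: sequences must be non-empty")
  cw_smith_waterman(seq_to_int(query), seq_to_int(subject), match, mismatch, gap)
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance
#' alignments scoring at least S in a search of query length `m` against total
#' subject length `n`. Strictly decreasing in S and linear in m and n. The
#' defaults (`lambda` 0.625, `K` 0.41) are ungapped nucleotide values matched
#' to the +2/-3 scoring of [align_local()].
#'
#' @param S alignment score (>= 0).
#' @param m query length.
#' @param n total subject length.
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @return positive E-value.
#' @export
evalue <- function(S, m, n, lambda = 0.625, K = 0.41) {
  if (any(S < 0)) stop("evalue: S must be >= 0")
  if (any(m < 1) || any(n < 1)) stop("evalue: m and n must be >= 1")
  if (lambda <= 0 || K <= 0) stop("evalue: lambda and K must be positive")
  K * m * n * exp(-lambda * S)
}

#' Annotate unknown miRNA precursors against a mature catalogue
#'
#' Aligns each unknown precursor locally against every catalogued mature and
#' keeps the best hit (highest score; ties broken by lexicographic subject
#' id). An unknown is annotated iff its best-hit E-value clears `e_cut`
#' (default 1e-5, the conventional Blast significance threshold); the looser
#' secondary gate (E < 0.05 and S > 100) is reported alongside as a labelled
#' column rather than used for acceptance.
#'
#' @param unknowns named character vector of precursor sequences.
#' @param catalog named character vector of mature sequences.
#' @param e_cut primary E-value acceptance threshold.
#' @param lambda,K Karlin-Altschul parameters passed to [evalue()].
#' @param match,mismatch,gap scoring passed to [align_local()].
#' @return data.frame with one row per unknown: query_id, subject_id, score,
#'   evalue, accepted (E < e_cut), accepted_secondary (E < 0.05 and S > 100).
#' @export
annotate_precursors <- function(unknowns, catalog, e_cut = 1e-5,
                                lambda = 0.625, K = 0.41,
                                match = 2, mismatch = -3, gap = -5) {
  if (length(catalog) == 0L) stop("annotate_precursors: catalogue is empty")
  if (is.null(names(unknowns)) || is.null(names(catalog)))
    stop("annotate_precursors: unknowns and catalog must be named")
  n_total <- sum(nchar(catalog))
  subj_order <- sort(names(catalog))
  rows <- lapply(names(unknowns), function(qid) {
    q <- unknowns[[qid]]
    best <- NULL
    for (sid in subj_order) {
      hit <- align_local(q, catalog[[sid]], match, mismatch, gap)
      if (is.null(best) || hit$score > best$score) {
        best <- hit; best$sid <- sid
      }
    }
    e <- evalue(best$score, nchar(q), n_total, lambda, K)
    data.frame(query_id = qid, subject_id = best$sid, score = best$score,
               evalue = e, accepted = e < e_cut,
               accepted_secondary = e < 0.05 & best$score > 100,
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- data.frame(query_id = character(0L), subject_id = character(0L),
                      score = numeric(0L), evalue = numeric(0L),
                      accepted = logical(0L), accepted_secondary = logical(0L),
                      stringsAsFactors = FALSE)
  out
}
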