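# Independent oracles used to cross-check the package's dynamic-programming
# and statistical kernels. Deliberately simple and separate from the
# implementation paths they verify.

r_random_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len, TRUE),
                                    collapse = "")

# ---- alignment score oracles (Biostrings) ----------------------------------

bs_align_score <- function(a, b, type, match, mismatch, gap_per_nt) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(chartr("U", "T", a)),
    Biostrings::DNAString(chartr("U", "T", b)),
    type = type, substitutionMatrix = sub,
    gapOpening = 0, gapExtension = gap_per_nt, scoreOnly = TRUE)
}

# ---- hypergeometric tail by explicit summation ------------------------------

hyper_tail_bruteforce <- function(k, K, n, N) {
  xs <- seq(k, min(K, n))
  if (length(xs) == 0L || k > min(K, n)) return(0)
  sum(choose(n, xs) * choose(N - n, K - xs)) / choose(N, K)
}

# ---- independently coded Benjamini-Hochberg step-up -------------------------

bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    q_sorted[i] <- min(1, running)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# ---- exhaustive co-linear duplex pairing enumeration ------------------------

# all monotone matchings between positions 1..n and 1..m as list of 2-col
# matrices (possibly empty matching)
enum_matchings <- function(n, m) {
  out <- list(matrix(integer(0L), ncol = 2L))
  recurse <- function(i, j, acc) {
    if (i > n || j > m) return(invisible(NULL))
    for (ii in i:n) for (jj in j:m) {
      mat <- rbind(acc, c(ii, jj))
      out[[length(out) + 1L]] <<- mat
      recurse(ii + 1L, jj + 1L, mat)
    }
  }
  recurse(1L, 1L, matrix(integer(0L), ncol = 2L))
  out
}

# score one matching under the nearest-neighbor model; NA if invalid
score_matching <- function(mat, a_int, b_int, model) {
  pair_id <- function(x, y) {
    key <- paste(x, y)
    switch(key, "0 3" = 1L, "3 0" = 2L, "1 2" = 3L, "2 1" = 4L,
           "2 3" = 5L, "3 2" = 6L, NA_integer_)
  }
  if (nrow(mat) == 0L) return(model$init)
  ids <- mapply(function(i, j) pair_id(a_int[i], b_int[j]), mat[, 1L], mat[, 2L])
  if (anyNA(ids)) return(NA_real_)
  e <- model$init
  if (nrow(mat) > 1L) {
    for (r in 2:nrow(mat)) {
      di <- mat[r, 1L] - mat[r - 1L, 1L]
      dj <- mat[r, 2L] - mat[r - 1L, 2L]
      if (di - 1L > model$max_loop || dj - 1L > model$max_loop) return(NA_real_)
      if (di == 1L && dj == 1L) {
        e <- e + model$stack[ids[r - 1L], ids[r]]
      } else {
        extra <- (di - 1L) + (dj - 1L)
        e <- e + model$loop_open + model$loop_ext * (extra - 1L)
      }
    }
  }
  e
}

# minimum duplex energy by exhaustive enumeration (strings, context 5'->3')
enum_duplex_min <- function(mature, context, model) {
  a_int <- cernaweaver:::seq_to_int(mature)
  b_int <- rev(cernaweaver:::seq_to_int(context))
  scores <- vapply(enum_matchings(length(a_int), length(b_int)),
                   score_matching, numeric(1L), a_int = a_int, b_int = b_int,
                   model = model)
  min(scores, na.rm = TRUE)
}

# ---- exhaustive bulge-limited edit alignment --------------------------------

enum_tail_cost <- function(tail, rext, max_bulge) {
  t_int <- cernaweaver:::seq_to_int(tail)
  r_int <- cernaweaver:::seq_to_int(rext)
  n <- length(t_int); m <- length(r_int)
  explore <- function(i, j, g) {
    if (i > n) return(0)  # trailing rext is free
    best <- Inf
    if (j <= m)
      best <- min(best, (t_int[i] != r_int[j]) + explore(i + 1L, j + 1L, g))
    if (g < max_bulge)
      best <- min(best, 1 + explore(i + 1L, j, g + 1L))
    if (g < max_bulge && j <= m)
      best <- min(best, 1 + explore(i, j + 1L, g + 1L))
    best
  }
  explore(1L, 1L, 0L)
}

# ---- cubic couple enumeration ----------------------------------------------

couples_bruteforce <- function(graph) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  nd <- igraph::as_data_frame(graph, what = "vertices")
  mirnas <- nd$name[nd$type == "miRNA"]
  pgs <- nd$name[nd$type == "pseudogene"]
  genes <- nd$name[nd$type == "gene"]
  out <- list()
  for (m in mirnas) for (p in pgs) {
    has_seq <- any(ed$type == "sequesters" & ed$from == m & ed$to == p)
    if (!has_seq) next
    tg <- character(0L)
    for (g in genes)
      if (any(ed$type == "targets" & ed$from == m & ed$to == g))
        tg <- c(tg, g)
    if (length(tg) > 0L)
      out[[length(out) + 1L]] <- c(mirna = m, pseudogene = p)
  }
  out
}
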