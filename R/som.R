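#' One-hot encoding of a 7-nt miRNA seed
#'
#' Each position contributes four slots (A, C, G, U), giving a 28-dimensional
#' binary vector; the encoding is invertible and Euclidean distance between two
#' encodings is `sqrt(2 * Hamming distance)`.
#'
#' @param seq 7-nt RNA string (no IUPAC ambiguity).
#' @return numeric vector of length 28.
#' @export
encode_seed <- function(seq) {
  seq <- as_rna(seq)
  if (nchar(seq) != 7L) stop("encode_seed: seed must be exactly 7 nt")
  ints <- seq_to_int(seq)
  v <- numeric(28L)
  v[(seq_len(7L) - 1L) * 4L + ints + 1L] <- 1
  v
}

#' Invert [encode_seed()]
#' @param v numeric vector of length 28 (one-hot by position).
#' @return 7-nt RNA string.
#' @export
decode_seed <- function(v) {
  stopifnot(length(v) == 28L)
  m <- matrix(v, nrow = 4L)
  paste(RNA_BASES[apply(m, 2L, which.max)], collapse = "")
}

#' Default square lattice side for n inputs
#' @noRd
som_default_side <- function(n) max(1L, as.integer(ceiling(sqrt(5 * sqrt(n)))))

#' Train a self-organizing map on miRNA seeds
#'
#' A rectangular 2-D lattice of neurons is trained by batch competitive
#' learning on the one-hot seed encodings: each epoch assigns every seed to
#' its best-matching unit (BMU), then moves every neuron toward the
#' neighborhood-weighted mean of its assigned inputs under a Gaussian
#' neighborhood whose radius, like the learning rate, decays linearly over
#' the epochs. Batch updates make the result independent of input order;
#' the run is deterministic given `rng_seed`. BMU distance ties break to the
#' lowest neuron index (row-major).
#'
#' @param seeds character vector of 7-nt seeds; names (miRNA ids) are kept in
#'   the lattice's assignment table.
#' @param rows,cols lattice dimensions; default `ceiling(sqrt(5 * sqrt(n)))`
#'   per side.
#' @param epochs training epochs.
#' @param lr0 initial learning rate (decays linearly to 0.01).
#' @param radius0 initial neighborhood radius (decays linearly to 0.5);
#'   default `max(rows, cols) / 2`.
#' @param rng_seed integer seed for weight initialization.
#' @return a `som_lattice` list: `rows`, `cols`, `weights` (neurons x 28,
#'   row-major neuron order), `assign` (data.frame id, seed, bmu), `meta`.
#' @export
train_som <- function(seeds, rows = NULL, cols = NULL, epochs = 100L,
                      lr0 = 0.5, radius0 = NULL, rng_seed = 1L) {
  if (length(seeds) == 0L) stop("train_som: need at least one seed")
  seeds <- as_rna(seeds)
  if (is.null(names(seeds))) names(seeds) <- sprintf("seed_%03d", seq_along(seeds))
  n <- length(seeds)
  if (is.null(rows)) rows <- som_default_side(n)
  if (is.null(cols)) cols <- som_default_side(n)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("train_som: lattice must have >= 1 neuron")
  if (is.null(radius0)) radius0 <- max(rows, cols) / 2
  epochs <- as.integer(epochs)

  X <- t(vapply(seeds, encode_seed, numeric(28L)))  # n x 28
  N <- rows * cols
  # squared grid distances between neurons (row-major indexing)
  gr <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  G2 <- as.matrix(stats::dist(gr))^2

  W <- withr::with_seed(rng_seed, matrix(runif(N * 28L), nrow = N))
  sigma_end <- 0.5
  lr_end <- 0.01
  for (e in seq_len(epochs)) {
    frac <- if (epochs > 1L) (e - 1) / (epochs - 1) else 0
    sigma <- radius0 + frac * (sigma_end - radius0)
    alpha <- lr0 + frac * (lr_end - lr0)
    bmu <- som_bmu(X, W)
    H <- exp(-G2[, bmu, drop = FALSE] / (2 * sigma^2))  # N x n
    den <- rowSums(H)
    num <- H %*% X
    upd <- den > 1e-12
    target <- W
    target[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    W <- W + alpha * (target - W)
  }
  bmu <- som_bmu(X, W)
  lattice <- list(rows = rows, cols = cols, weights = W,
                  assign = data.frame(id = names(seeds), seed = unname(seeds),
                                      bmu = bmu, stringsAsFactors = FALSE),
                  meta = list(epochs = epochs, lr0 = lr0, radius0 = radius0,
                              rng_seed = rng_seed))
  class(lattice) <- "som_lattice"
  lattice
}

# best-matching unit (row-major neuron index) for each row of X; ties to the
# lowest index
som_bmu <- function(X, W) {
  # squared distances: ||x||^2 - 2 x.W + ||w||^2
  d2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * X %*% t(W)
  apply(d2, 1L, which.min)
}

# grid (Euclidean) distance between two row-major neuron indices
som_grid_dist <- function(i, j, rows, cols) {
  ri <- (i - 1L) %/% cols; ci <- (i - 1L) %% cols
  rj <- (j - 1L) %/% cols; cj <- (j - 1L) %% cols
  sqrt((ri - rj)^2 + (ci - cj)^2)
}

#' Mean quantization error of a lattice on a seed set
#' @param lattice a `som_lattice`.
#' @param seeds character vector of 7-nt seeds.
#' @return mean Euclidean distance from each encoding to its BMU weight.
#' @export
som_quantization_error <- function(lattice, seeds) {
  X <- t(vapply(as_rna(seeds), encode_seed, numeric(28L)))
  bmu <- som_bmu(X, lattice$weights)
  mean(sqrt(rowSums((X - lattice$weights[bmu, , drop = FALSE])^2)))
}

#' Project target fragments onto a trained lattice
#'
#' Slides a `seed_len` window with stride 1 over the searchable region of the
#' target (the annotated 3'UTR for protein-coding transcripts, the whole
#' sequence for pseudogenes), reverse-complements each window, encodes it and
#' finds its BMU. A window is a candidate site for every catalogued miRNA
#' whose seed maps to the same cluster; `neighborhood > 0` relaxes "same
#' cluster" to a grid radius.
#'
#' @param lattice trained `som_lattice` (with the catalogue in `$assign`).
#' @param target one-row data.frame (or list) with `id`, `biotype`,
#'   `sequence`, `utr3_start`, `utr3_end`.
#' @param seed_len window length (7).
#' @param neighborhood grid radius for cluster compatibility (default 0:
#'   shared BMU only).
#' @return data.frame with columns mirna_id, target_id, site_start, site_end
#'   (1-based closed, on the full target sequence).
#' @export
project_fragments <- function(lattice, target, seed_len = 7L, neighborhood = 0) {
  stopifnot(inherits(lattice, "som_lattice"))
  empty <- data.frame(mirna_id = character(0L), target_id = character(0L),
                      site_start = integer(0L), site_end = integer(0L),
                      stringsAsFactors = FALSE)
  seq <- as_rna(target$sequence)
  if (identical(as.character(target$biotype), "protein_coding") &&
      !is.na(target$utr3_start)) {
    lo <- as.integer(target$utr3_start); hi <- as.integer(target$utr3_end)
  } else {
    lo <- 1L; hi <- nchar(seq)
  }
  if (hi - lo + 1L < seed_len) return(empty)
  starts <- seq.int(lo, hi - seed_len + 1L)
  bmu <- window_bmu(seq, starts, seed_len, lattice$weights)

  cand <- lapply(seq_len(nrow(lattice$assign)), function(k) {
    sb <- lattice$assign$bmu[k]
    ok <- if (neighborhood > 0) {
      som_grid_dist(bmu, sb, lattice$rows, lattice$cols) <= neighborhood
    } else bmu == sb
    if (!any(ok)) return(NULL)
    data.frame(mirna_id = lattice$assign$id[k],
               target_id = as.character(target$id),
               site_start = starts[ok], site_end = starts[ok] + seed_len - 1L,
               stringsAsFactors = FALSE)
  })
  cand <- rbind_rows(cand)
  if (is.null(cand)) empty else cand
}

# BMU for the reverse complement of every window of length `seed_len`
# starting at `starts` (coordinates on `seq`)
window_bmu <- function(seq, starts, seed_len, W) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ints <- match(chars, RNA_BASES) - 1L
  wsq <- rowSums(W^2)
  vapply(starts, function(s) {
    win <- ints[s:(s + seed_len - 1L)]
    rc <- 3L - rev(win)                      # reverse complement in int code
    slots <- (seq_len(seed_len) - 1L) * 4L + rc + 1L
    dots <- rowSums(W[, slots, drop = FALSE])
    d2 <- seed_len - 2 * dots + wsq
    which.min(d2)
  }, integer(1L))
}
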