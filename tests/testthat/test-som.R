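test_that("seed encoding is one-hot, invertible, and isometric to Hamming", {
  v <- encode_seed("AAAAAAA")
  expect_equal(sum(v), 7)
  expect_equal(which(v == 1), (0:6) * 4 + 1)
  expect_error(encode_seed("AAANAAA"), "ACGU")
  expect_error(encode_seed("AAAA"), "exactly 7")
  withr::local_seed(11)
  for (i in 1:20) {
    s <- r_random_rna(7L)
    expect_equal(decode_seed(encode_seed(s)), s)
  }
  # Euclidean distance = sqrt(2 * Hamming) at every Hamming distance 1..7
  base <- "ACGUACG"
  chars <- strsplit(base, "")[[1L]]
  for (h in 1:7) {
    other <- chars
    for (p in seq_len(h)) other[p] <- setdiff(c("A", "C", "G", "U"), chars[p])[1L]
    d <- sqrt(sum((encode_seed(base) - encode_seed(paste(other, collapse = ""))) ^ 2))
    expect_equal(d, sqrt(2 * h))
  }
})

test_that("a single seed on a 1x1 grid converges to its encoding", {
  lat <- train_som(c(m1 = "GAGGUAG"), rows = 1L, cols = 1L, rng_seed = 1L)
  expect_lt(sqrt(sum((lat$weights[1L, ] - encode_seed("GAGGUAG"))^2)), 1e-6)
})

test_that("training is deterministic, order-independent, and reduces error", {
  withr::local_seed(12)
  seeds <- setNames(replicate(10L, r_random_rna(7L)), sprintf("m%02d", 1:10))
  a <- train_som(seeds, rng_seed = 7L)
  b <- train_som(seeds, rng_seed = 7L)
  expect_identical(a$weights, b$weights)
  # batch updates: permuting input order changes nothing
  perm <- sample(seq_along(seeds))
  c_ <- train_som(seeds[perm], rng_seed = 7L)
  expect_equal(a$weights, c_$weights)
  expect_equal(a$assign$bmu[match(names(seeds)[perm], a$assign$id)],
               c_$assign$bmu)
  # duplicate seeds share a BMU
  dup <- train_som(c(x = "ACGUACG", y = "ACGUACG", z = "UUUUUUU"), rng_seed = 3L)
  expect_equal(dup$assign$bmu[1L], dup$assign$bmu[2L])
  # quantization error does not increase over training
  untrained <- list(rows = a$rows, cols = a$cols,
                    weights = withr::with_seed(7L,
                      matrix(runif(a$rows * a$cols * 28L), ncol = 28L)))
  class(untrained) <- "som_lattice"
  expect_lte(som_quantization_error(a, seeds),
             som_quantization_error(untrained, seeds))
  # weights stay in [0, 1] after training on one-hot data
  expect_true(all(a$weights >= 0 & a$weights <= 1))
})

test_that("well-separated planted clusters are recovered on a 2x2 grid", {
  withr::local_seed(13)
  center1 <- "AAAAAAA"
  center2 <- "GGGGGGG"
  flip1 <- function(s) {  # one substitution => within-cluster Hamming <= 2
    p <- sample.int(7L, 1L)
    substr(s, p, p) <- sample(setdiff(c("C", "U"), substr(s, p, p)), 1L)
    s
  }
  seeds <- c(center1, replicate(4L, flip1(center1)),
             center2, replicate(4L, flip1(center2)))
  names(seeds) <- sprintf("s%02d", seq_along(seeds))
  truth <- rep(1:2, each = 5L)
  hits <- 0L
  for (r in 1:20) {
    lat <- train_som(seeds, rows = 2L, cols = 2L, rng_seed = r)
    bmu <- lat$assign$bmu
    ok <- length(unique(bmu[truth == 1L])) == 1L &&
      length(unique(bmu[truth == 2L])) == 1L &&
      bmu[1L] != bmu[6L]
    hits <- hits + ok
  }
  expect_gte(hits, 11L)  # majority of 20 random restarts
})

test_that("fragment projection finds exact seed complements and respects regions", {
  withr::local_seed(14)
  seeds <- setNames(replicate(6L, r_random_rna(7L)), sprintf("m%d", 1:6))
  lat <- train_som(seeds, rng_seed = 2L)
  w <- revcomp_rna(seeds[["m3"]])
  seq <- paste0(r_random_rna(50L), w, r_random_rna(20L))
  tgt <- data.frame(id = "t1", biotype = "pseudogene", sequence = seq,
                    utr3_start = NA_integer_, utr3_end = NA_integer_)
  cand <- project_fragments(lat, tgt)
  hit <- cand[cand$mirna_id == "m3" & cand$site_start == 51L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$site_end, 57L)
  # target shorter than the window gives an empty result
  short <- data.frame(id = "t2", biotype = "pseudogene", sequence = "ACGUA",
                      utr3_start = NA_integer_, utr3_end = NA_integer_)
  expect_equal(nrow(project_fragments(lat, short)), 0L)
  # mRNA search is restricted to the annotated 3'UTR
  m <- data.frame(id = "t3", biotype = "protein_coding",
                  sequence = paste0(w, r_random_rna(40L), w),
                  utr3_start = 41L, utr3_end = 54L)
  cm <- project_fragments(lat, m)
  expect_true(all(cm$site_start >= 41L))
  expect_true(any(cm$mirna_id == "m3" & cm$site_start == 48L))
})

test_that("candidates are a superset of exhaustive perfect seed matches", {
  withr::local_seed(15)
  seeds <- setNames(replicate(10L, r_random_rna(7L)), sprintf("m%02d", 1:10))
  lat <- train_som(seeds, rng_seed = 4L)
  for (i in 1:25) {
    seq <- r_random_rna(150L)
    tgt <- data.frame(id = "t", biotype = "pseudogene", sequence = seq,
                      utr3_start = NA_integer_, utr3_end = NA_integer_)
    cand <- project_fragments(lat, tgt)
    ck <- paste(cand$mirna_id, cand$site_start)
    for (m in names(seeds)) {
      w <- revcomp_rna(seeds[[m]])
      occ <- gregexpr(w, seq, fixed = TRUE)[[1L]]
      for (s in occ[occ > 0L]) expect_true(paste(m, s) %in% ck)
    }
  }
})
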