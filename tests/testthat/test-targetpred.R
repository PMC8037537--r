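test_that("tail dissimilarity handles the boundary cases", {
  tail <- "ACGUACGUACGUACG"
  expect_equal(tail_dissimilarity(tail, revcomp_rna(tail)), 0)
  # self (not complement): no A:A / C:C pairs exist under RNA rules
  expect_equal(tail_dissimilarity("AAAA", "AAAA"), 1)
  expect_equal(tail_dissimilarity("", "ACGU"), 0)  # empty tail convention
})

test_that("tail dissimilarity equals exhaustive bulge-limited alignment", {
  withr::local_seed(16)
  for (i in 1:12) {
    tail <- r_random_rna(12L)
    ext <- r_random_rna(15L)
    got <- tail_dissimilarity(tail, ext, max_bulge = 3L)
    oracle <- enum_tail_cost(tail, revcomp_rna(ext), 3L) / 12
    expect_equal(got, min(1, oracle))
  }
})

test_that("energy model loads with stabilizing stacks and editable penalties", {
  em <- energy_model()
  expect_true(all(em$stack <= 0))
  expect_equal(em$init, 4.09)
  expect_equal(em$stack["GC", "CG"], -3.42, ignore_attr = TRUE)
  expect_error(energy_model(loop_open = -1), "loop penalties")
})

test_that("duplex energy of a perfect helix equals the hand-summed stack total", {
  em <- energy_model()
  withr::local_seed(17)
  for (i in 1:5) {
    mature <- r_random_rna(22L)
    context <- revcomp_rna(mature)  # perfect 22-bp duplex
    got <- duplex_energy(mature, context, em)
    pair_of <- c(A = "AU", C = "CG", G = "GC", U = "UA")
    pairs <- pair_of[strsplit(mature, "")[[1L]]]
    hand <- em$init + sum(vapply(seq_len(21L), function(k) {
      em$stack[pairs[k], pairs[k + 1L]]
    }, numeric(1L)))
    expect_equal(got, hand)
  }
})

test_that("duplex DP attains the exhaustive-pairing minimum on short duplexes", {
  em <- energy_model()
  withr::local_seed(18)
  for (i in 1:6) {
    a <- r_random_rna(7L)
    b <- r_random_rna(8L)
    got <- duplex_energy(a, b, em)
    oracle <- enum_duplex_min(a, b, em)
    expect_equal(got, oracle)
    # DP result is a lower bound on every explicitly enumerated pairing
    expect_lte(got, oracle + 1e-12)
  }
  # no complementary pairing possible (A against A): deltaG is initiation
  expect_equal(duplex_energy("AAAA", "AAAA", em), em$init)
})

test_that("prediction recovers planted sites with high sensitivity", {
  cfg <- synth_config(n_mrna = 100L, n_mirna = 20L, n_pseudogene = 0L,
                      planted_sites_per_utr = 1L, rng_seed = 42L)
  b <- gen_transcriptome(cfg)
  preds <- predict_targets(b$mirnas, b$transcripts, som_seed = 42L)
  expect_true(all(preds$deltaG < -12))
  truth <- b$truth$planted_interactions
  tk <- with(truth, paste(mirna_id, target_id, site_start, site_end))
  pk <- with(preds, paste(mirna_id, target_id, site_start, site_end))
  sens <- mean(tk %in% pk)
  expect_gte(sens, 0.9)
})

test_that("empty inputs give empty predictions", {
  cfg <- synth_config(n_mrna = 2L, n_mirna = 2L, n_pseudogene = 0L,
                      rng_seed = 1L)
  b <- gen_transcriptome(cfg)
  expect_equal(nrow(predict_targets(b$mirnas, b$transcripts[0L, ])), 0L)
  expect_equal(nrow(predict_targets(b$mirnas[0L, ], b$transcripts)), 0L)
})

test_that("filters are monotone in their thresholds", {
  cfg <- synth_config(n_mrna = 25L, n_mirna = 8L, n_pseudogene = 5L,
                      rng_seed = 21L)
  b <- gen_transcriptome(cfg)
  all_cand <- predict_targets(b$mirnas, b$transcripts, som_seed = 21L,
                              keep_all = TRUE)
  key <- function(d) paste(d$mirna_id, d$target_id, d$site_start)
  filt <- function(tau, cut) {
    all_cand[all_cand$dissimilarity <= tau & all_cand$deltaG < cut, ]
  }
  # tightening the deltaG cut never adds interactions
  expect_true(all(key(filt(0.3, -20)) %in% key(filt(0.3, -12))))
  # raising tau never removes candidates entering the energy stage
  expect_true(all(key(filt(0.2, -12)) %in% key(filt(0.4, -12))))
  # filtered output equals the pipeline's own filtering
  direct <- predict_targets(b$mirnas, b$transcripts, som_seed = 21L,
                            tau = 0.3, dg_cut = -12)
  expect_setequal(key(direct), key(filt(0.3, -12)))
})

test_that("prediction is deterministic under a fixed SOM seed", {
  cfg <- synth_config(n_mrna = 15L, n_mirna = 6L, n_pseudogene = 3L,
                      rng_seed = 33L)
  b <- gen_transcriptome(cfg)
  p1 <- predict_targets(b$mirnas, b$transcripts, som_seed = 9L)
  p2 <- predict_targets(b$mirnas, b$transcripts, som_seed = 9L)
  expect_identical(p1, p2)
})
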