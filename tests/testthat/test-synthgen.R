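test_that("empty configuration yields empty, consistent output", {
  cfg <- synth_config(n_mrna = 0L, n_mirna = 0L, n_pseudogene = 0L)
  b <- gen_transcriptome(cfg)
  expect_equal(nrow(b$transcripts), 0L)
  expect_equal(nrow(b$mirnas), 0L)
  expect_equal(nrow(b$truth$planted_interactions), 0L)
  expect_equal(nrow(b$truth$planted_elements), 0L)
  expect_equal(nrow(b$truth$pseudogene_parents), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_mrna = -1), "non-negative")
  expect_error(synth_config(identity_range = c(0.9, 1.2)), "identity_range")
  expect_error(synth_config(utr_len_range = c(3, 100)), "utr_len_range")
  expect_error(synth_config(mature_len = 30), "mature_len")
  expect_error(synth_config(planted_elements = "NOPE"), NA)
  expect_error(gen_transcriptome(synth_config(planted_elements = "NOPE",
                                              n_mrna = 1L)),
               "unknown planted element")
})

test_that("generation is byte-reproducible under a fixed seed", {
  cfg <- synth_config(n_mrna = 8L, n_mirna = 4L, n_pseudogene = 2L,
                      planted_elements = c("ARE", "GAIT"), rng_seed = 99L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synth_bundle(gen_transcriptome(cfg), d1)
  write_synth_bundle(gen_transcriptome(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("each planted site is the unique seed complement in its 3'UTR", {
  cfg <- synth_config(n_mrna = 60L, n_mirna = 12L, n_pseudogene = 0L,
                      planted_sites_per_utr = 1L, rng_seed = 5L)
  b <- gen_transcriptome(cfg)
  ti <- b$truth$planted_interactions
  expect_equal(nrow(ti), 60L)
  for (i in seq_len(nrow(ti))) {
    r <- b$transcripts[b$transcripts$id == ti$target_id[i], ]
    utr <- substr(r$sequence, r$utr3_start, r$utr3_end)
    w <- revcomp_rna(b$mirnas$seed[b$mirnas$id == ti$mirna_id[i]])
    occ <- gregexpr(w, utr, fixed = TRUE)[[1L]]
    occ <- occ[occ > 0L]
    # exactly one occurrence, exhaustive substring scan
    expect_equal(length(occ), 1L)
    expect_equal(occ + r$utr3_start - 1L, ti$site_start[i],
                 ignore_attr = TRUE)
    # truth window lies inside the annotated 3'UTR and re-slices to the
    # seed complement
    expect_true(ti$site_start[i] >= r$utr3_start &&
                  ti$site_end[i] <= r$utr3_end)
    expect_equal(substr(r$sequence, ti$site_start[i], ti$site_end[i]), w)
  }
})

test_that("mutate_copy realizes the rounded identity exactly, substitutions only", {
  withr::local_seed(1)
  s <- r_random_rna(1000L)
  out <- mutate_copy(s, 0.95)
  expect_equal(nchar(out), 1000L)
  diffs <- sum(strsplit(s, "")[[1L]] != strsplit(out, "")[[1L]])
  expect_equal(diffs, 50L)  # brute-force position-wise diff
  expect_identical(mutate_copy(s, 1.0), s)
  none <- mutate_copy("AAAA", 0.0)
  expect_false(grepl("A", none, fixed = TRUE))
  # realized identity matches round(len * target) / len across targets
  for (target in c(0.94, 0.97, 0.99)) {
    s2 <- r_random_rna(73L)
    out2 <- mutate_copy(s2, target)
    got <- mean(strsplit(s2, "")[[1L]] == strsplit(out2, "")[[1L]])
    expect_equal(got, round(73L * target) / 73L)
  }
})

test_that("hairpin precursors embed the mature and a near-complement arm", {
  withr::local_seed(2)
  mature <- r_random_rna(22L)
  pre <- make_hairpin(mature, 15L)
  expect_equal(nchar(pre), 59L)  # 22 + 15 + 22
  expect_equal(substr(pre, 1L, 22L), mature)
  arm <- substr(pre, 38L, 59L)
  mm <- sum(strsplit(arm, "")[[1L]] != strsplit(revcomp_rna(mature), "")[[1L]])
  expect_lte(mm, 3L)  # brute-force mismatch count on the 3' arm
  expect_error(make_hairpin(mature, 0L), "loop_len")
  expect_error(make_hairpin("ACGU", 15L), "mature length")
})

test_that("pseudogene identity is recoverable from the truth table", {
  cfg <- synth_config(n_mrna = 10L, n_mirna = 3L, n_pseudogene = 6L,
                      rng_seed = 31L)
  b <- gen_transcriptome(cfg)
  pp <- b$truth$pseudogene_parents
  expect_equal(nrow(pp), 6L)
  expect_true(all(pp$realized_identity >= 0.94 - 1e-9))
  for (i in seq_len(nrow(pp))) {
    child <- b$transcripts$sequence[b$transcripts$id == pp$pseudogene_id[i]]
    parent <- b$transcripts$sequence[b$transcripts$id == pp$parent_id[i]]
    got <- percent_identity(child, parent)
    expect_equal(got$identity, pp$realized_identity[i],
                 tolerance = 1 / nchar(parent))
  }
})
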