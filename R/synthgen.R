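#' Synthetic transcriptome configuration
#'
#' Builds and validates the configuration for [gen_transcriptome()]. The
#' defaults describe the study conditions the downstream analysis assumes:
#' protein-coding transcripts with annotated 3'UTRs carrying planted miRNA
#' response elements (a perfect 7-nt seed complement plus an adjacent
#' tail-pairing region of configurable complementarity), hairpin miRNA
#' precursors embedding their mature sequence, and pseudogenes generated as
#' high-identity (94-100%) mutated copies of parent mRNAs.
#'
#' @param n_mrna,n_mirna,n_pseudogene record counts (non-negative).
#' @param utr_len_range 3'UTR length interval in nt.
#' @param cds_len_range coding-region length interval in nt.
#' @param mature_len mature miRNA length in nt (18-25).
#' @param precursor_loop_len hairpin loop length in nt (>= 3; the default 15
#'   yields 59-nt precursors with a 22-nt mature, inside the 59-77 nt band).
#' @param identity_range pseudogene-to-parent identity interval, in
#'   `[0, 1]`.
#' @param planted_sites_per_utr either a single non-negative integer (fixed
#'   count) or a function `f(n)` returning `n` integer counts.
#' @param planted_elements character vector of cis-element names from the
#'   motif table to plant once per mRNA 3'UTR.
#' @param tail_complementarity fraction of tail positions planted as perfect
#'   complement (default 0.7, so the free-energy filter has signal).
#' @param tail_mismatch_placement `"distal"` (default) degrades pairing at the
#'   seed-distal end, emulating canonical seed plus 3'-supplementary pairing;
#'   `"random"` scatters the mismatches.
#' @param composition background base composition over A, C, G, U.
#' @param motif_table motif definitions used when planting elements; defaults
#'   to [default_motif_table()].
#' @param rng_seed integer seed; identical configs give identical output.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_mrna = 100L, n_mirna = 20L, n_pseudogene = 10L,
                         utr_len_range = c(150L, 300L),
                         cds_len_range = c(200L, 400L),
                         mature_len = 22L, precursor_loop_len = 15L,
                         identity_range = c(0.94, 1.00),
                         planted_sites_per_utr = 1L,
                         planted_elements = character(0L),
                         tail_complementarity = 0.7,
                         tail_mismatch_placement = c("distal", "random"),
                         composition = rep(0.25, 4L),
                         motif_table = NULL,
                         rng_seed = 1L) {
  cfg <- list(
    n_mrna = as.integer(n_mrna), n_mirna = as.integer(n_mirna),
    n_pseudogene = as.integer(n_pseudogene),
    utr_len_range = as.integer(utr_len_range),
    cds_len_range = as.integer(cds_len_range),
    mature_len = as.integer(mature_len),
    precursor_loop_len = as.integer(precursor_loop_len),
    identity_range = as.numeric(identity_range),
    planted_sites_per_utr = planted_sites_per_utr,
    planted_elements = as.character(planted_elements),
    tail_complementarity = as.numeric(tail_complementarity),
    tail_mismatch_placement = match.arg(tail_mismatch_placement),
    composition = as.numeric(composition),
    motif_table = motif_table,
    rng_seed = as.integer(rng_seed))
  if (any(c(cfg$n_mrna, cfg$n_mirna, cfg$n_pseudogene) < 0L))
    stop("synth_config: counts must be non-negative")
  if (length(cfg$utr_len_range) != 2L || cfg$utr_len_range[1L] > cfg$utr_len_range[2L] ||
      cfg$utr_len_range[1L] < 7L)
    stop("synth_config: utr_len_range must be an increasing interval with min >= seed length (7)")
  if (length(cfg$identity_range) != 2L || any(cfg$identity_range < 0) ||
      any(cfg$identity_range > 1) || cfg$identity_range[1L] > cfg$identity_range[2L])
    stop("synth_config: identity_range must be an increasing interval inside [0, 1]")
  if (cfg$mature_len < 18L || cfg$mature_len > 25L)
    stop("synth_config: mature_len must be 18-25 nt")
  if (cfg$precursor_loop_len < 3L)
    stop("synth_config: precursor_loop_len must be >= 3 nt")
  if (cfg$tail_complementarity < 0 || cfg$tail_complementarity > 1)
    stop("synth_config: tail_complementarity must be in [0, 1]")
  if (length(cfg$composition) != 4L || any(cfg$composition < 0) ||
      sum(cfg$composition) <= 0)
    stop("synth_config: composition must be four non-negative weights")
  if (is.function(cfg$planted_sites_per_utr)) {
    # accepted as-is; sampled at generation time
  } else if (length(cfg$planted_sites_per_utr) == 1L &&
             !is.na(cfg$planted_sites_per_utr) && cfg$planted_sites_per_utr >= 0) {
    cfg$planted_sites_per_utr <- as.integer(cfg$planted_sites_per_utr)
  } else {
    stop("synth_config: planted_sites_per_utr must be a count or a sampler function")
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Mutate a sequence to a target identity by substitutions
#'
#' Exactly `len - round(len * identity_target)` positions are substituted with
#' a different base, so the realized identity is `round(len * identity) / len`.
#' Output length always equals input length. Randomness is drawn from the
#' current RNG stream.
#'
#' @param seq non-empty RNA string.
#' @param identity_target fraction in `[0, 1]`.
#' @return mutated RNA string of the same length.
#' @export
mutate_copy <- function(seq, identity_target) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L,
            identity_target >= 0, identity_target <= 1)
  len <- nchar(seq)
  n_mut <- len - as.integer(round(len * identity_target))
  if (n_mut == 0L) return(seq)
  pos <- sample.int(len, n_mut)
  mutate_positions(seq, pos)
}

# substitute the given positions with a different base each
mutate_positions <- function(seq, pos) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    alt <- setdiff(RNA_BASES, chars[p])
    chars[p] <- alt[sample.int(3L, 1L)]
  }
  paste(chars, collapse = "")
}

#' Build a synthetic hairpin miRNA precursor
#'
#' The precursor is `mature + loop + near-reverse-complement of mature`: the
#' 3' arm is the reverse complement of the mature carrying 1-3 substitutions
#' (`arm_mismatches`), as in natural pre-miRNA stems. With the default 22-nt
#' mature and 15-nt loop the precursor is 59 nt, inside the 59-77 nt band
#' typical of the catalogued precursors.
#'
#' @param mature mature miRNA sequence, 18-25 nt.
#' @param loop_len loop length in nt, >= 3.
#' @param arm_mismatches number of substitutions on the 3' arm (0-3); if `NULL`
#'   a value in 1-3 is drawn from the current RNG stream.
#' @return precursor RNA string containing `mature` as an exact prefix.
#' @export
make_hairpin <- function(mature, loop_len, arm_mismatches = NULL) {
  mature <- as_rna(mature)
  if (nchar(mature) < 18L || nchar(mature) > 25L)
    stop("make_hairpin: mature length must be 18-25 nt")
  loop_len <- as.integer(loop_len)
  if (is.na(loop_len) || loop_len < 3L)
    stop("make_hairpin: loop_len must be >= 3 nt")
  if (is.null(arm_mismatches)) arm_mismatches <- sample.int(3L, 1L)
  arm_mismatches <- as.integer(arm_mismatches)
  if (arm_mismatches < 0L || arm_mismatches > 3L)
    stop("make_hairpin: arm_mismatches must be 0-3")
  loop <- random_rna(loop_len)
  arm <- revcomp_rna(mature)
  if (arm_mismatches > 0L)
    arm <- mutate_positions(arm, sample.int(nchar(arm), arm_mismatches))
  paste0(mature, loop, arm)
}

# expand one IUPAC code to its RNA bases
iupac_bases <- function(code) {
  map <- list(A = "A", C = "C", G = "G", U = "U",
              R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
              W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
              B = c("C", "G", "U"), D = c("A", "G", "U"),
              H = c("A", "C", "U"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "U"))
  out <- map[[code]]
  if (is.null(out)) stop("unknown IUPAC code: ", code)
  out
}

# IUPAC pattern -> plain regex character classes
iupac_to_regex <- function(pattern) {
  chars <- strsplit(as_rna(pattern, allow_iupac = TRUE), "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    b <- iupac_bases(ch)
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

# draw one concrete instance of an IUPAC pattern
instantiate_iupac <- function(pattern) {
  chars <- strsplit(as_rna(pattern, allow_iupac = TRUE), "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    b <- iupac_bases(ch)
    b[sample.int(length(b), 1L)]
  }, character(1L)), collapse = "")
}

#' Generate a synthetic transcriptome with known ground truth
#'
#' Emits protein-coding transcripts whose 3'UTRs carry planted miRNA response
#' elements and cis-elements, hairpin miRNA precursors with their matures, and
#' pseudogenes as mutated parent copies, together with a truth table recording
#' every planted feature. Deterministic given `config$rng_seed`.
#'
#' Each planted miRNA site is written as `[tail-pairing region][seed
#' complement]`: a perfect reverse complement of the 7-nt seed, preceded
#' (5'-ward on the target, matching antiparallel duplex geometry) by the
#' reverse complement of the miRNA tail degraded to the configured
#' complementarity. The truth table records the seed-complement window, and
#' background occurrences of a planting miRNA's seed complement elsewhere in
#' the same 3'UTR are scrubbed so the recorded sites are exhaustive.
#'
#' @param config a [synth_config()].
#' @return a `synth_bundle` list with elements `transcripts` (data.frame: id,
#'   biotype, sequence, utr3_start, utr3_end, parent_id), `mirnas` (data.frame:
#'   id, precursor, mature, seed, conserved) and `truth` (list of data.frames
#'   `planted_interactions`, `planted_elements`, `pseudogene_parents`).
#' @export
gen_transcriptome <- function(config) {
  if (!inherits(config, "synth_config")) stop("config must be a synth_config")
  withr::with_seed(config$rng_seed, gen_transcriptome_impl(config))
}

gen_transcriptome_impl <- function(cfg) {
  motifs <- if (is.null(cfg$motif_table)) default_motif_table() else cfg$motif_table
  if (length(cfg$planted_elements) > 0L &&
      !all(cfg$planted_elements %in% motifs$name))
    stop("unknown planted element name(s): ",
         paste(setdiff(cfg$planted_elements, motifs$name), collapse = ", "))

  # --- miRNA catalogue -------------------------------------------------------
  mirnas <- data.frame(id = character(0L), precursor = character(0L),
                       mature = character(0L), seed = character(0L),
                       conserved = logical(0L), stringsAsFactors = FALSE)
  if (cfg$n_mirna > 0L) {
    ids <- sprintf("mir_%03d", seq_len(cfg$n_mirna))
    mature <- vapply(ids, function(i) random_rna(cfg$mature_len, cfg$composition),
                     character(1L))
    precursor <- vapply(mature, make_hairpin, character(1L),
                        loop_len = cfg$precursor_loop_len)
    mirnas <- data.frame(id = ids, precursor = unname(precursor),
                         mature = unname(mature),
                         seed = extract_seed(unname(mature)),
                         conserved = FALSE, stringsAsFactors = FALSE)
  }

  # --- mRNAs with planted features ------------------------------------------
  tr <- list(); ints <- list(); elts <- list()
  tail_len <- cfg$mature_len - 8L
  site_len <- 7L + tail_len
  n_sites <- if (is.function(cfg$planted_sites_per_utr)) {
    as.integer(cfg$planted_sites_per_utr(cfg$n_mrna))
  } else rep(cfg$planted_sites_per_utr, cfg$n_mrna)
  if (cfg$n_mrna > 0L && any(n_sites > 0L) && cfg$n_mirna == 0L)
    stop("cannot plant miRNA sites without miRNAs (n_mirna = 0)")

  for (i in seq_len(cfg$n_mrna)) {
    id <- sprintf("mrna_%04d", i)
    cds_len <- sample_range(cfg$cds_len_range)
    utr_len <- sample_range(cfg$utr_len_range)
    utr <- random_rna(utr_len, cfg$composition)
    occupied <- matrix(numeric(0L), ncol = 2L)  # reserved [start, end] in UTR

    # elements first, one instance of each configured class
    for (el in cfg$planted_elements) {
      def <- motifs[motifs$name == el, , drop = FALSE]
      core <- instantiate_iupac(def$pattern)
      if (isTRUE(def$requires_hairpin)) {
        stem <- random_rna(max(def$min_stem, 5L), cfg$composition)
        planted <- paste0(stem, core, revcomp_rna(stem))
        core_off <- nchar(stem)
      } else {
        planted <- core
        core_off <- 0L
      }
      pos <- place_interval(utr_len, nchar(planted), occupied)
      if (is.na(pos)) next  # UTR too crowded; element skipped for this gene
      occupied <- rbind(occupied, c(pos, pos + nchar(planted) - 1L))
      substr(utr, pos, pos + nchar(planted) - 1L) <- planted
      elts[[length(elts) + 1L]] <- data.frame(
        transcript_id = id, element_name = el,
        start = cds_len + pos + core_off,
        end = cds_len + pos + core_off + nchar(core) - 1L,
        stringsAsFactors = FALSE)
    }

    # planted miRNA response elements
    k <- n_sites[i]
    mir_idx <- if (k > 0L) {
      sample.int(cfg$n_mirna, k, replace = k > cfg$n_mirna)
    } else integer(0L)
    for (m in mir_idx) {
      seed <- mirnas$seed[m]
      tail <- substr(mirnas$mature[m], 9L, cfg$mature_len)
      w <- revcomp_rna(seed)
      ext <- revcomp_rna(tail)
      n_mis <- tail_len - as.integer(round(tail_len * cfg$tail_complementarity))
      if (n_mis > 0L) {
        mis_pos <- if (cfg$tail_mismatch_placement == "distal") {
          seq_len(n_mis)  # 5'-most extension positions pair the seed-distal tail
        } else sample.int(tail_len, n_mis)
        ext <- mutate_positions(ext, mis_pos)
      }
      site <- paste0(ext, w)
      pos <- place_interval(utr_len, site_len, occupied)
      if (is.na(pos)) next
      occupied <- rbind(occupied, c(pos, pos + site_len - 1L))
      substr(utr, pos, pos + site_len - 1L) <- site
      ints[[length(ints) + 1L]] <- data.frame(
        mirna_id = mirnas$id[m], target_id = id,
        site_start = cds_len + pos + tail_len,
        site_end = cds_len + pos + tail_len + 6L,
        stringsAsFactors = FALSE)
    }

    # scrub accidental background matches of planted element patterns (they
    # could shadow a planted instance under leftmost non-overlapping
    # selection), then of planted seed complements
    for (el in cfg$planted_elements) {
      pat <- iupac_to_regex(motifs$pattern[motifs$name == el])
      utr <- scrub_spurious(utr, pat, occupied, fixed = FALSE)
    }
    for (m in unique(mir_idx)) {
      w <- revcomp_rna(mirnas$seed[m])
      utr <- scrub_spurious(utr, w, occupied)
    }

    tr[[length(tr) + 1L]] <- data.frame(
      id = id, biotype = "protein_coding",
      sequence = paste0(random_rna(cds_len, cfg$composition), utr),
      utr3_start = cds_len + 1L, utr3_end = cds_len + utr_len,
      parent_id = NA_character_, stringsAsFactors = FALSE)
  }

  # --- pseudogenes as mutated parent copies ---------------------------------
  pg <- list(); parents <- list()
  if (cfg$n_pseudogene > 0L) {
    if (cfg$n_mrna == 0L) stop("cannot generate pseudogenes without parent mRNAs")
    par_idx <- sample.int(cfg$n_mrna, cfg$n_pseudogene,
                          replace = cfg$n_pseudogene > cfg$n_mrna)
    for (j in seq_len(cfg$n_pseudogene)) {
      id <- sprintf("pseudo_%03d", j)
      parent <- tr[[par_idx[j]]]
      target <- runif(1L, cfg$identity_range[1L], cfg$identity_range[2L])
      seq <- mutate_copy(parent$sequence, target)
      len <- nchar(seq)
      pg[[j]] <- data.frame(
        id = id, biotype = "pseudogene", sequence = seq,
        utr3_start = NA_integer_, utr3_end = NA_integer_,
        parent_id = parent$id, stringsAsFactors = FALSE)
      parents[[j]] <- data.frame(
        pseudogene_id = id, parent_id = parent$id,
        realized_identity = round(len * target) / len,
        stringsAsFactors = FALSE)
    }
  }

  empty_ints <- data.frame(mirna_id = character(0L), target_id = character(0L),
                           site_start = integer(0L), site_end = integer(0L),
                           stringsAsFactors = FALSE)
  empty_elts <- data.frame(transcript_id = character(0L),
                           element_name = character(0L), start = integer(0L),
                           end = integer(0L), stringsAsFactors = FALSE)
  empty_par <- data.frame(pseudogene_id = character(0L), parent_id = character(0L),
                          realized_identity = numeric(0L), stringsAsFactors = FALSE)
  transcripts <- if (length(tr) + length(pg) > 0L) {
    do.call(rbind, c(tr, pg))
  } else {
    data.frame(id = character(0L), biotype = character(0L),
               sequence = character(0L), utr3_start = integer(0L),
               utr3_end = integer(0L), parent_id = character(0L),
               stringsAsFactors = FALSE)
  }
  out <- list(
    transcripts = transcripts,
    mirnas = mirnas,
    truth = list(
      planted_interactions = if (length(ints)) do.call(rbind, ints) else empty_ints,
      planted_elements = if (length(elts)) do.call(rbind, elts) else empty_elts,
      pseudogene_parents = if (length(parents)) do.call(rbind, parents) else empty_par),
    config = cfg)
  class(out) <- "synth_bundle"
  out
}

sample_range <- function(range) {
  if (range[1L] == range[2L]) return(range[1L])
  sample(seq(range[1L], range[2L]), 1L)
}

# pick a start so [start, start+len-1] fits in 1..total without touching
# `occupied` intervals; NA if no slot found after a bounded number of draws
place_interval <- function(total, len, occupied, tries = 200L) {
  if (len > total) return(NA_integer_)
  for (t in seq_len(tries)) {
    s <- sample.int(total - len + 1L, 1L)
    e <- s + len - 1L
    if (nrow(occupied) == 0L ||
        all(e < occupied[, 1L] | s > occupied[, 2L])) return(s)
  }
  NA_integer_
}

# re-randomize background bases until `pattern` (fixed string or regex of
# fixed width) occurs only at planted positions, never touching reserved
# intervals
scrub_spurious <- function(utr, pattern, occupied, max_rounds = 50L,
                           fixed = TRUE) {
  plen <- nchar(gsub("\\[[^]]*\\]", "N", pattern))
  for (round in seq_len(max_rounds)) {
    hits <- gregexpr(pattern, utr, fixed = fixed)[[1L]]
    hits <- hits[hits > 0L]
    # planted occurrences lie fully inside a reserved interval; others are noise
    spurious <- hits[vapply(hits, function(s) {
      nrow(occupied) == 0L ||
        !any(s >= occupied[, 1L] & (s + plen - 1L) <= occupied[, 2L])
    }, logical(1L))]
    if (length(spurious) == 0L) return(utr)
    for (s in spurious) {
      cand <- seq(s, s + plen - 1L)
      free <- cand[vapply(cand, function(p) {
        nrow(occupied) == 0L || !any(p >= occupied[, 1L] & p <= occupied[, 2L])
      }, logical(1L))]
      if (length(free) == 0L) next
      p <- free[sample.int(length(free), 1L)]
      substr(utr, p, p) <- mutate_positions(substr(utr, p, p), 1L)
    }
  }
  utr
}

#' Write a synthetic bundle to disk
#'
#' Emits `transcripts.fasta`, `matures.fasta`, `precursors.fasta`, an
#' `annotation.tsv` (id, biotype, utr3_start, utr3_end, parent_id) and the
#' truth tables as TSV, all with 1-based closed coordinates.
#'
#' @param bundle a `synth_bundle` from [gen_transcriptome()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synth_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    transcripts = file.path(dir, "transcripts.fasta"),
    matures = file.path(dir, "matures.fasta"),
    precursors = file.path(dir, "precursors.fasta"),
    annotation = file.path(dir, "annotation.tsv"),
    truth_interactions = file.path(dir, "truth_planted_interactions.tsv"),
    truth_elements = file.path(dir, "truth_planted_elements.tsv"),
    truth_parents = file.path(dir, "truth_pseudogene_parents.tsv"))
  tx <- bundle$transcripts
  write_fasta_rna(setNames(tx$sequence, tx$id), paths[["transcripts"]])
  write_fasta_rna(setNames(bundle$mirnas$mature, bundle$mirnas$id),
                  paths[["matures"]])
  write_fasta_rna(setNames(bundle$mirnas$precursor, bundle$mirnas$id),
                  paths[["precursors"]])
  write_tsv(tx[, c("id", "biotype", "utr3_start", "utr3_end", "parent_id")],
            paths[["annotation"]])
  write_tsv(bundle$truth$planted_interactions, paths[["truth_interactions"]])
  write_tsv(bundle$truth$planted_elements, paths[["truth_elements"]])
  write_tsv(bundle$truth$pseudogene_parents, paths[["truth_parents"]])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Generate a synthetic term map for enrichment testing
#'
#' Draws `n_terms` gene sets uniformly at random from `genes`, the simplest
#' null in which no term is enriched in any random study set.
#'
#' @param genes population gene ids.
#' @param n_terms number of terms.
#' @param size_range term size interval.
#' @return data.frame with columns term_id, term_name, gene_id.
#' @export
gen_term_map <- function(genes, n_terms = 50L, size_range = c(5L, 40L)) {
  stopifnot(length(genes) > 0L, n_terms >= 0L)
  size_range[2L] <- min(size_range[2L], length(genes))
  size_range[1L] <- min(size_range[1L], size_range[2L])
  rows <- lapply(seq_len(n_terms), function(t) {
    sz <- sample_range(size_range)
    data.frame(term_id = sprintf("TERM:%04d", t),
               term_name = sprintf("synthetic term %d", t),
               gene_id = sample(genes, sz), stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(term_id = character(0L), term_name = character(0L),
                      gene_id = character(0L), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
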