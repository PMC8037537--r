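#' Load the RNA/RNA duplex energy model
#'
#' Reads the packaged nearest-neighbor stack table (Watson-Crick plus GU
#' wobble, kcal/mol; all stacks stabilizing) and combines it with the duplex
#' initiation penalty and the loop/bulge cost. Point `path` at an edited copy
#' to change the energy semantics of the deltaG filter.
#'
#' @param path stack-table TSV (columns pair1, pair2, dg); defaults to the
#'   packaged table.
#' @param init duplex initiation free energy, kcal/mol.
#' @param loop_open penalty per bulge/internal-loop event, kcal/mol.
#' @param loop_ext additional penalty per extra unpaired nucleotide, kcal/mol.
#' @param max_loop maximum unpaired nucleotides per strand between two pairs.
#' @return an `energy_model` list with the 6x6 stack matrix (pair order AU,
#'   UA, CG, GC, GU, UG), `init`, `loop_open`, `loop_ext`, `max_loop`.
#' @export
energy_model <- function(path = NULL, init = 4.09, loop_open = 3.0,
                         loop_ext = 0.5, max_loop = 8L) {
  if (is.null(path))
    path <- system.file("extdata", "stack_energies.tsv",
                        package = "cernaweaver", mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- matrix(0, 6L, 6L, dimnames = list(pairs, pairs))
  i1 <- match(tab$pair1, pairs); i2 <- match(tab$pair2, pairs)
  if (anyNA(i1) || anyNA(i2)) stop("energy_model: unknown pair label in ", path)
  stack[cbind(i1, i2)] <- tab$dg
  if (any(stack > 0)) stop("energy_model: all stack energies must be <= 0")
  if (loop_open < 0 || loop_ext < 0)
    stop("energy_model: loop penalties must be >= 0")
  structure(list(stack = stack, init = init, loop_open = loop_open,
                 loop_ext = loop_ext, max_loop = as.integer(max_loop)),
            class = "energy_model")
}

#' Bulge-aware dissimilarity between a miRNA tail and a site extension
#'
#' The tail is the mature minus its seed (positions 9 to the end). The
#' extension is the stretch of target sequence immediately 5' of the
#' seed-complement window (antiparallel duplex geometry places tail pairing
#' there), `|tail| + max_bulge` nt long. The dissimilarity is the minimum
#' unit-cost edit alignment of the tail against the reverse complement of the
#' extension, allowing at most `max_bulge` total gap nucleotides (bulges on
#' either strand), normalized by tail length and clipped to `[0, 1]`. A
#' perfectly pairing extension gives 0; an empty tail gives 0 by convention.
#'
#' @param mirna_tail tail sequence (mature positions 9..end).
#' @param extended_fragment target-side extension, read 5'->3'.
#' @param max_bulge maximum total gap nucleotides (default 4).
#' @return dissimilarity fraction in `[0, 1]`.
#' @export
tail_dissimilarity <- function(mirna_tail, extended_fragment, max_bulge = 4L) {
  mirna_tail <- as_rna(mirna_tail)
  if (nchar(mirna_tail) == 0L) return(0)
  rext <- revcomp_rna(as_rna(extended_fragment))
  cost <- cw_tail_dissim(seq_to_int(mirna_tail), seq_to_int(rext),
                         as.integer(max_bulge))
  min(1, max(0, cost / nchar(mirna_tail)))
}

#' Binding free energy of a miRNA:target duplex
#'
#' Computes the minimum free energy over co-linear antiparallel pairings of
#' the full mature against the site with its 5' context, by dynamic
#' programming under the nearest-neighbor model: initiation plus stack
#' energies over contiguous pairs (Watson-Crick and GU wobble) plus
#' bulge/internal-loop penalties. More complementarity gives a lower (more
#' negative) deltaG; if no pairing is possible the result is the initiation
#' energy alone.
#'
#' @param mature mature miRNA sequence, 5'->3'.
#' @param site_with_context target subsequence covering the seed-complement
#'   window and its 5' extension, read 5'->3'.
#' @param model an [energy_model()].
#' @return free energy in kcal/mol (negative = stable).
#' @export
duplex_energy <- function(mature, site_with_context, model = energy_model()) {
  a <- seq_to_int(as_rna(mature))
  b <- rev(seq_to_int(as_rna(site_with_context)))  # antiparallel: reverse only
  cw_duplex_energy(a, b, model$stack, model$init, model$loop_open,
                   model$loop_ext, model$max_loop)
}

#' Predict miRNA-target interactions
#'
#' The four-stage predictor: (1) train a SOM on the catalogue seeds; (2)
#' project sliding target windows onto the lattice and keep windows whose
#' cluster hosts a catalogued seed; (3) score the miRNA tail against the
#' 5'-ward site extension and keep candidates with dissimilarity <= `tau`;
#' (4) compute the duplex free energy over seed plus tail and keep
#' interactions with deltaG strictly below `dg_cut` (default -12 kcal/mol).
#' Protein-coding targets are searched in their 3'UTR only, pseudogenes
#' full-length. Output is sorted by deltaG ascending (ties by miRNA, target,
#' site start).
#'
#' @param mirnas data.frame catalogue with columns `id` and `mature`.
#' @param targets data.frame with columns `id`, `biotype`, `sequence`,
#'   `utr3_start`, `utr3_end` (see [gen_transcriptome()]).
#' @param tau dissimilarity threshold (fraction of tail length).
#' @param dg_cut free-energy cut, kcal/mol (interactions kept when
#'   deltaG < dg_cut).
#' @param max_bulge maximum bulged nucleotides in tail pairing.
#' @param model an [energy_model()].
#' @param lattice optional pre-trained `som_lattice`; otherwise one is
#'   trained with `som_seed`.
#' @param som_seed RNG seed for SOM weight initialization.
#' @param neighborhood cluster-compatibility radius (see
#'   [project_fragments()]).
#' @param keep_all return all candidates surviving projection with their
#'   dissimilarity and deltaG, without applying the tau and deltaG filters
#'   (used for threshold diagnostics).
#' @return data.frame of interactions: mirna_id, target_id, target_kind,
#'   site_start, site_end, dissimilarity, deltaG.
#' @export
predict_targets <- function(mirnas, targets, tau = 0.3, dg_cut = -12,
                            max_bulge = 4L, model = energy_model(),
                            lattice = NULL, som_seed = 1L, neighborhood = 0,
                            keep_all = FALSE) {
  empty <- data.frame(mirna_id = character(0L), target_id = character(0L),
                      target_kind = character(0L), site_start = integer(0L),
                      site_end = integer(0L), dissimilarity = numeric(0L),
                      deltaG = numeric(0L), stringsAsFactors = FALSE)
  if (nrow(mirnas) == 0L || nrow(targets) == 0L) return(empty)
  stopifnot(all(c("id", "mature") %in% names(mirnas)),
            all(c("id", "biotype", "sequence") %in% names(targets)))
  mirnas$mature <- as_rna(mirnas$mature)
  seeds <- setNames(extract_seed(mirnas$mature), mirnas$id)
  if (is.null(lattice)) lattice <- train_som(seeds, rng_seed = som_seed)
  tails <- setNames(substr(mirnas$mature, 9L, nchar(mirnas$mature)), mirnas$id)
  matures <- setNames(mirnas$mature, mirnas$id)

  out <- lapply(seq_len(nrow(targets)), function(t) {
    tgt <- targets[t, ]
    cand <- project_fragments(lattice, tgt, neighborhood = neighborhood)
    if (nrow(cand) == 0L) return(NULL)
    seq <- as_rna(tgt$sequence)
    tl <- nchar(tails[cand$mirna_id])
    ext_start <- pmax(1L, cand$site_start - (tl + max_bulge))
    tail_ints <- lapply(tails[cand$mirna_id], seq_to_int)
    rext_ints <- lapply(seq_len(nrow(cand)), function(k) {
      if (ext_start[k] >= cand$site_start[k]) return(integer(0L))
      ext <- substr(seq, ext_start[k], cand$site_start[k] - 1L)
      seq_to_int(revcomp_rna(ext))
    })
    cost <- cw_tail_dissim_many(tail_ints, rext_ints, as.integer(max_bulge))
    d <- ifelse(tl == 0L, 0, pmin(1, pmax(0, cost / pmax(tl, 1L))))
    keep <- if (keep_all) rep(TRUE, length(d)) else d <= tau
    if (!any(keep)) return(NULL)
    cand <- cand[keep, , drop = FALSE]
    d <- d[keep]; ext_start <- ext_start[keep]
    ctx <- substr(rep(seq, nrow(cand)), ext_start, cand$site_end)
    a_ints <- lapply(matures[cand$mirna_id], seq_to_int)
    b_ints <- lapply(ctx, function(s) rev(seq_to_int(s)))
    dg <- cw_duplex_energy_many(a_ints, b_ints, model$stack, model$init,
                                model$loop_open, model$loop_ext, model$max_loop)
    keep2 <- if (keep_all) rep(TRUE, length(dg)) else dg < dg_cut
    if (!any(keep2)) return(NULL)
    data.frame(mirna_id = cand$mirna_id[keep2], target_id = cand$target_id[keep2],
               target_kind = ifelse(tgt$biotype == "pseudogene",
                                    "pseudogene", "mRNA"),
               site_start = cand$site_start[keep2],
               site_end = cand$site_end[keep2],
               dissimilarity = d[keep2], deltaG = dg[keep2],
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(out)
  if (is.null(out)) return(empty)
  out[order(out$deltaG, out$mirna_id, out$target_id, out$site_start), ,
      drop = FALSE]
}
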