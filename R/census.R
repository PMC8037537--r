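#' Transcript biotype census
#'
#' Tallies an annotation by biotype and summarizes the coding/noncoding
#' breakdown of the transcriptome, the style of summary in which 99% of pharynx
#' transcripts are protein coding and the remaining 1% split into miRNAs,
#' pseudogenes, snRNAs, snoRNAs, rRNAs, miscRNAs and mtRNAs.
#'
#' @param annotation data.frame with at least a `biotype` column (one row per
#'   transcript), e.g. the `annotation.tsv` written by [write_synth_bundle()].
#' @return a `biotype_census` list: `counts` (named integer vector over all
#'   recognized biotypes), `total`, `noncoding` and `fraction_noncoding`.
#' @export
#' @examples
#' classify_biotypes(data.frame(biotype = c("protein_coding", "miRNA")))
classify_biotypes <- function(annotation) {
  stopifnot(is.data.frame(annotation), "biotype" %in% names(annotation))
  bt <- as.character(annotation$biotype)
  bad <- which(!bt %in% BIOTYPES)
  if (length(bad) > 0L)
    stop("unrecognized biotype '", bt[bad[1L]], "' in annotation row ", bad[1L])
  counts <- vapply(BIOTYPES, function(b) sum(bt == b), integer(1L))
  total <- length(bt)
  noncoding <- total - counts[["protein_coding"]]
  out <- list(counts = counts, total = total, noncoding = noncoding,
              fraction_noncoding = if (total > 0L) noncoding / total else NA_real_)
  class(out) <- "biotype_census"
  out
}

BIOTYPES <- c("protein_coding", "miRNA", "pseudogene", "snRNA", "snoRNA",
              "rRNA", "miscRNA", "mtRNA")

#' @export
print.biotype_census <- function(x, ...) {
  cat("Biotype census:", x$total, "transcripts,", x$noncoding, "noncoding (",
      if (is.na(x$fraction_noncoding)) "-" else
        sprintf("%.1f%%", 100 * x$fraction_noncoding), ")\n")
  print(x$counts)
  invisible(x)
}

#' Global percent identity between two nucleotide sequences
#'
#' Needleman-Wunsch global alignment under unit costs (match +1, mismatch -1,
#' gap -2 per nt by default); identity is counted Blast-style as
#' matches / alignment columns, gap columns included. Symmetry in the two
#' arguments is guaranteed by aligning them in canonical (lexicographic)
#' order. The traceback is deterministic (diagonal preferred, then a gap in
#' the second sequence).
#'
#' @param a,b non-empty nucleotide strings (RNA or DNA; T is mapped to U).
#' @param match,mismatch,gap alignment scores.
#' @return list with `identity` (fraction), `alignment_length` (columns) and
#'   `score`.
#' @export
#' @examples
#' percent_identity("ACGU", "ACGA")$identity  # 0.75
percent_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as_rna(a); b <- as_rna(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("percent_identity: sequences must be non-empty")
  if (a > b) { tmp <- a; a <- b; b <- tmp }  # canonical order => symmetry
  res <- cw_needleman(seq_to_int(a), seq_to_int(b), match, mismatch, gap)
  list(identity = res$matches / res$columns,
       alignment_length = res$columns,
       score = res$score)
}

#' Load a packaged table transcribed from the study
#'
#' Available fixtures: `conserved_mirnas` and `specific_mirnas` (the annotated
#' miRNA catalogue split by conservation), `pseudogenes` (the 27 annotated
#' pseudogenes with parent paralogue and Blast percent identity) and
#' `pathway_interactions` (the mRNA-miRNA-pseudogene interactions of the Wnt,
#' FoxO, Tgf-β and Hh pathways, one row per miRNA-gene pair with the
#' interacting pseudogene, when any, on the same row). Row order is stable.
#'
#' @param name fixture name.
#' @return data.frame.
#' @export
#' @examples
#' head(load_fixture("conserved_mirnas"))
load_fixture <- function(name = c("conserved_mirnas", "specific_mirnas",
                                  "pseudogenes", "pathway_interactions")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("table_", name, ".tsv"),
                      package = "cernaweaver", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  if (name == "pathway_interactions") {
    if (!"pseudogene" %in% names(df)) df$pseudogene <- NA_character_
    df$pseudogene[is.na(df$pseudogene)] <- ""
  }
  df
}
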