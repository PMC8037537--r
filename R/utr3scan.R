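#' Default 3'UTR cis-element motif table
#'
#' Loads the packaged motif definitions for the seven element classes scanned
#' in mRNA 3'UTRs: MBE (musashi-binding element), GAIT (interferon-gamma-
#' activated inhibitor of translation, hairpin-gated), CPE (cytoplasmic
#' polyadenylation element), ARE (AU-rich element), MOS-PRE (polyadenylation
#' response element), the GU-rich destabilization element and the UNR binding
#' site. Patterns are IUPAC consensus choices documented in the table file
#' header; pass an edited copy via `path` to change them.
#'
#' @param path motif TSV (columns name, pattern, requires_hairpin, min_stem).
#' @return data.frame of motif definitions (U/T equivalence applied).
#' @export
default_motif_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motifs.tsv", package = "cernaweaver",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "pattern", "requires_hairpin", "min_stem") %in%
                  names(tab)))
  tab$pattern <- as_rna(tab$pattern, allow_iupac = TRUE)
  tab$requires_hairpin <- as.logical(tab$requires_hairpin)
  if (any(nchar(tab$pattern) == 0L)) stop("motif table: empty pattern")
  if (any(tab$requires_hairpin & tab$min_stem < 3L))
    stop("motif table: hairpin motifs need min_stem >= 3")
  tab
}

#' Scan a 3'UTR sequence for cis-regulatory elements
#'
#' Reports all non-overlapping leftmost matches of each element's IUPAC
#' pattern (per element; different elements may overlap). Hairpin-gated
#' elements (GAIT) additionally require a flanking stem: at least `min_stem`
#' consecutive complementary base pairs between an upstream and a downstream
#' segment, both within 30 nt of the match.
#'
#' @param seq RNA string (T is mapped to U).
#' @param table motif definitions, default [default_motif_table()].
#' @param transcript_id id recorded in the hits.
#' @return data.frame of hits: transcript_id, element, start, end, match
#'   (1-based closed; `match` re-slices from the sequence).
#' @export
scan_utr <- function(seq, table = default_motif_table(),
                     transcript_id = NA_character_) {
  seq <- as_rna(seq)
  empty <- data.frame(transcript_id = character(0L), element = character(0L),
                      start = integer(0L), end = integer(0L),
                      match = character(0L), stringsAsFactors = FALSE)
  if (nchar(seq) == 0L) return(empty)
  subject <- Biostrings::RNAString(seq)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    pat <- Biostrings::RNAString(table$pattern[i])
    if (nchar(seq) < length(pat)) return(NULL)
    m <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    if (length(m) == 0L) return(NULL)
    starts <- Biostrings::start(m); ends <- Biostrings::end(m)
    keep <- leftmost_nonoverlapping(starts, ends)
    starts <- starts[keep]; ends <- ends[keep]
    if (isTRUE(table$requires_hairpin[i])) {
      ok <- vapply(seq_along(starts), function(j) {
        has_flanking_stem(seq, starts[j], ends[j],
                          min_stem = table$min_stem[i], window = 30L)
      }, logical(1L))
      starts <- starts[ok]; ends <- ends[ok]
    }
    if (length(starts) == 0L) return(NULL)
    data.frame(transcript_id = transcript_id, element = table$name[i],
               start = starts, end = ends,
               match = substring(seq, starts, ends), stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out)) empty else out
}

# greedy leftmost selection of non-overlapping intervals (inputs sorted by
# start, as matchPattern returns them)
leftmost_nonoverlapping <- function(starts, ends) {
  keep <- logical(length(starts))
  last_end <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] > last_end) {
      keep[i] <- TRUE
      last_end <- ends[i]
    }
  }
  keep
}

# stem-loop heuristic: >= min_stem consecutive complementary base pairs
# between an upstream segment ending at or before `start - 1` and a
# downstream segment starting at or after `end + 1`, both within `window` nt
has_flanking_stem <- function(seq, start, end, min_stem = 4L, window = 30L) {
  n <- nchar(seq)
  up_lo <- max(1L, start - window)
  dn_hi <- min(n, end + window)
  if (start - up_lo < min_stem || dn_hi - end < min_stem) return(FALSE)
  up <- substr(seq, up_lo, start - 1L)
  dn <- substr(seq, end + 1L, dn_hi)
  # stem iff revcomp(downstream) shares a >= min_stem substring with upstream
  rcdn <- revcomp_rna(dn)
  max_len <- min(nchar(up), nchar(rcdn))
  if (max_len < min_stem) return(FALSE)
  for (len in seq(max_len, min_stem)) {
    for (s in seq_len(nchar(rcdn) - len + 1L)) {
      if (grepl(substr(rcdn, s, s + len - 1L), up, fixed = TRUE)) return(TRUE)
    }
  }
  FALSE
}

#' Scan the 3'UTRs of an annotated transcript table
#'
#' Runs [scan_utr()] on the annotated 3'UTR of every protein-coding
#' transcript and reports hits in full-sequence coordinates.
#'
#' @param transcripts data.frame with `id`, `biotype`, `sequence`,
#'   `utr3_start`, `utr3_end` (see [gen_transcriptome()]).
#' @param table motif definitions.
#' @return data.frame of hits as in [scan_utr()].
#' @export
scan_utr3 <- function(transcripts, table = default_motif_table()) {
  keep <- transcripts$biotype == "protein_coding" & !is.na(transcripts$utr3_start)
  rows <- lapply(which(keep), function(i) {
    utr <- substr(transcripts$sequence[i], transcripts$utr3_start[i],
                  transcripts$utr3_end[i])
    h <- scan_utr(utr, table, transcript_id = transcripts$id[i])
    h$start <- h$start + transcripts$utr3_start[i] - 1L
    h$end <- h$end + transcripts$utr3_start[i] - 1L
    h
  })
  out <- rbind_rows(rows)
  if (is.null(out)) {
    data.frame(transcript_id = character(0L), element = character(0L),
               start = integer(0L), end = integer(0L), match = character(0L),
               stringsAsFactors = FALSE)
  } else out
}

#' Element presence/absence matrix over a gene panel
#'
#' @param hits data.frame from [scan_utr()] (rows for many transcripts).
#' @param panel transcript/gene ids defining the rows; defaults to the ids in
#'   `hits`.
#' @param elements element classes defining the columns; defaults to the
#'   packaged motif table's classes.
#' @return logical matrix, genes x elements.
#' @export
element_profile <- function(hits, panel = NULL,
                            elements = default_motif_table()$name) {
  if (is.null(panel)) panel <- unique(hits$transcript_id)
  m <- matrix(FALSE, nrow = length(panel), ncol = length(elements),
              dimnames = list(panel, elements))
  if (nrow(hits) > 0L) {
    hits <- hits[hits$transcript_id %in% panel & hits$element %in% elements, ]
    m[cbind(match(hits$transcript_id, panel), match(hits$element, elements))] <- TRUE
  }
  m
}
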