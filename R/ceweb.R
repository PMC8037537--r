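#' Build a ceRNA network from predicted interactions
#'
#' Overlays energy-filtered miRNA interactions on pathway gene sets. Nodes
#' are typed (`gene`, `miRNA`, `pseudogene`, `pathway`); edges are typed:
#' `targets` (miRNA -> gene, only for genes belonging to at least one
#' supplied pathway), `sequesters` (miRNA -> pseudogene, for every
#' pseudogene interaction whose miRNA was retained by a targets edge) and
#' `member_of` (gene -> pathway). Duplicate interactions (same miRNA, same
#' target) collapse to one edge keeping the minimum deltaG. Node ordering is
#' deterministic.
#'
#' @param interactions data.frame with columns mirna_id, target_id,
#'   target_kind (`"mRNA"` or `"pseudogene"`) and optionally deltaG, e.g.
#'   from [predict_targets()] or [fixture_interactions()].
#' @param pathway_sets named list mapping pathway name to a character vector
#'   of member gene ids.
#' @return a `cerna_graph`: a directed [igraph::graph] with vertex
#'   attributes `type` and edge attributes `type`, `deltaG`.
#' @export
build_network <- function(interactions, pathway_sets) {
  stopifnot(is.list(pathway_sets), !is.null(names(pathway_sets)))
  need <- c("mirna_id", "target_id", "target_kind")
  stopifnot(all(need %in% names(interactions)))
  if (!"deltaG" %in% names(interactions))
    interactions$deltaG <- rep(NA_real_, nrow(interactions))

  # collapse duplicates, keep the most stable duplex
  key <- paste(interactions$mirna_id, interactions$target_id, sep = "\r")
  ord <- order(interactions$deltaG, na.last = TRUE)
  interactions <- interactions[ord, , drop = FALSE]
  interactions <- interactions[!duplicated(key[ord]), , drop = FALSE]

  pathway_names <- sort(names(pathway_sets))
  genes <- sort(unique(unlist(pathway_sets, use.names = FALSE)))

  mrna <- interactions[interactions$target_kind != "pseudogene", , drop = FALSE]
  mrna <- mrna[mrna$target_id %in% genes, , drop = FALSE]
  pseu <- interactions[interactions$target_kind == "pseudogene", , drop = FALSE]
  pseu <- pseu[pseu$mirna_id %in% mrna$mirna_id, , drop = FALSE]

  mirnas <- sort(unique(c(mrna$mirna_id, pseu$mirna_id)))
  pseudogenes <- sort(unique(pseu$target_id))

  nodes <- data.frame(
    name = c(genes, mirnas, pseudogenes, pathway_names),
    type = c(rep("gene", length(genes)), rep("miRNA", length(mirnas)),
             rep("pseudogene", length(pseudogenes)),
             rep("pathway", length(pathway_names))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$name))
    stop("build_network: node id used with more than one type: ",
         nodes$name[duplicated(nodes$name)][1L])

  member <- rbind_rows(lapply(pathway_names, function(p) {
    g <- sort(unique(pathway_sets[[p]]))
    if (length(g) == 0L) return(NULL)
    data.frame(from = g, to = p, type = "member_of", deltaG = NA_real_,
               stringsAsFactors = FALSE)
  }))
  targets <- if (nrow(mrna) > 0L) {
    data.frame(from = mrna$mirna_id, to = mrna$target_id, type = "targets",
               deltaG = mrna$deltaG, stringsAsFactors = FALSE)
  } else NULL
  sequesters <- if (nrow(pseu) > 0L) {
    data.frame(from = pseu$mirna_id, to = pseu$target_id, type = "sequesters",
               deltaG = pseu$deltaG, stringsAsFactors = FALSE)
  } else NULL
  edges <- rbind_rows(list(member, targets, sequesters))
  if (is.null(edges))
    edges <- data.frame(from = character(0L), to = character(0L),
                        type = character(0L), deltaG = numeric(0L),
                        stringsAsFactors = FALSE)
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  class(g) <- c("cerna_graph", class(g))
  g
}

#' Convert the packaged pathway-interaction table to interaction rows
#'
#' Expands the pathway fixture into the `interactions` shape expected by
#' [build_network()]: one `mRNA` row per miRNA-gene pair and one
#' `pseudogene` row per miRNA-pseudogene pair.
#'
#' @param tab data.frame from `load_fixture("pathway_interactions")`.
#' @return data.frame with mirna_id, target_id, target_kind.
#' @export
fixture_interactions <- function(tab = load_fixture("pathway_interactions")) {
  mrna <- data.frame(mirna_id = tab$mirna, target_id = tab$gene_name,
                     target_kind = "mRNA", stringsAsFactors = FALSE)
  has_pg <- !is.na(tab$pseudogene) & nzchar(tab$pseudogene)
  pseu <- data.frame(mirna_id = tab$mirna[has_pg],
                     target_id = tab$pseudogene[has_pg],
                     target_kind = "pseudogene", stringsAsFactors = FALSE)
  rbind(mrna, pseu)
}

#' Pathway gene sets from the packaged pathway-interaction table
#'
#' @param tab data.frame from `load_fixture("pathway_interactions")`.
#' @return named list pathway -> gene names.
#' @export
fixture_pathway_sets <- function(tab = load_fixture("pathway_interactions")) {
  lapply(split(tab$gene_name, tab$pathway), function(g) sort(unique(g)))
}

#' Enumerate ceRNA couples in a network
#'
#' A couple is a (miRNA, pseudogene) pair joined by a `sequesters` edge whose
#' miRNA also `targets` at least one pathway gene: the pseudogene competes
#' with those genes for the miRNA. Genes shared with the miRNA and their
#' pathways are listed; couples are sorted by miRNA id, then pseudogene id.
#'
#' @param graph a `cerna_graph` from [build_network()].
#' @return data.frame with mirna_id, pseudogene_id, gene_ids
#'   (comma-collapsed), pathways (comma-collapsed).
#' @export
cerna_couples <- function(graph) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  empty <- data.frame(mirna_id = character(0L), pseudogene_id = character(0L),
                      gene_ids = character(0L), pathways = character(0L),
                      stringsAsFactors = FALSE)
  seq_ed <- ed[ed$type == "sequesters", , drop = FALSE]
  if (nrow(seq_ed) == 0L) return(empty)
  tgt_ed <- ed[ed$type == "targets", , drop = FALSE]
  mem_ed <- ed[ed$type == "member_of", , drop = FALSE]
  rows <- lapply(seq_len(nrow(seq_ed)), function(i) {
    mir <- seq_ed$from[i]
    genes <- sort(unique(tgt_ed$to[tgt_ed$from == mir]))
    if (length(genes) == 0L) return(NULL)
    paths <- sort(unique(mem_ed$to[mem_ed$from %in% genes]))
    data.frame(mirna_id = mir, pseudogene_id = seq_ed$to[i],
               gene_ids = paste(genes, collapse = ","),
               pathways = paste(paths, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out)) return(empty)
  out <- unique(out)
  out[order(out$mirna_id, out$pseudogene_id), , drop = FALSE]
}

#' Genes shared by two or more pathways
#'
#' @param pathway_sets named list pathway -> gene ids.
#' @return named list gene -> sorted pathway names, restricted to genes with
#'   pathway multiplicity >= 2; genes sorted by id.
#' @export
shared_proteins <- function(pathway_sets) {
  stopifnot(length(pathway_sets) >= 2L)
  long <- data.frame(
    gene = unlist(pathway_sets, use.names = FALSE),
    pathway = rep(names(pathway_sets), lengths(pathway_sets)),
    stringsAsFactors = FALSE)
  by_gene <- lapply(split(long$pathway, long$gene), function(p) sort(unique(p)))
  by_gene <- by_gene[lengths(by_gene) >= 2L]
  by_gene[order(names(by_gene))]
}

#' Export a ceRNA network to a standard format
#'
#' `edge_list` writes a single TSV with a typed node section followed by a
#' typed edge section, and `graphml` writes GraphML via igraph; both
#' round-trip through [import_graph()] reproducing node and edge sets
#' exactly.
#'
#' @param graph a `cerna_graph`.
#' @param path output file.
#' @param format `"edge_list"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("edge_list", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  nd <- igraph::as_data_frame(graph, what = "vertices")
  ed <- igraph::as_data_frame(graph, what = "edges")
  nd <- nd[order(nd$name), , drop = FALSE]
  ed <- ed[order(ed$type, ed$from, ed$to), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("record\tid\ttype\tto\tdeltaG", con)
  if (nrow(nd) > 0L)
    writeLines(sprintf("node\t%s\t%s\t\t", nd$name, nd$type), con)
  if (nrow(ed) > 0L)
    writeLines(sprintf("edge\t%s\t%s\t%s\t%s", ed$from, ed$type, ed$to,
                       ifelse(is.na(ed$deltaG), "", format(ed$deltaG, digits = 10))),
               con)
  invisible(path)
}

#' Re-import a network written by [export_graph()]
#'
#' @param path file written by [export_graph()].
#' @param format `"edge_list"` or `"graphml"`.
#' @return a `cerna_graph`.
#' @export
import_graph <- function(path, format = c("edge_list", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    class(g) <- c("cerna_graph", class(g))
    return(g)
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = NULL, quote = "")
  nd <- tab[tab$record == "node", , drop = FALSE]
  ed <- tab[tab$record == "edge", , drop = FALSE]
  nodes <- data.frame(name = nd$id, type = nd$type, stringsAsFactors = FALSE)
  edges <- data.frame(from = ed$id, to = ed$to, type = ed$type,
                      deltaG = suppressWarnings(as.numeric(ed$deltaG)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  class(g) <- c("cerna_graph", class(g))
  g
}
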