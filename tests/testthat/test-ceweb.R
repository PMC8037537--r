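fixture_graph <- function() {
  build_network(fixture_interactions(), fixture_pathway_sets())
}

test_that("the fixture network contains the expected typed nodes and edges", {
  g <- fixture_graph()
  nd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  # the documented miRNA-pseudogene interaction appears as a sequesters edge
  expect_true(any(ed$type == "sequesters" & ed$from == "cin-mir-92c-5p" &
                    ed$to == "ENSCING00000011392"))
  # exactly the three interacting pseudogenes enter the graph
  expect_setequal(nd$name[nd$type == "pseudogene"],
                  c("ENSCING00000011392", "ENSCING00000018651",
                    "ENSCING00000007698"))
  expect_setequal(nd$name[nd$type == "pathway"],
                  c("Wnt", "FoxO", "Tgf-β", "Hh"))
  # no dangling edges; edge types match endpoint types
  for (i in seq_len(nrow(ed))) {
    ft <- nd$type[nd$name == ed$from[i]]
    tt <- nd$type[nd$name == ed$to[i]]
    expect_equal(unname(c(targets = "miRNA", sequesters = "miRNA",
                          member_of = "gene")[ed$type[i]]), ft)
    expect_equal(unname(c(targets = "gene", sequesters = "pseudogene",
                          member_of = "pathway")[ed$type[i]]), tt)
  }
  # edge count equals an independent tally of de-duplicated fixture rows
  tab <- load_fixture("pathway_interactions")
  n_member <- length(unique(paste(tab$pathway, tab$gene_name)))
  n_targets <- length(unique(paste(tab$mirna, tab$gene_name)))
  has_pg <- nzchar(tab$pseudogene)
  n_seq <- length(unique(paste(tab$mirna, tab$pseudogene)[has_pg]))
  expect_equal(igraph::ecount(g), n_member + n_targets + n_seq)
})

test_that("empty interactions give a pathway/gene-only graph", {
  empty <- data.frame(mirna_id = character(0L), target_id = character(0L),
                      target_kind = character(0L))
  g <- build_network(empty, fixture_pathway_sets())
  nd <- igraph::as_data_frame(g, what = "vertices")
  expect_setequal(unique(nd$type), c("gene", "pathway"))
  ed <- igraph::as_data_frame(g, what = "edges")
  expect_true(all(ed$type == "member_of"))
  expect_equal(nrow(cerna_couples(g)), 0L)
})

test_that("ceRNA couples match the study and a cubic enumeration oracle", {
  g <- fixture_graph()
  cp <- cerna_couples(g)
  expect_equal(nrow(cp), 3L)
  sfrp <- cp[cp$mirna_id == "cin-mir-153-5p", ]
  expect_equal(sfrp$pseudogene_id, "ENSCING00000007698")
  expect_match(sfrp$gene_ids, "Sfrp1/5")
  expect_match(sfrp$pathways, "Wnt")
  oracle <- couples_bruteforce(g)
  expect_equal(nrow(cp), length(oracle))
  ok <- paste(cp$mirna_id, cp$pseudogene_id)
  expect_setequal(ok, vapply(oracle, function(x)
    paste(x[["mirna"]], x[["pseudogene"]]), character(1L)))
})

test_that("shared proteins equal brute-force pairwise intersections", {
  sets <- fixture_pathway_sets()
  sh <- shared_proteins(sets)
  expect_true("Smad4 protein(Smad4)" %in% names(sh))
  expect_setequal(sh[["Smad4 protein(Smad4)"]], c("Wnt", "FoxO", "Tgf-β"))
  # brute force over all pathway pairs
  expected <- character(0L)
  for (a in names(sets)) for (b in names(sets)) {
    if (a < b) expected <- c(expected, intersect(sets[[a]], sets[[b]]))
  }
  expect_setequal(names(sh), unique(expected))
  # disjoint sets share nothing
  expect_length(shared_proteins(list(p1 = c("a", "b"), p2 = c("c"))), 0L)
})

test_that("graph exports round-trip exactly in both formats", {
  g <- fixture_graph()
  for (fmt in c("edge_list", "graphml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(g, path, fmt)
    g2 <- import_graph(path, fmt)
    nd1 <- igraph::as_data_frame(g, what = "vertices")
    nd2 <- igraph::as_data_frame(g2, what = "vertices")
    expect_setequal(paste(nd1$name, nd1$type), paste(nd2$name, nd2$type))
    ed1 <- igraph::as_data_frame(g, what = "edges")
    ed2 <- igraph::as_data_frame(g2, what = "edges")
    expect_setequal(paste(ed1$from, ed1$to, ed1$type),
                    paste(ed2$from, ed2$to, ed2$type))
  }
  # export -> import -> export is byte-identical (edge list)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, p1, "edge_list")
  export_graph(import_graph(p1, "edge_list"), p2, "edge_list")
  expect_identical(readLines(p1), readLines(p2))
  # empty graph: header-only file
  empty <- build_network(data.frame(mirna_id = character(0L),
                                    target_id = character(0L),
                                    target_kind = character(0L)),
                         list(p = character(0L)))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  export_graph(empty, p3, "edge_list")
  expect_equal(length(readLines(p3)), 2L)  # header + the pathway node
  expect_error(export_graph(g, tempfile(), "dot"))
})

test_that("GraphML export is well-formed with declared keys and valid refs", {
  skip_if_not_installed("xml2")
  g <- fixture_graph()
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, path, "graphml")
  doc <- xml2::read_xml(path)  # errors if not well-formed XML
  expect_equal(xml2::xml_name(doc), "graphml")
  ns <- xml2::xml_ns(doc)
  expect_true("http://graphml.graphdrawing.org/xmlns" %in% unlist(ns))
  nodes <- xml2::xml_find_all(doc, ".//d1:node", ns)
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  expect_equal(length(nodes), igraph::vcount(g))
  expect_equal(length(edges), igraph::ecount(g))
  ids <- xml2::xml_attr(nodes, "id")
  expect_true(all(xml2::xml_attr(edges, "source") %in% ids))
  expect_true(all(xml2::xml_attr(edges, "target") %in% ids))
  # attribute keys are declared before use
  keys <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:key", ns), "id")
  used <- unique(xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:data", ns),
                                "key"))
  expect_true(all(used %in% keys))
})

test_that("couples shrink monotonically as the energy cut tightens upstream", {
  cfg <- synth_config(n_mrna = 40L, n_mirna = 10L, n_pseudogene = 8L,
                      rng_seed = 77L)
  b <- gen_transcriptome(cfg)
  cand <- predict_targets(b$mirnas, b$transcripts, som_seed = 77L,
                          keep_all = TRUE)
  sets <- list(pw1 = b$transcripts$id[b$transcripts$biotype ==
                                        "protein_coding"][1:30])
  n_prev <- Inf
  for (cut in c(-12, -20, -28, -36)) {
    keep <- cand[cand$dissimilarity <= 0.3 & cand$deltaG < cut, ]
    cp <- cerna_couples(build_network(keep, sets))
    expect_lte(nrow(cp), n_prev)
    n_prev <- nrow(cp)
  }
})
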