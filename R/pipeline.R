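#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (free-energy cut -12 kcal/mol, dissimilarity threshold 0.3,
#' precursor E-value gate 1e-5, enrichment p and Benjamini cuts 0.05, EASE
#' 0.1), rejects unknown keys and out-of-range thresholds, and returns the
#' keys in canonical order; normalization is idempotent.
#'
#' @param config named list (possibly partial), or a YAML file path.
#' @return normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- list(
    mode = "synth", out_dir = "cerna_run", seed = 1L,
    n_mrna = 100L, n_mirna = 20L, n_pseudogene = 10L,
    planted_sites_per_utr = 1L,
    planted_elements = c("MBE", "GAIT", "CPE", "ARE"),
    dg_cut = -12, tau = 0.3, max_bulge = 4L,
    e_cut = 1e-5, p_cut = 0.05, q_cut = 0.05, ease_cut = 0.1)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("validate_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  cfg <- cfg[names(defaults)]
  if (!cfg$mode %in% c("synth", "fixtures"))
    stop("validate_config: mode must be 'synth' or 'fixtures'")
  if (cfg$dg_cut >= 0)
    stop("validate_config: dg_cut must be negative (kcal/mol)")
  if (cfg$tau < 0 || cfg$tau > 1)
    stop("validate_config: tau must be in [0, 1]")
  for (key in c("p_cut", "q_cut", "ease_cut")) {
    if (cfg[[key]] <= 0 || cfg[[key]] > 1)
      stop("validate_config: ", key, " must be in (0, 1]")
  }
  if (cfg$e_cut <= 0) stop("validate_config: e_cut must be positive")
  cfg$seed <- as.integer(cfg$seed)
  for (key in c("n_mrna", "n_mirna", "n_pseudogene", "max_bulge"))
    cfg[[key]] <- as.integer(cfg[[key]])
  cfg
}

#' Run the full ceRNA analysis pipeline
#'
#' In `synth` mode, generates a synthetic transcriptome with planted ground
#' truth and runs every stage over it: biotype census, precursor annotation,
#' seed families, SOM target prediction with the free-energy filter, term
#' enrichment against a synthetic null term map, 3'UTR element scanning and
#' ceRNA network construction with couples. In `fixtures` mode, the packaged
#' study tables are analyzed instead (census of the annotated noncoding
#' classes, pseudogene identity summary, pathway network and couples). All
#' stage outputs are written as TSV sidecars next to a Markdown report, and a
#' JSON manifest records the config, seeds, per-file MD5 digests and record
#' counts; identical configs reproduce identical bytes.
#'
#' @param config named list or YAML path, see [validate_config()].
#' @return (invisibly) list with `manifest`, `report_path`, `manifest_path`,
#'   and the main stage results.
#' @export
run_all <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir <- normalizePath(cfg$out_dir)
  if (cfg$mode == "synth") run_all_synth(cfg, out_dir) else
    run_all_fixtures(cfg, out_dir)
}

run_all_synth <- function(cfg, out_dir) {
  scfg <- synth_config(n_mrna = cfg$n_mrna, n_mirna = cfg$n_mirna,
                       n_pseudogene = cfg$n_pseudogene,
                       planted_sites_per_utr = cfg$planted_sites_per_utr,
                       planted_elements = cfg$planted_elements,
                       rng_seed = cfg$seed)
  bundle <- gen_transcriptome(scfg)
  data_paths <- write_synth_bundle(bundle, file.path(out_dir, "data"))

  tx <- bundle$transcripts
  annotation <- rbind(
    data.frame(id = tx$id, biotype = tx$biotype, stringsAsFactors = FALSE),
    data.frame(id = bundle$mirnas$id, biotype = rep("miRNA", nrow(bundle$mirnas)),
               stringsAsFactors = FALSE))
  census <- classify_biotypes(annotation)

  precursors <- setNames(bundle$mirnas$precursor, bundle$mirnas$id)
  matures <- setNames(bundle$mirnas$mature, bundle$mirnas$id)
  mir_report <- if (length(matures) > 0L) {
    annotate_precursors(precursors, matures, e_cut = cfg$e_cut)
  } else {
    data.frame(query_id = character(0L), subject_id = character(0L),
               score = numeric(0L), evalue = numeric(0L),
               accepted = logical(0L), accepted_secondary = logical(0L),
               stringsAsFactors = FALSE)
  }
  families <- seed_families(bundle$mirnas)

  all_cand <- predict_targets(bundle$mirnas, tx, tau = cfg$tau,
                              dg_cut = cfg$dg_cut, max_bulge = cfg$max_bulge,
                              som_seed = cfg$seed, keep_all = TRUE)
  after_tau <- all_cand[all_cand$dissimilarity <= cfg$tau, , drop = FALSE]
  preds <- after_tau[after_tau$deltaG < cfg$dg_cut, , drop = FALSE]
  preds <- preds[order(preds$deltaG, preds$mirna_id, preds$target_id,
                       preds$site_start), , drop = FALSE]

  coding_ids <- tx$id[tx$biotype == "protein_coding"]
  study <- unique(preds$target_id[preds$target_kind == "mRNA"])
  term_map <- withr::with_seed(cfg$seed + 1L,
                               gen_term_map(coding_ids, n_terms = 50L))
  enr <- fisher_enrich(study, coding_ids, term_map)
  sig <- filter_significant(enr, cfg$p_cut, cfg$q_cut, cfg$ease_cut)

  motifs <- default_motif_table()
  hits <- scan_utr3(tx, motifs)
  profile <- element_profile(hits, panel = coding_ids, elements = motifs$name)

  pathway_sets <- withr::with_seed(cfg$seed + 2L, {
    n_per <- max(1L, min(30L, length(coding_ids)))
    setNames(lapply(1:4, function(i) sort(sample(coding_ids, n_per))),
             paste0("pathway_", 1:4))
  })
  graph <- build_network(preds, pathway_sets)
  couples <- cerna_couples(graph)

  # ---- sidecars -------------------------------------------------------------
  side <- c(census = "census.tsv", mirna_annotation = "mirna_annotation.tsv",
            candidates = "candidates.tsv", interactions = "interactions.tsv",
            enrichment = "enrichment.tsv", element_hits = "element_hits.tsv",
            element_profile = "element_profile.tsv", couples = "couples.tsv",
            network = "network.tsv")
  side <- vapply(side, function(f) file.path(out_dir, f), character(1L))
  write_tsv(data.frame(biotype = names(census$counts),
                       count = unname(census$counts)), side[["census"]])
  write_tsv(mir_report, side[["mirna_annotation"]])
  write_tsv(all_cand, side[["candidates"]])
  write_tsv(preds, side[["interactions"]])
  write_tsv(enr, side[["enrichment"]])
  write_tsv(hits, side[["element_hits"]])
  write_tsv(data.frame(id = rownames(profile), profile, check.names = FALSE),
            side[["element_profile"]])
  write_tsv(couples, side[["couples"]])
  export_graph(graph, side[["network"]], format = "edge_list")

  counts <- list(
    transcripts = nrow(tx), mirnas = nrow(bundle$mirnas),
    census_total = census$total, noncoding = census$noncoding,
    precursors_annotated = sum(mir_report$accepted),
    seed_families = length(families),
    candidates = nrow(all_cand), after_dissimilarity = nrow(after_tau),
    interactions_mrna = sum(preds$target_kind == "mRNA"),
    interactions_pseudogene = sum(preds$target_kind == "pseudogene"),
    enriched_terms = nrow(enr), significant_terms = nrow(sig),
    element_hits = nrow(hits), couples = nrow(couples))

  report_path <- file.path(out_dir, "report.md")
  lines <- c(
    "# ceRNA pipeline report (synthetic mode)", "",
    sprintf("Seed: %d", cfg$seed),
    sprintf("Free-energy cut: %g kcal/mol; dissimilarity threshold: %g",
            cfg$dg_cut, cfg$tau), "",
    "## Biotype census",
    sprintf("- %s: %d", names(census$counts), unname(census$counts)),
    sprintf("- total: %d (noncoding fraction %.3f)", census$total,
            census$fraction_noncoding), "",
    "## miRNA catalogue",
    sprintf("- precursors annotated to a mature (E < %g): %d / %d", cfg$e_cut,
            sum(mir_report$accepted), nrow(mir_report)),
    sprintf("- seed families: %d", length(families)), "",
    "## Interaction prediction",
    sprintf("- candidate sites after cluster projection: %d", nrow(all_cand)),
    sprintf("- after tail-dissimilarity filter (d <= %g): %d", cfg$tau,
            nrow(after_tau)),
    sprintf("- after free-energy filter (deltaG < %g): %d (mRNA %d, pseudogene %d)",
            cfg$dg_cut, nrow(preds), counts$interactions_mrna,
            counts$interactions_pseudogene), "",
    "## Enrichment",
    sprintf("- terms tested: %d; significant at p < %g, Benjamini < %g, EASE <= %g: %d",
            nrow(enr), cfg$p_cut, cfg$q_cut, cfg$ease_cut, nrow(sig)), "",
    "## 3'UTR elements",
    sprintf("- hits: %d over %d transcripts", nrow(hits),
            length(unique(hits$transcript_id))), "",
    "## ceRNA network",
    sprintf("- nodes: %d; edges: %d; couples: %d", igraph::vcount(graph),
            igraph::ecount(graph), nrow(couples)))
  writeLines(lines, report_path)

  manifest <- build_manifest(cfg, c(data_paths, side, report = report_path),
                             counts)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(manifest = manifest, manifest_path = manifest_path,
                 report_path = report_path, bundle = bundle, census = census,
                 mirna_annotation = mir_report, candidates = all_cand,
                 interactions = preds, enrichment = enr,
                 element_hits = hits, element_profile = profile,
                 graph = graph, couples = couples,
                 pathway_sets = pathway_sets))
}

run_all_fixtures <- function(cfg, out_dir) {
  conserved <- load_fixture("conserved_mirnas")
  specific <- load_fixture("specific_mirnas")
  pseudo <- load_fixture("pseudogenes")
  tab <- load_fixture("pathway_interactions")

  # annotated noncoding class counts of the study transcriptome
  nc_counts <- c(miRNA = 90L, pseudogene = 27L, snRNA = 19L, snoRNA = 36L,
                 rRNA = 11L, miscRNA = 10L, mtRNA = 8L)
  total_transcripts <- 15074L
  annotation <- data.frame(
    biotype = c(rep("protein_coding", total_transcripts - sum(nc_counts)),
                rep(names(nc_counts), nc_counts)),
    stringsAsFactors = FALSE)
  census <- classify_biotypes(annotation)

  interactions <- fixture_interactions(tab)
  pathway_sets <- fixture_pathway_sets(tab)
  graph <- build_network(interactions, pathway_sets)
  couples <- cerna_couples(graph)
  shared <- shared_proteins(pathway_sets)

  side <- c(census = "census.tsv", pseudogenes = "pseudogenes.tsv",
            couples = "couples.tsv", shared = "shared_proteins.tsv",
            network = "network.tsv")
  side <- vapply(side, function(f) file.path(out_dir, f), character(1L))
  write_tsv(data.frame(biotype = names(census$counts),
                       count = unname(census$counts)), side[["census"]])
  write_tsv(pseudo, side[["pseudogenes"]])
  write_tsv(couples, side[["couples"]])
  write_tsv(data.frame(gene = names(shared),
                       pathways = vapply(shared, paste, character(1L),
                                         collapse = ",")), side[["shared"]])
  export_graph(graph, side[["network"]], format = "edge_list")

  counts <- list(
    census_total = census$total, noncoding = census$noncoding,
    conserved_mirnas = nrow(conserved), specific_mirnas = nrow(specific),
    pseudogenes = nrow(pseudo),
    pathways = length(pathway_sets),
    interaction_rows = nrow(interactions), couples = nrow(couples),
    shared_proteins = length(shared))

  report_path <- file.path(out_dir, "report.md")
  lines <- c(
    "# ceRNA pipeline report (fixture mode)", "",
    "## Biotype census",
    sprintf("- total transcripts: %d; noncoding: %d (%.1f%%)", census$total,
            census$noncoding, 100 * census$fraction_noncoding), "",
    "## miRNA catalogue",
    sprintf("- conserved miRNAs: %d; species-specific: %d; annotated: %d",
            nrow(conserved), nrow(specific), nrow(conserved) + nrow(specific)), "",
    "## Pseudogenes",
    sprintf("- catalogued: %d; identity to parent: %.2f-%.2f%%", nrow(pseudo),
            min(pseudo$identity_pct), max(pseudo$identity_pct)), "",
    "## ceRNA network",
    sprintf("- pathways: %s", paste(sort(names(pathway_sets)), collapse = ", ")),
    sprintf("- nodes: %d; edges: %d", igraph::vcount(graph),
            igraph::ecount(graph)),
    sprintf("- ceRNA couples: %d (%s)", nrow(couples),
            paste(couples$mirna_id, couples$pseudogene_id, sep = "~",
                  collapse = "; ")),
    sprintf("- genes shared by >= 2 pathways: %d", length(shared)))
  writeLines(lines, report_path)

  manifest <- build_manifest(cfg, c(side, report = report_path), counts)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(manifest = manifest, manifest_path = manifest_path,
                 report_path = report_path, census = census, graph = graph,
                 couples = couples, shared = shared,
                 pathway_sets = pathway_sets))
}

build_manifest <- function(cfg, paths, counts) {
  digests <- tools::md5sum(unlist(paths))
  names(digests) <- basename(names(digests))
  list(config = cfg,
       seeds = list(primary = cfg$seed, term_map = cfg$seed + 1L,
                    pathways = cfg$seed + 2L),
       files = as.list(digests),
       counts = counts,
       version = as.character(utils::packageVersion("cernaweaver")))
}
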