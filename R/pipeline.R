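# End-to-end pipeline: simulate (or load) inputs, propagate annotations,
# build per-species metabolic networks, compute the four distance
# matrices, build neighbor-joining network trees, measure congruence with
# the species tree, and run the PIC category screen. Every intermediate
# artifact is written as a plain-text standard format (TSV / Newick /
# PHYLIP) so each stage can be inspected and re-run independently.

#' Run the full genome-reduction analysis pipeline
#'
#' @param config a [scenario_config()] describing the simulated world, or
#'   `NULL` to analyse an existing fixture directory given in `input_dir`
#' @param out_dir output directory for all stage artifacts
#' @param input_dir optional directory of input files (as written by
#'   [emit_fixture_files()]); used when `config` is `NULL`
#' @param seed master seed; overrides `config$seed` when given
#' @param quiet suppress progress messages
#' @return a `run_manifest`: list with the config snapshot, seed, input
#'   file digests, per-stage output paths, and summary numbers (pangenome
#'   counts, mapping efficiency, congruence per distance measure, PIC
#'   screen results, degeneracy flags)
#' @export
run_pipeline <- function(config = NULL, out_dir, input_dir = NULL,
                         seed = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config)) {
    if (!is.null(seed)) {
      config$seed <- as.integer(seed)
    }
    say("stage simulate: generating fixture bundle (seed ", config$seed, ")")
    tree <- simulate_species_tree(config$n_species, seed = config$seed)
    bundle <- simulate_gene_content(tree, config)
    input_dir <- file.path(out_dir, "inputs")
    emit_fixture_files(bundle, input_dir)
  } else {
    if (is.null(input_dir)) stop_invalid("supply either a config or an input_dir")
    say("stage load: reading fixtures from ", input_dir)
    bundle <- read_fixture_bundle(input_dir)
  }
  table <- bundle$orthogroups
  species_tree <- bundle$species_tree

  say("stage pangenome")
  pangenome <- pangenome_partition(table)
  og_stats <- orthogroup_stats(table)

  say("stage annotate: orthogroup-consensus KO propagation")
  annotation <- propagate_ko(table, bundle$annotations)
  efficiency <- annotation_efficiency(annotation, table)
  counts_by_cat <- category_counts(annotation, table, bundle$ko_to_pathway)
  utils::write.table(
    data.frame(species = rownames(counts_by_cat), counts_by_cat, check.names = FALSE),
    file.path(out_dir, "category_counts.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(annotation$effective, file.path(out_dir, "effective_annotations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  say("stage network: per-species metabolic networks")
  gene_species <- species_of_genes(table)
  eff <- annotation$effective
  networks <- lapply(table$species, function(sp) {
    ks <- eff$k[gene_species[eff$gene] == sp]
    build_network(ks, bundle$ko_map, species = sp)
  })
  for (nw in networks) {
    export_edge_list(nw, file.path(out_dir, paste0(nw$species, ".edges.tsv")))
  }

  say("stage distances + network trees + congruence")
  measures <- c("jaccard", "wjaccard", "canberra", "adcan")
  congruence <- list(); network_trees <- list(); degenerate <- character(0)
  for (ms in measures) {
    dm <- distance_matrix(networks, measure = ms)
    write_phylip_lower(dm, file.path(out_dir, paste0("dist_", ms, ".phy")))
    if (all(dm == 0)) {
      # identical networks: NJ topology is undefined; flag, don't report
      degenerate <- c(degenerate, ms)
      congruence[[ms]] <- NA_real_
      next
    }
    njt <- suppressWarnings(neighbor_join(dm))
    network_trees[[ms]] <- njt
    write_newick(njt, file.path(out_dir, paste0("njtree_", ms, ".nwk")))
    congruence[[ms]] <- shared_split_fraction(njt, species_tree)$shared_pct
  }

  say("stage pic: category screen against proteome size")
  screen_tree <- species_tree
  if (!ape::is.binary(screen_tree)) screen_tree <- resolve_polytomies(screen_tree)
  screen <- category_screen(screen_tree, counts_by_cat, bundle$proteome_sizes)
  utils::write.table(screen, file.path(out_dir, "screen_results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  bl_cor <- branch_length_correlation(screen_tree, bundle$proteome_sizes)

  manifest <- structure(list(
    config = if (!is.null(config)) unclass(config) else NULL,
    seed = if (!is.null(config)) config$seed else NA_integer_,
    version = as.character(utils::packageVersion("bqpipe")),
    input_dir = input_dir,
    input_digests = digest_dir(input_dir),
    out_dir = out_dir,
    summary = list(
      n_species = length(table$species),
      pangenome = list(core = pangenome$n_core, shared = pangenome$n_shared,
                       unique = pangenome$n_unique),
      og_stats = list(n_ogs = og_stats$n_ogs, total_genes = og_stats$total_genes,
                      pct_assigned = og_stats$pct_assigned,
                      mean_og_size = og_stats$mean_og_size),
      efficiency = list(direct = efficiency$efficiency_direct,
                        effective = efficiency$efficiency_effective),
      congruence_pct = congruence,
      degenerate_measures = degenerate,
      n_significant = sum(screen$significant),
      n_categories = nrow(screen),
      significant_categories = screen$category[screen$significant],
      branch_length_r = bl_cor$r, branch_length_p = bl_cor$p
    ),
    screen = screen,
    networks = networks,
    network_trees = network_trees,
    species_tree = species_tree,
    bundle = bundle
  ), class = "run_manifest")
  report(manifest, out_dir)
  manifest
}

species_of_genes <- function(table) {
  out <- character(0)
  for (og in names(table$genes)) {
    for (s in table$species) {
      g <- table$genes[[og]][[s]]
      if (length(g)) out[g] <- s
    }
  }
  for (s in table$species) {
    g <- table$unassigned[[s]]
    if (length(g)) out[g] <- s
  }
  out
}

digest_dir <- function(dir) {
  if (is.null(dir) || !dir.exists(dir)) return(character(0))
  files <- sort(list.files(dir, full.names = TRUE))
  stats::setNames(as.character(tools::md5sum(files)), basename(files))
}

#' Write the human- and machine-readable pipeline report
#'
#' Emits `report.txt` (prose summary, including the Adkins-Canberra vs
#' Jaccard congruence comparison) and `report.json` with the same
#' numbers.
#'
#' @param manifest a `run_manifest` from [run_pipeline()]
#' @param out_dir directory for the two report files
#' @return invisibly, the summary list written to JSON
#' @export
report <- function(manifest, out_dir = manifest$out_dir) {
  stopifnot(inherits(manifest, "run_manifest"))
  s <- manifest$summary
  if (is.null(s)) stop_invalid("manifest has no summary; pipeline incomplete")
  txt <- c(
    sprintf("bqpipe run (seed %s) -- %d species", manifest$seed, s$n_species),
    sprintf("pangenome: %d core / %d shared / %d unique orthogroups",
            s$pangenome$core, s$pangenome$shared, s$pangenome$unique),
    sprintf("orthogroups: %d OGs, %d genes, %.1f%% assigned, mean size %.2f",
            s$og_stats$n_ogs, s$og_stats$total_genes,
            s$og_stats$pct_assigned, s$og_stats$mean_og_size),
    sprintf("KO mapping efficiency: %.1f%% direct -> %.1f%% after propagation",
            s$efficiency$direct, s$efficiency$effective),
    "congruence of network trees with the species tree (% shared splits):",
    vapply(names(s$congruence_pct), function(ms) {
      v <- s$congruence_pct[[ms]]
      if (is.na(v)) sprintf("  %-9s degenerate (identical networks; no NJ topology)", ms)
      else sprintf("  %-9s %.1f%%", ms, v)
    }, character(1)),
    sprintf("PIC screen: %d of %d categories significant (R > %.2f, p < %.2f): %s",
            s$n_significant, s$n_categories,
            attr(manifest$screen, "r_threshold"), attr(manifest$screen, "alpha"),
            paste(s$significant_categories, collapse = ", ")),
    sprintf("root-to-tip branch length vs proteome size: R = %s, p = %s",
            format(s$branch_length_r, digits = 3), format(s$branch_length_p, digits = 3))
  )
  writeLines(txt, file.path(out_dir, "report.txt"))
  jsonlite::write_json(s, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(s)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %s; see report.txt in %s\n", x$seed, x$out_dir))
  invisible(x)
}
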