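# Synthetic genome-reduction scenarios.
#
# The simulator generates the full input bundle the analysis consumes --
# species tree, orthogroup table, partial KO annotations, KO -> reaction ->
# compound map, proteome sizes -- under a generative model of lineage-
# specific gene loss. Gene content starts complete at the root and each
# gene copy is lost along a branch as a Poisson process: survival over a
# branch of length L is exp(-rate * L). The loss rate is
# base_loss_rate, multiplied by the category's ppe_loss_multiplier on
# branches all of whose descendant tips are designated "PPE" (reduced)
# lineages. Informational categories are additionally coupled to current
# proteome size: their rate is scaled by (1 + lambda * (1 - P/P_root)),
# so lineages that have already shrunk lose informational genes faster --
# the proteomic-constraint direction of causality. Soluble-metabolite and
# informational categories carry multipliers > 1 in the default scenario
# (the Black Queen / proteomic-constraint world); insoluble ones sit at 1.

#' Specify one functional category of orthogroups
#'
#' @param category_id KEGG-pathway-like label, e.g. `"KO00220"`
#' @param n_ogs number of orthogroups in the category
#' @param solubility one of `"soluble"`, `"insoluble"`, `"informational"`,
#'   `"neutral"` -- drives which loss multipliers apply
#' @param ppe_loss_multiplier loss-rate multiplier on all-PPE branches
#'   (>= 0; 1 = no lineage effect)
#' @return object of class `category_spec`
#' @export
category_spec <- function(category_id, n_ogs, solubility, ppe_loss_multiplier = 1) {
  solubility <- match.arg(solubility, c("soluble", "insoluble", "informational", "neutral"))
  if (!is_count(n_ogs) || n_ogs < 1L) stop_invalid("n_ogs must be a positive integer")
  if (!is.numeric(ppe_loss_multiplier) || ppe_loss_multiplier < 0) {
    stop_invalid("ppe_loss_multiplier must be >= 0")
  }
  structure(list(category_id = as.character(category_id), n_ogs = as.integer(n_ogs),
                 solubility = solubility, ppe_loss_multiplier = ppe_loss_multiplier),
            class = "category_spec")
}

#' Default category set of the genome-reduction scenario
#'
#' Mirrors the pathway classes at stake in the picoeukaryote analysis:
#' soluble-metabolite biosynthesis (amino acids, carotenoids -- lost
#' preferentially from reduced lineages), insoluble-metabolite
#' biosynthesis (fatty acids, lipids, steroids -- retained),
#' informational-fidelity machinery (DNA repair, translation factors,
#' tRNA biogenesis -- coupled to proteome size), and a neutral class.
#'
#' @param n_ogs_per_category orthogroups per category (default 50)
#' @param soluble_multiplier,informational_multiplier loss-rate
#'   multipliers on all-PPE branches (defaults 300 and 200). Large relative
#'   to the background rate: preferential loss is concentrated in the
#'   reduced lineages while background turnover stays small ("retained"
#'   insoluble pathways).
#' @return list of [category_spec()]
#' @export
default_categories <- function(n_ogs_per_category = 50L,
                               soluble_multiplier = 300,
                               informational_multiplier = 200) {
  spec <- list(
    c("KO00220", "soluble"), c("KO00300", "soluble"),
    c("KO00400", "soluble"), c("KO00906", "soluble"),
    c("KO00061", "insoluble"), c("KO01004", "insoluble"), c("KO00100", "insoluble"),
    c("KO03400", "informational"), c("KO03012", "informational"),
    c("KO03016", "informational"),
    c("KO00500", "neutral")
  )
  lapply(spec, function(s) {
    mult <- switch(s[2L], soluble = soluble_multiplier,
                   informational = informational_multiplier, 1)
    category_spec(s[1L], n_ogs_per_category, s[2L], mult)
  })
}

#' Scenario configuration for the genome-reduction simulator
#'
#' Defaults state the world the analysis assumes: 16 species of which 7
#' are reduced ("PPE") lineages, category-structured gene content with
#' elevated loss of soluble-pathway and informational genes in the PPE
#' lineages, and partial direct KO annotation.
#'
#' @param n_species number of species (>= 3)
#' @param n_ppe number of reduced lineages (< n_species); the PPE tips are
#'   the first `n_ppe` tips in the tree's fixed tip ordering
#' @param categories list of [category_spec()]
#' @param base_loss_rate expected losses per gene per unit branch length
#' @param annotation_fraction probability a surviving gene receives a
#'   direct K assignment
#' @param info_lambda strength of the informational-loss coupling to
#'   current proteome size (rate multiplier `1 + lambda * (1 - P/P_root)`)
#' @param root_copy_lambda Poisson rate for extra gene copies per
#'   orthogroup at the root (root copies = 1 + Poisson(lambda); paralogy)
#' @param unassigned_lambda mean number of species-specific singleton
#'   genes per species (genes outside any orthogroup). In real genomes
#'   this lineage-specific complement is a large, variable share of the
#'   proteome, and it is what decouples proteome size from the shared
#'   background-loss process.
#' @param unassigned_sigma lognormal standard deviation (log scale) of
#'   the per-species singleton mean: each species draws its own mean
#'   `unassigned_lambda * exp(N(-sigma^2/2, sigma))` (so the expectation
#'   stays `unassigned_lambda`), then a Poisson count. 0 = constant mean.
#' @param annotation_noise probability a direct annotation is replaced by
#'   a random wrong K number (tests consensus tie-breaking; default 0)
#' @param seed integer master seed
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(n_species = 16L, n_ppe = 7L,
                            categories = default_categories(),
                            base_loss_rate = 0.005,
                            annotation_fraction = 0.3,
                            info_lambda = 4,
                            root_copy_lambda = 0.3,
                            unassigned_lambda = 230,
                            unassigned_sigma = 0.25,
                            annotation_noise = 0,
                            seed = 1L) {
  if (!is_count(n_species) || n_species < 3L) stop_invalid("n_species must be an integer >= 3")
  if (!is_count(n_ppe) || n_ppe < 0L || n_ppe >= n_species) {
    stop_invalid("n_ppe must satisfy 0 <= n_ppe < n_species")
  }
  if (annotation_fraction < 0 || annotation_fraction > 1) {
    stop_invalid("annotation_fraction must lie in [0, 1]")
  }
  rates <- c(base_loss_rate, info_lambda, root_copy_lambda, unassigned_lambda,
             unassigned_sigma, annotation_noise)
  if (any(rates < 0)) stop_invalid("rates must be >= 0")
  stopifnot(all(vapply(categories, inherits, logical(1), "category_spec")))
  structure(list(n_species = as.integer(n_species), n_ppe = as.integer(n_ppe),
                 categories = categories, base_loss_rate = base_loss_rate,
                 annotation_fraction = annotation_fraction,
                 info_lambda = info_lambda, root_copy_lambda = root_copy_lambda,
                 unassigned_lambda = unassigned_lambda,
                 unassigned_sigma = unassigned_sigma,
                 annotation_noise = annotation_noise, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a rooted binary species tree
#'
#' Random binary topology with strictly positive uniform branch lengths;
#' tips are labelled `sp01`, `sp02`, ... in the tree's cladewise tip
#' order, so the first `n_ppe` labels form a reproducible (and partly
#' clustered) set of reduced lineages. Deterministic for a fixed seed.
#'
#' @param n_species number of tips (>= 3)
#' @param seed integer seed
#' @return rooted binary `phylo` tree
#' @export
simulate_species_tree <- function(n_species, seed = 1L) {
  if (!is_count(n_species) || n_species < 3L) stop_invalid("n_species must be an integer >= 3")
  set.seed(derive_seed(seed, "species_tree"))
  tree <- ape::rtree(n_species, rooted = TRUE)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

ppe_tips <- function(tree, n_ppe) {
  sort(tree$tip.label)[seq_len(n_ppe)]
}

# For each edge, TRUE iff every tip descending from it is a PPE tip.
edge_all_ppe <- function(tree, ppe) {
  n_tip <- length(tree$tip.label)
  is_ppe_tip <- tree$tip.label %in% ppe
  all_ppe <- rep(FALSE, n_tip + tree$Nnode)
  all_ppe[seq_len(n_tip)] <- is_ppe_tip
  # postorder: compute per-node flags children-first
  po <- ape::postorder(tree)
  node_flag <- all_ppe
  has_kids <- rep(FALSE, n_tip + tree$Nnode)
  kid_and <- rep(TRUE, n_tip + tree$Nnode)
  for (e in po) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    kid_and[parent] <- kid_and[parent] && node_flag[child]
    has_kids[parent] <- TRUE
    node_flag[parent] <- kid_and[parent]
  }
  node_flag[tree$edge[, 2L]]
}

#' Simulate category-structured gene content along a species tree
#'
#' Runs the branch-wise Poisson loss process described in the package
#' overview and assembles a complete, mutually consistent input bundle:
#' orthogroup table (with species-specific singletons in `unassigned`),
#' gene counts, partial direct KO annotations (one K number per
#' orthogroup, plus optional annotation noise), a KO -> reaction ->
#' compound map with category-structured compound pools, a KO -> pathway
#' map, and per-species proteome sizes (orthogroup genes + singletons).
#'
#' @param tree rooted binary `phylo` tree from [simulate_species_tree()]
#' @param config a [scenario_config()]
#' @return object of class `fixture_bundle`; see fields in the
#'   description. Ground-truth slots (`og_category`, `og_k`, `ppe`) allow
#'   downstream results to be checked against the simulated truth.
#' @export
simulate_gene_content <- function(tree, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(tree$tip.label) < config$n_ppe + 1L) {
    stop_invalid("tree needs at least n_ppe + 1 tips")
  }
  set.seed(derive_seed(config$seed, "gene_content"))
  species <- sort(tree$tip.label)
  ppe <- ppe_tips(tree, config$n_ppe)

  cats <- config$categories
  n_ogs_total <- sum(vapply(cats, `[[`, integer(1), "n_ogs"))
  og_ids <- sprintf("OG%07d", seq_len(n_ogs_total))
  og_category <- rep(vapply(cats, `[[`, character(1), "category_id"),
                     vapply(cats, `[[`, integer(1), "n_ogs"))
  og_solubility <- rep(vapply(cats, `[[`, character(1), "solubility"),
                       vapply(cats, `[[`, integer(1), "n_ogs"))
  og_mult <- rep(vapply(cats, `[[`, numeric(1), "ppe_loss_multiplier"),
                 vapply(cats, `[[`, integer(1), "n_ogs"))
  names(og_category) <- names(og_solubility) <- names(og_mult) <- og_ids
  og_k <- stats::setNames(sprintf("K%05d", seq_len(n_ogs_total)), og_ids)

  root_copies <- 1L + stats::rpois(n_ogs_total, config$root_copy_lambda)
  p_root <- sum(root_copies)

  # branch-wise loss: copies[node, og] filled root-down
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  copies <- matrix(NA_integer_, nrow = n_tip + tree$Nnode, ncol = n_ogs_total)
  copies[root_node, ] <- root_copies
  all_ppe_edge <- edge_all_ppe(tree, ppe)
  is_info <- og_solubility == "informational"
  # preorder: parents before children (reverse postorder)
  pre <- rev(ape::postorder(tree))
  for (e in pre) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    p_parent <- sum(copies[parent, ])
    info_factor <- 1 + config$info_lambda * (1 - p_parent / p_root)
    rate <- config$base_loss_rate *
      (if (all_ppe_edge[e]) og_mult else rep(1, n_ogs_total)) *
      ifelse(is_info, info_factor, 1)
    surv <- exp(-rate * len)
    copies[child, ] <- stats::rbinom(n_ogs_total, copies[parent, ], surv)
  }

  # materialise genes at the tips
  genes <- stats::setNames(vector("list", n_ogs_total), og_ids)
  for (og_i in seq_len(n_ogs_total)) {
    genes[[og_i]] <- stats::setNames(rep(list(character(0)), length(species)), species)
  }
  unassigned <- stats::setNames(rep(list(character(0)), length(species)), species)
  direct <- character(0)
  k_universe <- unname(og_k)
  for (sp in species) {
    tip_i <- match(sp, tree$tip.label)
    counter <- 0L
    for (og_i in seq_len(n_ogs_total)) {
      cnt <- copies[tip_i, og_i]
      if (cnt > 0L) {
        ids <- sprintf("%s_g%04d", sp, counter + seq_len(cnt))
        counter <- counter + cnt
        genes[[og_i]][[sp]] <- ids
        annotate <- stats::runif(cnt) < config$annotation_fraction
        if (any(annotate)) {
          ks <- rep(og_k[[og_i]], sum(annotate))
          if (config$annotation_noise > 0) {
            flip <- stats::runif(length(ks)) < config$annotation_noise
            if (any(flip)) ks[flip] <- sample(k_universe, sum(flip), replace = TRUE)
          }
          direct[genes[[og_i]][[sp]][annotate]] <- ks
        }
      }
    }
    sigma <- config$unassigned_sigma %||% 0
    ua_mean <- config$unassigned_lambda *
      exp(stats::rnorm(1L, -sigma^2 / 2, sigma))
    n_ua <- stats::rpois(1L, ua_mean)
    if (n_ua > 0L) {
      unassigned[[sp]] <- sprintf("%s_g%04d", sp, counter + seq_len(n_ua))
    }
  }

  # orthogroup invariant: >= 2 genes total; singletons move to unassigned,
  # empty orthogroups are dropped (as an orthogroup inference tool would)
  sizes <- vapply(genes, function(row) sum(lengths(row)), integer(1))
  for (og in og_ids[sizes == 1L]) {
    sp <- names(which(lengths(genes[[og]]) == 1L))[1L]
    g <- genes[[og]][[sp]]
    unassigned[[sp]] <- c(unassigned[[sp]], g)
    direct <- direct[setdiff(names(direct), g)]
  }
  keep <- og_ids[sizes >= 2L]
  genes <- genes[keep]

  table <- orthogroup_table(species, genes, unassigned = unassigned)
  counts <- gene_counts(table)
  proteome_sizes <- vapply(species, function(sp) {
    sum(counts[, sp]) + length(unassigned[[sp]])
  }, numeric(1))

  map <- simulate_ko_map(og_k, og_category)
  ko_to_pathway <- data.frame(k = unname(og_k), pathway = unname(og_category),
                              stringsAsFactors = FALSE)

  structure(list(
    species_tree = tree, orthogroups = table, gene_counts = counts,
    annotations = direct, ko_map = map, ko_to_pathway = ko_to_pathway,
    proteome_sizes = proteome_sizes,
    og_category = og_category[keep], og_k = og_k[keep],
    og_root_copies = stats::setNames(root_copies, og_ids)[keep],
    ppe = ppe, config = config
  ), class = "fixture_bundle")
}

# One reaction per K (sometimes two), compounds drawn from a
# category-specific pool plus a small shared hub pool, so networks are
# category-structured but overlap between species.
simulate_ko_map <- function(og_k, og_category) {
  cats <- unique(unname(og_category))
  pools <- stats::setNames(lapply(seq_along(cats), function(i) {
    sprintf("C%02d%03d", i, seq_len(30L))
  }), cats)
  hubs <- sprintf("C99%03d", seq_len(10L))
  k2rn <- list(); rn2cpd <- list()
  rn_i <- 0L
  for (og in names(og_k)) {
    k <- og_k[[og]]
    n_rn <- 1L + (stats::runif(1) < 0.3)
    rns <- character(n_rn)
    for (j in seq_len(n_rn)) {
      rn_i <- rn_i + 1L
      rn <- sprintf("R%05d", rn_i)
      pool <- pools[[og_category[[og]]]]
      n_cpd <- sample(2:3, 1L)
      cpds <- sample(pool, n_cpd)
      if (stats::runif(1) < 0.3) cpds <- c(cpds[-1L], sample(hubs, 1L))
      rn2cpd[[rn]] <- unique(cpds)
      rns[j] <- rn
    }
    k2rn[[k]] <- rns
  }
  structure(list(ko_to_rn = k2rn, rn_to_cpds = rn2cpd), class = "ko_map")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d species (%d PPE), %d orthogroups, %d direct annotations\n",
              length(x$orthogroups$species), length(x$ppe),
              length(x$orthogroups$genes), length(x$annotations)))
  invisible(x)
}

#' Analytic per-tip survival probabilities by category
#'
#' For categories without the informational proteome-size coupling the
#' loss process is an inhomogeneous Poisson thinning, so a root gene copy
#' survives to a tip with probability `exp(-sum_e rate_e * len_e)` over
#' the root-to-tip branches. Used as the independent oracle for the
#' simulator. Informational categories (coupled to the realised proteome
#' trajectory) return `NA`.
#'
#' @param tree the species tree
#' @param config the [scenario_config()]
#' @return matrix tips x categories of survival probabilities
#' @export
expected_category_survival <- function(tree, config) {
  ppe <- ppe_tips(tree, config$n_ppe)
  all_ppe_edge <- edge_all_ppe(tree, ppe)
  cats <- config$categories
  cat_ids <- vapply(cats, `[[`, character(1), "category_id")
  out <- matrix(NA_real_, nrow = length(tree$tip.label), ncol = length(cats),
                dimnames = list(tree$tip.label, cat_ids))
  # accumulate per-tip weighted path lengths (plain and PPE-weighted)
  n_all <- length(tree$tip.label) + tree$Nnode
  plain <- rep(0, n_all); weighted <- rep(0, n_all)
  pre <- rev(ape::postorder(tree))
  for (e in pre) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    plain[child] <- plain[parent] + len
    weighted[child] <- weighted[parent] + if (all_ppe_edge[e]) 0 else len
  }
  ppe_len <- plain - weighted  # path length spent on all-PPE branches
  for (ci in seq_along(cats)) {
    if (cats[[ci]]$solubility == "informational" && config$info_lambda > 0) next
    mult <- cats[[ci]]$ppe_loss_multiplier
    exponent <- config$base_loss_rate *
      (weighted[seq_along(tree$tip.label)] + mult * ppe_len[seq_along(tree$tip.label)])
    out[, ci] <- exp(-exponent)
  }
  out
}

#' Write a fixture bundle to disk as plain-text files
#'
#' Emits exactly the formats the I/O modules consume: `Orthogroups.tsv`,
#' `Orthogroups.GeneCount.csv`, `unassigned.tsv`, one
#' `<species>.gene2ko.tsv` per species, `ko2rn.tsv`, `rn2cpd.tsv`,
#' `ko2pathway.tsv`, `species_tree.nwk` and `proteome_sizes.tsv`.
#' Reading the directory back with [read_fixture_bundle()] reproduces the
#' bundle.
#'
#' @param bundle a [simulate_gene_content()] result
#' @param directory output directory (created if needed)
#' @return named character vector of file paths
#' @export
emit_fixture_files <- function(bundle, directory) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- c(
    orthogroups = file.path(directory, "Orthogroups.tsv"),
    gene_counts = file.path(directory, "Orthogroups.GeneCount.csv"),
    unassigned = file.path(directory, "unassigned.tsv"),
    ko2rn = file.path(directory, "ko2rn.tsv"),
    rn2cpd = file.path(directory, "rn2cpd.tsv"),
    ko2pathway = file.path(directory, "ko2pathway.tsv"),
    species_tree = file.path(directory, "species_tree.nwk"),
    proteome_sizes = file.path(directory, "proteome_sizes.tsv")
  )
  write_orthogroups_tsv(bundle$orthogroups, paths[["orthogroups"]])
  write_gene_counts_csv(bundle$gene_counts, paths[["gene_counts"]])
  ua <- bundle$orthogroups$unassigned
  ua_df <- data.frame(species = rep(names(ua), lengths(ua)),
                      gene = unlist(ua, use.names = FALSE))
  utils::write.table(ua_df, paths[["unassigned"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_ko_map(bundle$ko_map, paths[["ko2rn"]], paths[["rn2cpd"]])
  utils::write.table(bundle$ko_to_pathway, paths[["ko2pathway"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_newick(bundle$species_tree, paths[["species_tree"]])
  ps <- data.frame(species = names(bundle$proteome_sizes),
                   n_genes = as.integer(bundle$proteome_sizes))
  utils::write.table(ps, paths[["proteome_sizes"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (sp in bundle$orthogroups$species) {
    p <- file.path(directory, paste0(sp, ".gene2ko.tsv"))
    ann <- bundle$annotations[startsWith(names(bundle$annotations), paste0(sp, "_"))]
    df <- data.frame(gene = names(ann), k = unname(ann))
    utils::write.table(df, p, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    paths[[paste0("gene2ko_", sp)]] <- p
  }
  paths
}

#' Read a fixture directory back into a bundle
#'
#' Inverse of [emit_fixture_files()] (ground-truth slots such as the
#' orthogroup -> category map are rebuilt from the KO -> pathway file).
#'
#' @param directory a directory written by [emit_fixture_files()]
#' @return a `fixture_bundle` (without the simulation `config`)
#' @export
read_fixture_bundle <- function(directory) {
  ua_df <- utils::read.delim(file.path(directory, "unassigned.tsv"),
                             stringsAsFactors = FALSE)
  tree <- read_newick(file.path(directory, "species_tree.nwk"))
  table0 <- read_orthogroups_tsv(file.path(directory, "Orthogroups.tsv"))
  ua <- stats::setNames(rep(list(character(0)), length(table0$species)), table0$species)
  for (i in seq_len(nrow(ua_df))) {
    ua[[ua_df$species[i]]] <- c(ua[[ua_df$species[i]]], ua_df$gene[i])
  }
  table <- orthogroup_table(table0$species, table0$genes, unassigned = ua)
  ann_paths <- file.path(directory, paste0(table$species, ".gene2ko.tsv"))
  direct <- load_gene_ko_tsv(ann_paths[file.exists(ann_paths)])
  map <- read_ko_map(file.path(directory, "ko2rn.tsv"),
                     file.path(directory, "rn2cpd.tsv"))
  k2p <- utils::read.delim(file.path(directory, "ko2pathway.tsv"),
                           stringsAsFactors = FALSE)
  ps_df <- utils::read.delim(file.path(directory, "proteome_sizes.tsv"),
                             stringsAsFactors = FALSE)
  structure(list(
    species_tree = tree, orthogroups = table, gene_counts = gene_counts(table),
    annotations = direct, ko_map = map, ko_to_pathway = k2p,
    proteome_sizes = stats::setNames(as.numeric(ps_df$n_genes), ps_df$species),
    og_category = NULL, og_k = NULL, og_root_copies = NULL,
    ppe = NULL, config = NULL
  ), class = "fixture_bundle")
}
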