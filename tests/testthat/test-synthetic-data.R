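# The simulator is first-class code: its statistical behaviour is checked
# against analytic Poisson-survival calculations, not against itself.

test_that("simulate_species_tree produces rooted binary trees deterministically", {
  tr3 <- simulate_species_tree(3, seed = 1L)
  expect_s3_class(tr3, "phylo")
  expect_length(tr3$tip.label, 3L)
  expect_equal(tr3$Nnode, 2L)
  expect_true(ape::is.rooted(tr3) && ape::is.binary(tr3))

  tr16 <- simulate_species_tree(16, seed = 7L)
  expect_length(tr16$tip.label, 16L)
  expect_equal(tr16$Nnode, 15L)  # 2n - 1 nodes on a rooted binary tree
  expect_true(all(tr16$edge.length > 0))
  expect_false(anyDuplicated(tr16$tip.label) > 0)

  expect_identical(ape::write.tree(simulate_species_tree(16, seed = 7L)),
                   ape::write.tree(tr16))
  expect_error(simulate_species_tree(2, seed = 1L), class = "bqpipe_invalid_argument")
})

test_that("scenario_config validates its invariants", {
  expect_error(scenario_config(n_species = 5, n_ppe = 5), class = "bqpipe_invalid_argument")
  expect_error(scenario_config(annotation_fraction = 1.2), class = "bqpipe_invalid_argument")
  expect_error(scenario_config(base_loss_rate = -0.1), class = "bqpipe_invalid_argument")
  expect_error(category_spec("KO1", 3, "soluble", -1), class = "bqpipe_invalid_argument")
})

test_that("no-loss limit: all tips carry the root content exactly", {
  b <- small_bundle(seed = 5L, base_loss_rate = 0, unassigned_lambda = 0)
  counts <- b$gene_counts
  # every species has the same per-OG count, equal to the root copy number
  for (og in rownames(counts)) {
    expect_true(all(counts[og, ] == b$og_root_copies[[og]]))
  }
  pg <- pangenome_partition(b$orthogroups)
  expect_equal(pg$n_core, nrow(counts))
  expect_equal(pg$n_shared + pg$n_unique, 0L)
})

test_that("tip gene counts match analytic Poisson survival probabilities", {
  # one big soluble category with a strong multiplier; survival at a tip is
  # exp(-sum_e rate_e * len_e), computable branch by branch
  cfg <- scenario_config(
    n_species = 10L, n_ppe = 4L,
    categories = list(category_spec("KOSOL", 2000L, "soluble", 50)),
    base_loss_rate = 0.03, root_copy_lambda = 0, unassigned_lambda = 0,
    annotation_fraction = 0, seed = 11L
  )
  tree <- simulate_species_tree(10, seed = 11L)
  b <- simulate_gene_content(tree, cfg)
  surv <- expected_category_survival(tree, cfg)[, "KOSOL"]
  # per-tip observed survivors vs Binomial(2000, p) expectation
  tip_counts <- colSums(b$gene_counts)[names(surv)]
  n0 <- 2000
  for (sp in names(surv)) {
    sd_bin <- sqrt(n0 * surv[[sp]] * (1 - surv[[sp]]))
    expect_lt(abs(tip_counts[[sp]] - n0 * surv[[sp]]), 5 * sd_bin + 3)
  }
  ppe <- b$ppe
  expect_lt(mean(tip_counts[ppe]), mean(tip_counts[setdiff(names(surv), ppe)]))
})

test_that("increasing the PPE multiplier never increases expected PPE gene counts", {
  mean_ppe_count <- function(mult, seed) {
    cfg <- scenario_config(
      n_species = 10L, n_ppe = 4L,
      categories = list(category_spec("KOSOL", 200L, "soluble", mult)),
      base_loss_rate = 0.03, root_copy_lambda = 0, unassigned_lambda = 0,
      annotation_fraction = 0, seed = seed
    )
    b <- simulate_gene_content(simulate_species_tree(10, seed = seed), cfg)
    mean(colSums(b$gene_counts)[b$ppe])
  }
  for (seed in 1:4) {
    counts <- vapply(c(1, 10, 50), mean_ppe_count, numeric(1), seed = seed)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("annotation_fraction = 1 annotates every surviving orthogroup gene", {
  b <- small_bundle(seed = 2L, annotation_fraction = 1)
  og_genes <- unlist(lapply(b$orthogroups$genes, unlist), use.names = FALSE)
  expect_setequal(names(b$annotations), og_genes)
  expect_true(all(grepl("^K[0-9]{5}$", b$annotations)))
})

test_that("fixture emission is deterministic and round-trips exactly", {
  b <- small_bundle(seed = 9L)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  emit_fixture_files(b, d1)
  emit_fixture_files(small_bundle(seed = 9L), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }

  back <- read_fixture_bundle(d1)
  expect_identical(back$orthogroups$species, b$orthogroups$species)
  expect_identical(back$orthogroups$genes, b$orthogroups$genes)
  expect_identical(lapply(back$orthogroups$unassigned, sort),
                   lapply(b$orthogroups$unassigned, sort))
  expect_identical(back$gene_counts, b$gene_counts)
  expect_identical(back$annotations[sort(names(back$annotations))],
                   b$annotations[sort(names(b$annotations))])
  expect_identical(back$ko_map, b$ko_map)
  expect_equal(back$proteome_sizes, b$proteome_sizes)
  expect_equal(unname(phangorn::RF.dist(back$species_tree, b$species_tree)), 0)
})

test_that("proteome sizes equal orthogroup genes plus unassigned singletons", {
  b <- small_bundle(seed = 4L)
  for (sp in b$orthogroups$species) {
    expect_equal(
      unname(b$proteome_sizes[[sp]]),
      sum(b$gene_counts[, sp]) + length(b$orthogroups$unassigned[[sp]])
    )
  }
  # every annotated K appears in the ko map
  expect_true(all(b$annotations %in% names(b$ko_map$ko_to_rn)))
})

test_that("empty-ish bundles still emit valid files", {
  cfg <- scenario_config(
    n_species = 3L, n_ppe = 1L,
    categories = list(category_spec("KOX", 1L, "neutral", 1)),
    base_loss_rate = 0, unassigned_lambda = 0, seed = 1L
  )
  b <- simulate_gene_content(simulate_species_tree(3, seed = 1L), cfg)
  d <- file.path(tempdir(), "fx_min")
  unlink(d, recursive = TRUE)
  paths <- emit_fixture_files(b, d)
  expect_true(all(file.exists(paths)))
  # GeneCount.csv has one column per species (plus Orthogroup and Total)
  hdr <- strsplit(readLines(paths[["gene_counts"]], n = 1L), ",")[[1L]]
  expect_length(hdr, 3L + 2L)
})
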