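# Shared fixture builders. Everything is generated in code; no stored data.

# Minimal two-species, one-OG table: A has gA1,gA2; B has gB1.
tiny_table <- function() {
  orthogroup_table(
    species = c("A", "B"),
    genes = list(OG0 = list(A = c("gA1", "gA2"), B = "gB1"))
  )
}

# Small, fast simulation scenario (fewer OGs than the default world).
small_config <- function(seed = 1L, ...) {
  args <- list(
    n_species = 10L, n_ppe = 4L,
    categories = default_categories(n_ogs_per_category = 8L),
    unassigned_lambda = 10,
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}

small_bundle <- function(seed = 1L, ...) {
  cfg <- small_config(seed = seed, ...)
  simulate_gene_content(simulate_species_tree(cfg$n_species, seed = cfg$seed), cfg)
}

# Hand-built ko map: K00001 -> r1 -> {c1, c2}; K00002 -> {r1, r2},
# r2 -> {c2, c3}; K00003 -> r3 -> {c4} (single-compound reaction).
toy_ko_map <- function() {
  ko_map(
    ko_to_rn = data.frame(k = c("K00001", "K00002", "K00002", "K00003"),
                          rn = c("r1", "r1", "r2", "r3")),
    rn_to_cpd = data.frame(rn = c("r1", "r1", "r2", "r2", "r3"),
                           cpd = c("c1", "c2", "c2", "c3", "c4"))
  )
}

# Random nonnegative vectors with some exact zeros (for metric properties).
random_nonneg <- function(n, zero_frac = 0.3) {
  x <- stats::runif(n, 0, 5)
  x[stats::runif(n) < zero_frac] <- 0
  x
}

# Correlated bivariate Brownian traits on a tree: x and y are BM with
# correlation rho, built from two independent BM traits.
bm_pair <- function(tree, rho) {
  z1 <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  z2 <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  list(x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
}
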