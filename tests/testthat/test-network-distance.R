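# Term-by-term reference implementations, deliberately written differently
# from the package code (explicit loops), used as oracles.
ref_canberra <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) {
    d <- abs(x[i]) + abs(y[i])
    if (d > 0) s <- s + abs(x[i] - y[i]) / d
  }
  s
}
ref_wjac <- function(x, y) {
  hi <- 0; lo <- 0
  for (i in seq_along(x)) { hi <- hi + max(x[i], y[i]); lo <- lo + min(x[i], y[i]) }
  if (hi == 0) 0 else 1 - lo / hi
}

test_that("the four distance measures reproduce the worked examples", {
  expect_equal(jaccard_distance(c("a", "b", "c"), c("b", "c", "d")), 1 - 2 / 4)
  expect_equal(weighted_jaccard(c(1, 2, 0), c(2, 1, 1)), 1 - 2 / 5)
  expect_equal(canberra(c(1, 2, 0), c(2, 1, 1)), 1 / 3 + 1 / 3 + 1)
  expect_equal(adkins_canberra(c(1, 2, 0), c(2, 1, 1)), (5 / 3) / 3)
})

test_that("boundary behaviour: identity, disjoint sets, joint zeros, NZ = 0", {
  expect_equal(jaccard_distance(letters[1:3], letters[1:3]), 0)
  expect_equal(jaccard_distance(c("a"), c("b")), 1)
  expect_equal(jaccard_distance(character(0), character(0)), 0)
  expect_equal(weighted_jaccard(c(0, 0), c(0, 0)), 0)
  expect_equal(canberra(c(1, 0), c(2, 0)), 1 / 3)   # joint-zero term skipped
  expect_equal(adkins_canberra(c(1, 0, 0), c(0, 0, 0)), 1)  # single active term
  expect_warning(z <- adkins_canberra(c(0, 0), c(0, 0)), "NZ = 0")
  expect_equal(z, 0)
  # strict "nonzero in both" reading available as an option
  expect_equal(adkins_canberra(c(1, 2, 0), c(2, 1, 1), nz = "both"), (5 / 3) / 2)
})

test_that("invalid inputs are rejected", {
  expect_error(weighted_jaccard(c(1, -1), c(1, 1)), class = "bqpipe_invalid_argument")
  expect_error(canberra(c(1, 2), c(1, 2, 3)), class = "bqpipe_invalid_argument")
})

test_that("metric axioms hold on random nonnegative vectors", {
  withr::local_seed(42)
  for (rep in 1:25) {
    x <- random_nonneg(12); y <- random_nonneg(12); z <- random_nonneg(12)
    for (f in list(weighted_jaccard, canberra,
                   function(a, b) suppressWarnings(adkins_canberra(a, b)))) {
      expect_equal(f(x, x), 0)
      expect_equal(f(x, y), f(y, x))
      expect_gte(f(x, y), 0)
    }
    # Canberra is a metric: triangle inequality
    expect_lte(canberra(x, z), canberra(x, y) + canberra(y, z) + 1e-12)
    # termwise scale invariance
    c_scale <- stats::runif(1, 0.1, 10)
    expect_equal(weighted_jaccard(c_scale * x, c_scale * y), weighted_jaccard(x, y))
    expect_equal(canberra(c_scale * x, c_scale * y), canberra(x, y))
    # against the loop oracles
    expect_equal(canberra(x, y), ref_canberra(x, y))
    expect_equal(weighted_jaccard(x, y), ref_wjac(x, y))
  }
})

test_that("weighted Jaccard equals unweighted on all 0/1 vectors of a 5-universe", {
  universe <- letters[1:5]
  subsets <- lapply(0:31, function(m) universe[bitwAnd(m, 2^(0:4)) > 0])
  for (i in subsets) {
    for (j in subsets) {
      xi <- as.numeric(universe %in% i)
      xj <- as.numeric(universe %in% j)
      expect_equal(weighted_jaccard(xi, xj), jaccard_distance(i, j))
    }
  }
})

test_that("distance_matrix agrees with pairwise calls and respects relabeling", {
  b <- small_bundle(seed = 5L, annotation_fraction = 1)
  ann <- propagate_ko(b$orthogroups, b$annotations)
  sp_of <- bqpipe:::species_of_genes(b$orthogroups)
  networks <- lapply(b$orthogroups$species[1:4], function(sp) {
    build_network(ann$effective$k[sp_of[ann$effective$gene] == sp],
                  b$ko_map, species = sp)
  })
  for (ms in c("jaccard", "wjaccard", "canberra", "adcan")) {
    m <- distance_matrix(networks, measure = ms)
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) == 0))
    universe <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
    v1 <- node_abundance_vector(networks[[1]], universe)
    v3 <- node_abundance_vector(networks[[3]], universe)
    pair <- switch(ms,
                   jaccard = jaccard_distance(networks[[1]]$nodes, networks[[3]]$nodes),
                   wjaccard = weighted_jaccard(v1, v3),
                   canberra = canberra(v1, v3),
                   adcan = adkins_canberra(v1, v3))
    expect_equal(m[1, 3], pair)
  }
  m1 <- distance_matrix(networks, measure = "adcan")
  m2 <- distance_matrix(rev(networks), measure = "adcan")
  expect_equal(m2[rownames(m1), colnames(m1)], m1)
  expect_error(distance_matrix(networks[1:2]), class = "bqpipe_invalid_argument")
  # three identical networks give the zero matrix
  same <- lapply(c("a", "b", "c"), function(s) {
    nw <- networks[[1]]; nw$species <- s; nw
  })
  expect_true(all(distance_matrix(same, measure = "canberra") == 0))
})

test_that("PHYLIP lower-triangular files round-trip and have n + 1 lines", {
  b <- small_bundle(seed = 1L, annotation_fraction = 1)
  ann <- propagate_ko(b$orthogroups, b$annotations)
  sp_of <- bqpipe:::species_of_genes(b$orthogroups)
  networks <- lapply(b$orthogroups$species, function(sp) {
    build_network(ann$effective$k[sp_of[ann$effective$gene] == sp],
                  b$ko_map, species = sp)
  })
  m <- distance_matrix(networks, measure = "adcan")
  p <- withr::local_tempfile(fileext = ".phy")
  write_phylip_lower(m, p)
  expect_length(readLines(p), nrow(m) + 1L)
  back <- read_phylip_lower(p)
  expect_equal(back, m, tolerance = 1e-8)

  z <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  pz <- withr::local_tempfile(fileext = ".phy")
  write_phylip_lower(z, pz)
  lines <- readLines(pz)
  expect_identical(lines[1], "3")
  expect_match(lines[3], "^B +0")
  expect_match(lines[4], "^C +0 0")

  dup <- matrix(0, 2, 2, dimnames = list(c("samelongname1", "samelongname2"),
                                         c("samelongname1", "samelongname2")))
  expect_error(write_phylip_lower(dup, pz), class = "bqpipe_invalid_argument")
})
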