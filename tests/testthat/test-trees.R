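additive_4taxon <- function() {
  # unrooted tree: A and B joined (pendant 1, 2), internal branch 2,
  # C and D joined (pendant 3, 4)
  d <- matrix(c(0, 3, 6, 7,
                3, 0, 7, 8,
                6, 7, 0, 7,
                7, 8, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d
}

test_that("neighbor joining recovers an additive 4-taxon tree exactly", {
  d <- additive_4taxon()
  # four-point check that AB|CD is the generating split:
  # d(A,B) + d(C,D) < d(A,C) + d(B,D) = d(A,D) + d(B,C)
  expect_lt(d["A", "B"] + d["C", "D"], d["A", "C"] + d["B", "D"])
  expect_equal(d["A", "C"] + d["B", "D"], d["A", "D"] + d["B", "C"])

  tr <- neighbor_join(d)
  expect_identical(splits(tr), "A|B")
  # exact additive recovery: path distances equal the input matrix
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d)
  # pendant branch lengths are the generating ones
  bl <- stats::setNames(tr$edge.length[tr$edge[, 2] <= 4],
                        tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(bl[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4))
})

test_that("three taxa resolve by the three-point formulas; degenerate input is a star", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_join(d)
  bl <- stats::setNames(tr$edge.length[tr$edge[, 2] <= 3],
                        tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 2, C = 3))

  z <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tz <- neighbor_join(z)
  expect_true(all(tz$edge.length == 0))
  expect_error(neighbor_join(z[1:2, 1:2]), class = "bqpipe_invalid_argument")
  ns <- matrix(c(0, 1, 2, 2, 0, 1, 1, 2, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_error(neighbor_join(ns), class = "bqpipe_invalid_argument")
})

test_that("NJ is consistent on additive distances from random binary trees", {
  withr::local_seed(7)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n, rooted = FALSE)
    d <- ape::cophenetic.phylo(true)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    est <- neighbor_join(d)
    expect_equal(unname(phangorn::RF.dist(est, true)), 0)
    # and agrees topologically with the reference NJ implementation
    expect_equal(unname(phangorn::RF.dist(est, ape::nj(d))), 0)
  }
})

test_that("Newick I/O round-trips and guards malformed input", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:2):0;", p)
  tr <- read_newick(p)
  expect_length(tr$tip.label, 2L)

  writeLines("((A:1,B:2):3);", p)
  tr2 <- read_newick(p)
  expect_s3_class(tr2, "phylo")

  writeLines("((A:1,B:2;", p)
  expect_error(read_newick(p), "unbalanced", class = "bqpipe_parse_error")

  writeLines("(A,B,(C,D));", p)
  expect_warning(tr3 <- read_newick(p), "no branch lengths")
  expect_true(all(tr3$edge.length == 0))

  withr::local_seed(1)
  for (rep in 1:5) {
    tr <- ape::rtree(8)
    write_newick(tr, p)
    back <- read_newick(p)
    expect_equal(unname(phangorn::RF.dist(back, tr)), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  }
})

test_that("splits counts nontrivial bipartitions only", {
  t4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_identical(splits(t4), "A|B")
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_identical(splits(star), character(0))
  withr::local_seed(3)
  for (n in 5:10) {
    tr <- ape::rtree(n, rooted = FALSE)
    expect_length(splits(tr), n - 3L)
  }
})

test_that("shared_split_fraction and RF behave on known pairs and NNI moves", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(shared_split_fraction(t1, t1)$shared_pct, 100)
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  cg <- shared_split_fraction(t1, t2)
  expect_equal(cg$shared_pct, 0)
  expect_equal(cg$rf, 2L)
  t3 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(shared_split_fraction(t1, t3), class = "bqpipe_invalid_argument")

  withr::local_seed(11)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    nni <- phangorn::rNNI(tr, 1)
    cg <- shared_split_fraction(nni, tr)
    # cross-check the RF identity against phangorn on every draw
    expect_equal(cg$rf, unname(phangorn::RF.dist(nni, tr)))
    if (cg$rf == 2L) {  # generic case: one NNI changes exactly one split
      expect_equal(cg$shared_pct, 100 * (n - 4) / (n - 3))
    }
  }

  # denominator options
  cg_u <- shared_split_fraction(t1, t2, denominator = "union")
  expect_equal(cg_u$shared_pct, 0)
})

test_that("root-to-tip lengths sum the unique root path", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):3);", p)
  tr <- read_newick(p)
  rtl <- root_to_tip_lengths(tr)
  expect_equal(rtl[c("A", "B")], c(A = 4, B = 5))

  co <- ape::rcoal(8)  # ultrametric: all root-to-tip distances equal
  rtl_u <- root_to_tip_lengths(co)
  expect_equal(max(rtl_u) - min(rtl_u), 0, tolerance = 1e-10)

  # exhaustive path-sum oracle on a random rooted tree
  withr::local_seed(5)
  tr2 <- ape::rtree(10)
  rtl2 <- root_to_tip_lengths(tr2)
  for (tip in seq_along(tr2$tip.label)) {
    node <- tip; total <- 0
    while (node != 11L) {  # root = n_tip + 1
      e <- which(tr2$edge[, 2] == node)
      total <- total + tr2$edge.length[e]
      node <- tr2$edge[e, 1]
    }
    expect_equal(unname(rtl2[tr2$tip.label[tip]]), total)
  }

  expect_error(root_to_tip_lengths(ape::unroot(tr2)), class = "bqpipe_invalid_argument")
})
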