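# Tree construction and comparison.
#
# Trees are `ape` "phylo" objects throughout. Neighbor joining follows the
# Saitou & Nei agglomeration: repeatedly join the pair minimising
# Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k), with branch lengths
# from the canonical formulas, negative lengths clamped to zero, and ties
# broken by the lexicographically smallest pair of cluster representative
# labels so the result is deterministic. Congruence between two trees on
# the same tips is the fraction of nontrivial unrooted bipartitions
# (splits) they share.

#' Neighbor-joining tree from a distance matrix
#'
#' @param m symmetric numeric matrix with zero diagonal and species
#'   dimnames; at least 3 species.
#' @return an unrooted `phylo` tree. Negative branch lengths produced by
#'   the NJ formulas are clamped to 0 with a warning.
#' @export
neighbor_join <- function(m) {
  if (is.null(rownames(m))) stop_invalid("distance matrix must carry species dimnames")
  n <- nrow(m)
  if (n < 3L) stop_invalid("neighbor joining needs at least 3 taxa, got ", n)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE))) {
    stop_invalid("distance matrix is not symmetric")
  }
  if (any(abs(diag(m)) > 1e-12)) stop_invalid("distance matrix diagonal must be zero")
  labels <- rownames(m)
  d <- unname(m)
  # frag: newick fragment per active cluster; rep: smallest tip label inside
  frag <- labels
  rep_lab <- labels
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (length(frag) > 3L) {
    k <- length(frag)
    r <- rowSums(d)
    q <- (k - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest (min, max) label pair
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    bi <- clamp(0.5 * d[i, j] + (r[i] - r[j]) / (2 * (k - 2)))
    bj <- clamp(d[i, j] - (0.5 * d[i, j] + (r[i] - r[j]) / (2 * (k - 2))))
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], bi, frag[j], bj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  # three remaining clusters join at the unrooted central node
  b1 <- clamp(0.5 * (d[1, 2] + d[1, 3] - d[2, 3]))
  b2 <- clamp(0.5 * (d[1, 2] + d[2, 3] - d[1, 3]))
  b3 <- clamp(0.5 * (d[1, 3] + d[2, 3] - d[1, 2]))
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", frag[1], b1, frag[2], b2, frag[3], b3)
  if (clamped) warning("negative neighbor-joining branch length(s) clamped to 0")
  tree <- ape::read.tree(text = nwk)
  tree
}

#' Read a Newick tree file
#'
#' @param path path to a Newick file
#' @return a `phylo` tree. Missing branch lengths default to 0 with a
#'   warning.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_invalid("file does not exist: ", path)
  txt <- paste(readLines(path), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop_parse("unbalanced parentheses in ", path, ": ", n_open, " '(' vs ", n_close, " ')'")
  }
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop_parse("cannot parse Newick in ", path, ": ",
                                                  conditionMessage(e)))
  if (is.null(tree)) stop_parse("cannot parse Newick in ", path)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree
}

#' Write a tree as Newick
#' @param tree a `phylo` tree
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Nontrivial unrooted splits (bipartitions) of a tree
#'
#' Each internal edge of the unrooted tree bipartitions the tips; trivial
#' splits (one tip against the rest) are excluded. A split is stored in
#' canonical form as the sorted tip labels of the side containing the
#' lexicographically smallest tip, joined with `"|"`.
#'
#' @param tree a `phylo` tree (rooted trees are unrooted first)
#' @return character vector of canonical split keys (possibly empty)
#' @export
splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  n <- length(tips)
  if (n < 4L) return(character(0))
  tr <- ape::unroot(tree)
  parts <- ape::prop.part(tr)
  lab <- attr(parts, "labels")
  anchor <- min(lab)
  keys <- vapply(parts, function(idx) {
    side <- lab[idx]
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    if (!(anchor %in% side)) side <- setdiff(lab, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Shared-split congruence between two trees
#'
#' The percentage of nontrivial unrooted splits shared between a query
#' tree and a reference tree (by default relative to the reference's
#' split count), plus the Robinson-Foulds distance.
#'
#' @param t1 query tree (`phylo`)
#' @param t2 reference tree (`phylo`); must have the same tip set
#' @param denominator which split count normalises the percentage:
#'   `"reference"` (default; splits of `t2`), `"union"` or `"average"`
#' @return list of class `congruence` with `shared_pct`, `n_shared`,
#'   `n_splits_1`, `n_splits_2`, and `rf` (Robinson-Foulds distance)
#' @export
shared_split_fraction <- function(t1, t2, denominator = c("reference", "union", "average")) {
  denominator <- match.arg(denominator)
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop_invalid("trees have different tip sets")
  }
  s1 <- splits(t1); s2 <- splits(t2)
  n_shared <- length(intersect(s1, s2))
  denom <- switch(denominator,
                  reference = length(s2),
                  union = length(union(s1, s2)),
                  average = (length(s1) + length(s2)) / 2)
  structure(list(
    shared_pct = if (denom > 0) 100 * n_shared / denom else NA_real_,
    n_shared = n_shared,
    n_splits_1 = length(s1),
    n_splits_2 = length(s2),
    rf = length(s1) + length(s2) - 2L * n_shared,
    denominator = denominator
  ), class = "congruence")
}

#' @export
print.congruence <- function(x, ...) {
  cat(sprintf("<congruence> %.1f%% shared splits (%d/%d vs reference; RF = %d)\n",
              x$shared_pct, x$n_shared, x$n_splits_2, x$rf))
  invisible(x)
}

#' Root-to-tip path lengths
#'
#' Branch-length distance from the root (the ancestral node of all
#' species) to each tip.
#'
#' @param tree a rooted `phylo` tree with branch lengths
#' @return named numeric vector, one entry per tip
#' @export
root_to_tip_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop_invalid("tree must be rooted")
  if (is.null(tree$edge.length)) stop_invalid("tree must carry branch lengths")
  depths <- ape::node.depth.edgelength(tree)
  stats::setNames(depths[seq_along(tree$tip.label)], tree$tip.label)
}

#' Resolve polytomies with zero-length branches
#'
#' Independent-contrast computation requires a binary tree; this helper
#' resolves multifurcations arbitrarily (but deterministically) with
#' zero-length internal branches.
#'
#' @param tree a `phylo` tree
#' @return a binary `phylo` tree
#' @export
resolve_polytomies <- function(tree) {
  out <- ape::multi2di(tree, random = FALSE)
  if (is.null(out$edge.length)) out$edge.length <- rep(0, nrow(out$edge))
  out$edge.length[is.na(out$edge.length)] <- 0
  out
}
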