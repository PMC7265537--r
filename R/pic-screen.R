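# Phylogenetic independent contrasts (PIC) and the category correlation
# screen.
#
# Species trait values are not independent observations: closely related
# species resemble each other through shared ancestry. Felsenstein's
# contrasts transform n tip values on a rooted binary tree into n-1
# standardized differences that are mutually independent under Brownian
# motion, so ordinary correlation machinery applies. Because each
# contrast's sign is arbitrary (it depends on which daughter is "left"),
# correlation between two contrast sets is computed through the origin.

#' Phylogenetic independent contrasts
#'
#' Standard Felsenstein recursion: at each internal node with daughter
#' values x_L, x_R reached by (possibly extended) branch lengths v_L, v_R,
#' the contrast is (x_L - x_R) / sqrt(v_L + v_R); the node's ancestral
#' value is the precision-weighted average and its parent branch is
#' extended by v_L v_R / (v_L + v_R).
#'
#' @param tree rooted, binary `phylo` tree with nonnegative branch lengths
#' @param trait named numeric vector covering every tip label
#' @return numeric vector of n_tips - 1 standardized contrasts (named by
#'   internal node number)
#' @export
pic_contrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    stop_invalid("tree must be rooted and binary: resolve polytomies first ",
                 "(see resolve_polytomies())")
  }
  if (is.null(tree$edge.length)) stop_invalid("tree must carry branch lengths")
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing)) stop_invalid("trait missing for tips: ", paste(missing, collapse = ", "))
  trait <- as.numeric(trait[tree$tip.label])
  if (any(!is.finite(trait))) stop_invalid("trait values must be finite")

  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  x <- c(trait, rep(NA_real_, n_node))
  v_extra <- rep(0, n_tip + n_node)   # branch extension accumulated at each node
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  contrasts <- stats::setNames(rep(NA_real_, n_node),
                               as.character(seq_len(n_node) + n_tip))
  # postorder over internal nodes: children before parents
  ord <- unique(tree$edge[ape::postorder(tree), 1L])
  for (node in ord) {
    kid_edges <- children[[as.character(node)]]
    kids <- tree$edge[kid_edges, 2L]
    vl <- tree$edge.length[kid_edges[1L]] + v_extra[kids[1L]]
    vr <- tree$edge.length[kid_edges[2L]] + v_extra[kids[2L]]
    vsum <- vl + vr
    if (vsum <= 0) stop_invalid("zero total branch-length variance at node ", node,
                                "; contrasts are undefined")
    contrasts[[as.character(node)]] <- (x[kids[1L]] - x[kids[2L]]) / sqrt(vsum)
    x[node] <- if (vl == 0) x[kids[1L]] else if (vr == 0) x[kids[2L]] else
      (x[kids[1L]] / vl + x[kids[2L]] / vr) / (1 / vl + 1 / vr)
    v_extra[node] <- vl * vr / vsum
  }
  contrasts
}

#' PIC-corrected correlation between two traits
#'
#' Both traits are converted to contrasts on the same tree and correlated
#' through the origin: R = sum(u w) / sqrt(sum(u^2) sum(w^2)). The
#' two-sided p-value comes from t = R sqrt((m - 1) / (1 - R^2)) on m - 1
#' degrees of freedom, m = number of contrasts.
#'
#' @param tree rooted binary `phylo` tree
#' @param trait_x,trait_y named numeric vectors over the tips
#' @return list with `r`, `p`, `n_contrasts`, and `degenerate` (TRUE when
#'   either contrast set has zero variance, leaving R undefined)
#' @export
pic_correlation <- function(tree, trait_x, trait_y) {
  u <- pic_contrasts(tree, trait_x)
  w <- pic_contrasts(tree, trait_y)
  m <- length(u)
  if (m < 3L) {
    stop(errorCondition(paste0("insufficient data: ", m, " contrasts (need >= 3)"),
                        class = c("bqpipe_insufficient_data", "error")))
  }
  su <- sum(u^2); sw <- sum(w^2)
  # degeneracy is judged relative to trait magnitude: contrasts of a
  # constant trait are ~1e-15 * |trait|, not exactly zero
  tol_u <- (1e-10)^2 * m * max(1, mean(as.numeric(trait_x)^2))
  tol_w <- (1e-10)^2 * m * max(1, mean(as.numeric(trait_y)^2))
  if (su <= tol_u || sw <= tol_w) {
    return(list(r = NA_real_, p = NA_real_, n_contrasts = m, degenerate = TRUE))
  }
  r <- sum(u * w) / sqrt(su * sw)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((m - 1) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = m - 1)
  }
  list(r = r, p = p, n_contrasts = m, degenerate = FALSE)
}

#' Category-wise PIC correlation screen against proteome size
#'
#' For each functional category, correlates the per-species gene count
#' with proteome size after PIC correction and flags categories with
#' R > `r_threshold` and p < `alpha` (raw p; no multiple-testing
#' correction by default, matching how such screens are conventionally
#' reported -- set `fdr = TRUE` for Benjamini-Hochberg adjustment).
#' Also reports `slope_reduction`: the percent drop in fitted gene count
#' from the largest to the smallest proteome along the ordinary best-fit
#' line on the raw species values (a descriptive companion to R, not a
#' PIC quantity).
#'
#' @param tree rooted binary `phylo` species tree
#' @param counts matrix species x category (e.g. from [category_counts()])
#' @param proteome_sizes named numeric vector over the species
#' @param r_threshold,alpha significance thresholds (defaults 0.5, 0.05)
#' @param fdr apply Benjamini-Hochberg correction to the p-values used for
#'   the significance flag (default FALSE)
#' @return data.frame of class `pic_screen` with one row per category:
#'   category, r, p, n_contrasts, significant, degenerate, slope_reduction
#' @export
category_screen <- function(tree, counts, proteome_sizes,
                            r_threshold = 0.5, alpha = 0.05, fdr = FALSE) {
  stopifnot(is.matrix(counts))
  sp <- rownames(counts)
  if (!setequal(sp, tree$tip.label)) stop_invalid("count matrix species must match tree tips")
  prot <- proteome_sizes[sp]
  res <- lapply(colnames(counts), function(cat) {
    y <- stats::setNames(as.numeric(counts[, cat]), sp)
    cr <- pic_correlation(tree, y, stats::setNames(as.numeric(prot), sp))
    slope_red <- NA_real_
    if (!cr$degenerate) {
      fit <- stats::lm(y ~ prot)
      rng <- range(prot)
      fit_hi <- sum(stats::coef(fit) * c(1, rng[2L]))
      fit_lo <- sum(stats::coef(fit) * c(1, rng[1L]))
      if (is.finite(fit_hi) && abs(fit_hi) > 0) {
        slope_red <- 100 * (fit_hi - fit_lo) / fit_hi
      }
    }
    data.frame(category = cat, r = cr$r, p = cr$p, n_contrasts = cr$n_contrasts,
               degenerate = cr$degenerate, slope_reduction = slope_red,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  p_flag <- if (fdr) stats::p.adjust(out$p, method = "BH") else out$p
  out$significant <- !out$degenerate & !is.na(out$r) &
    out$r > r_threshold & p_flag < alpha
  class(out) <- c("pic_screen", class(out))
  attr(out, "r_threshold") <- r_threshold
  attr(out, "alpha") <- alpha
  out
}

#' PIC correlation between root-to-tip branch length and proteome size
#'
#' Tests whether lineages with smaller proteomes evolve on longer
#' branches (as accelerated evolution after repair-gene loss would
#' predict). Root-to-tip distances come from [root_to_tip_lengths()].
#'
#' @param tree rooted binary `phylo` tree with branch lengths
#' @param proteome_sizes named numeric vector over the tips
#' @return as [pic_correlation()]
#' @export
branch_length_correlation <- function(tree, proteome_sizes) {
  rtl <- root_to_tip_lengths(tree)
  pic_correlation(tree, rtl, proteome_sizes[names(rtl)])
}
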