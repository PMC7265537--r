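# Network similarity: four distance measures over species metabolic
# networks, and the labelled distance matrices fed to neighbor joining.
#
# The unweighted measure compares compound node *sets*; the weighted
# measures compare node-*abundance* vectors laid out over the union
# compound universe of the networks being compared. All four are
# distances (1 - similarity for the Jaccard family): zero for identical
# inputs, symmetric, nonnegative.

#' Unweighted Jaccard distance between two sets
#'
#' `1 - |I intersect J| / |I union J|`. Two empty sets are identical by
#' convention (distance 0).
#'
#' @param i,j vectors interpreted as sets (duplicates ignored)
#' @return distance in \[0, 1\]
#' @export
jaccard_distance <- function(i, j) {
  i <- unique(i); j <- unique(j)
  u <- length(union(i, j))
  if (u == 0L) return(0)
  1 - length(intersect(i, j)) / u
}

#' Weighted Jaccard distance between two nonnegative vectors
#'
#' `1 - sum(min(x_i, y_i)) / sum(max(x_i, y_i))`. Reduces to the
#' unweighted Jaccard distance of the supports when `x` and `y` are 0/1
#' indicator vectors. Two all-zero vectors are identical (distance 0).
#'
#' @param x,y numeric vectors, same length, entries >= 0
#' @return distance in \[0, 1\]
#' @export
weighted_jaccard <- function(x, y) {
  check_pair(x, y)
  smax <- sum(pmax(x, y))
  if (smax == 0) return(0)
  1 - sum(pmin(x, y)) / smax
}

#' Canberra distance
#'
#' `sum_i |x_i - y_i| / (|x_i| + |y_i|)`, with jointly-zero terms
#' contributing 0 (the standard convention that keeps d(x, x) = 0).
#'
#' @param x,y numeric vectors, same length, entries >= 0
#' @return distance >= 0 (at most the number of positions)
#' @export
canberra <- function(x, y) {
  check_pair(x, y)
  denom <- abs(x) + abs(y)
  active <- denom > 0
  sum(abs(x[active] - y[active]) / denom[active])
}

#' Adkins form of the Canberra distance
#'
#' The Canberra distance divided by `NZ`, the number of active positions
#' -- positions where `x` or `y` is nonzero (jointly-zero positions are
#' excluded, so AdCan is the mean of the active Canberra terms and lies in
#' \[0, 1\]). The stricter reading of `NZ` -- positions nonzero in *both*
#' vectors -- is available via `nz = "both"`; it can exceed 1 and is
#' undefined on disjoint supports.
#'
#' @param x,y numeric vectors, same length, entries >= 0
#' @param nz `"either"` (default) or `"both"`: which positions count in NZ
#' @return distance in \[0, 1\] for `nz = "either"`; 0 with a warning when
#'   NZ = 0
#' @export
adkins_canberra <- function(x, y, nz = c("either", "both")) {
  nz <- match.arg(nz)
  check_pair(x, y)
  n_active <- if (nz == "either") sum(x != 0 | y != 0) else sum(x != 0 & y != 0)
  if (n_active == 0L) {
    warning("NZ = 0 (no active positions); Adkins-Canberra defined as 0")
    return(0)
  }
  canberra(x, y) / n_active
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("vectors differ in length: ",
                                           length(x), " vs ", length(y))
  if (any(x < 0) || any(y < 0)) stop_invalid("negative entries are not allowed")
  invisible(TRUE)
}

#' Pairwise distance matrix over species metabolic networks
#'
#' The unweighted `jaccard` measure compares compound node sets; the
#' weighted measures (`wjaccard`, `canberra`, `adcan`) compare
#' node-abundance vectors over the union compound universe of all
#' networks.
#'
#' @param networks list of [build_network()] results with distinct species
#'   labels; at least 3 (a neighbor-joining tree needs >= 3 leaves)
#' @param measure one of `"jaccard"`, `"wjaccard"`, `"canberra"`, `"adcan"`
#' @return symmetric numeric matrix with zero diagonal, dimnames = species
#' @export
distance_matrix <- function(networks,
                            measure = c("jaccard", "wjaccard", "canberra", "adcan")) {
  measure <- match.arg(measure)
  if (length(networks) < 3L) stop_invalid("need at least 3 networks, got ", length(networks))
  labels <- vapply(networks, function(n) n$species, character(1))
  if (anyDuplicated(labels)) stop_invalid("duplicate species labels in networks")
  universe <- sort(unique(unlist(lapply(networks, function(n) n$nodes), use.names = FALSE)))
  vecs <- lapply(networks, node_abundance_vector, cpd_universe = universe)
  n <- length(networks)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      d <- switch(measure,
        jaccard  = jaccard_distance(networks[[a]]$nodes, networks[[b]]$nodes),
        wjaccard = weighted_jaccard(vecs[[a]], vecs[[b]]),
        canberra = canberra(vecs[[a]], vecs[[b]]),
        adcan    = adkins_canberra(vecs[[a]], vecs[[b]]))
      m[a, b] <- m[b, a] <- d
    }
  }
  m
}

#' Write a distance matrix in PHYLIP lower-triangular format
#'
#' First line is the species count; each following line is the species
#' label (padded to 10 characters in strict mode, which also enforces
#' unique labels once truncated to 10) and the distances to the preceding
#' species.
#'
#' @param m symmetric numeric matrix with species dimnames
#' @param path output path
#' @param relaxed if `TRUE`, labels longer than 10 characters are written
#'   in full (tab-separated); default is strict PHYLIP
#' @export
write_phylip_lower <- function(m, path, relaxed = FALSE) {
  labels <- rownames(m)
  if (is.null(labels)) stop_invalid("matrix must carry species dimnames")
  if (!relaxed) {
    short <- substr(gsub("[^A-Za-z0-9_.-]", "_", labels), 1L, 10L)
    if (anyDuplicated(short)) {
      stop_invalid("sanitized 10-character labels collide: ",
                   paste(short[duplicated(short)], collapse = ", "))
    }
    padded <- formatC(short, width = 10, flag = "-")
  } else {
    padded <- labels
  }
  lines <- character(nrow(m) + 1L)
  lines[1L] <- as.character(nrow(m))
  for (i in seq_len(nrow(m))) {
    vals <- if (i > 1L) paste(sprintf("%.10g", m[i, seq_len(i - 1L)]),
                              collapse = " ") else ""
    lines[i + 1L] <- trimws(paste(padded[i], vals), which = "right")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP lower-triangular distance matrix
#' @param path file written by [write_phylip_lower()]
#' @return symmetric numeric matrix with zero diagonal
#' @export
read_phylip_lower <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) != n + 1L) {
    stop_parse("expected ", n, " species rows in ", path)
  }
  labels <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]]
    labels[i] <- fields[1L]
    if (i > 1L) {
      vals <- as.numeric(fields[-1L])
      if (length(vals) != i - 1L) stop_parse("row ", i, " has ", length(vals),
                                             " values, expected ", i - 1L)
      m[i, seq_len(i - 1L)] <- vals
      m[seq_len(i - 1L), i] <- vals
    }
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' Write a distance matrix as a full TSV table
#' @param m matrix with dimnames
#' @param path output path
#' @export
write_distance_tsv <- function(m, path) {
  df <- data.frame(species = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
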