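# Compound-level metabolic networks.
#
# Each annotated gene carries a K number; each K maps to one or more KEGG
# reactions (rn), and each reaction involves a set of compounds (cpd). A
# genome's metabolic network is the undirected graph on compounds in which
# every gene contributes, for each reaction of its K, one unit of weight to
# every unordered pair of that reaction's compounds (clique expansion --
# reaction directionality is not modelled). Edge weight therefore reflects
# the abundance of enzymes (gene copies) catalysing reactions between two
# compounds; paralogs count multiply. Reactions with a single compound
# contribute an isolated node.

#' Construct a KO -> reaction -> compound map
#'
#' @param ko_to_rn data.frame with columns `k`, `rn`
#' @param rn_to_cpd data.frame with columns `rn`, `cpd`
#' @return object of class `ko_map`: list of two named lists,
#'   `ko_to_rn` (K -> character vector of reaction ids) and
#'   `rn_to_cpds` (rn -> character vector of compound ids)
#' @export
ko_map <- function(ko_to_rn, rn_to_cpd) {
  stopifnot(all(c("k", "rn") %in% names(ko_to_rn)),
            all(c("rn", "cpd") %in% names(rn_to_cpd)))
  k2r <- lapply(split(as.character(ko_to_rn$rn), as.character(ko_to_rn$k)), unique)
  r2c <- lapply(split(as.character(rn_to_cpd$cpd), as.character(rn_to_cpd$rn)), unique)
  missing_rn <- setdiff(unlist(k2r, use.names = FALSE), names(r2c))
  if (length(missing_rn)) {
    stop_invalid("reactions referenced by ko_to_rn but absent from rn_to_cpd: ",
                 paste(utils::head(missing_rn, 5), collapse = ", "))
  }
  if (any(lengths(r2c) < 1L)) stop_invalid("every reaction needs at least one compound")
  structure(list(ko_to_rn = k2r, rn_to_cpds = r2c), class = "ko_map")
}

#' Read a KO map from its two TSV files
#' @param ko2rn_path TSV with header `k<TAB>rn`
#' @param rn2cpd_path TSV with header `rn<TAB>cpd`
#' @return a [ko_map()]
#' @export
read_ko_map <- function(ko2rn_path, rn2cpd_path) {
  k2r <- utils::read.delim(ko2rn_path, stringsAsFactors = FALSE)
  r2c <- utils::read.delim(rn2cpd_path, stringsAsFactors = FALSE)
  ko_map(k2r, r2c)
}

#' Write a KO map as two TSV files
#' @param map a [ko_map()]
#' @param ko2rn_path,rn2cpd_path output paths
#' @export
write_ko_map <- function(map, ko2rn_path, rn2cpd_path) {
  k2r <- data.frame(k = rep(names(map$ko_to_rn), lengths(map$ko_to_rn)),
                    rn = unlist(map$ko_to_rn, use.names = FALSE))
  r2c <- data.frame(rn = rep(names(map$rn_to_cpds), lengths(map$rn_to_cpds)),
                    cpd = unlist(map$rn_to_cpds, use.names = FALSE))
  utils::write.table(k2r, ko2rn_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(r2c, rn2cpd_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(ko2rn_path, rn2cpd_path))
}

#' Build a species' metabolic network from its K-number list
#'
#' @param k_numbers character vector of K numbers, one entry per annotated
#'   gene (repeats = paralogs; multiplicity matters).
#' @param map a [ko_map()]
#' @param species species label attached to the network
#' @param exclude_cpds optional character vector of compounds to drop
#'   before clique expansion (e.g. ubiquitous currency metabolites). Off by
#'   default: no compound is filtered.
#' @return object of class `metabolic_network`: list with `species`,
#'   `nodes` (sorted cpd ids), `edges` (data.frame from, to, weight with
#'   from < to, sorted), `node_abundance` (named numeric: summed incident
#'   weight; isolated nodes 0) and `unmapped_k` (named count table of K
#'   numbers absent from the map -- reported, not fatal).
#' @export
build_network <- function(k_numbers, map, species = "species", exclude_cpds = NULL) {
  stopifnot(inherits(map, "ko_map"))
  k_numbers <- as.character(k_numbers)
  known <- k_numbers %in% names(map$ko_to_rn)
  unmapped <- table(k_numbers[!known])
  from <- character(0); to <- character(0)
  isolated <- character(0)
  for (k in k_numbers[known]) {
    for (rn in map$ko_to_rn[[k]]) {
      cpds <- setdiff(map$rn_to_cpds[[rn]], exclude_cpds)
      if (length(cpds) == 1L) {
        isolated <- c(isolated, cpds)
      } else if (length(cpds) >= 2L) {
        prs <- utils::combn(sort(cpds), 2L)
        from <- c(from, prs[1L, ]); to <- c(to, prs[2L, ])
      }
    }
  }
  if (length(from)) {
    agg <- stats::aggregate(list(weight = rep(1L, length(from))),
                            by = list(from = from, to = to), FUN = sum)
    agg <- agg[order(agg$from, agg$to), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(from = character(0), to = character(0), weight = integer(0))
  }
  nodes <- sort(unique(c(agg$from, agg$to, isolated)))
  ab <- stats::setNames(numeric(length(nodes)), nodes)
  if (nrow(agg)) {
    for (col in c("from", "to")) {
      w <- tapply(agg$weight, agg[[col]], sum)
      ab[names(w)] <- ab[names(w)] + w
    }
  }
  structure(list(species = species, nodes = nodes, edges = agg,
                 node_abundance = ab, unmapped_k = unmapped),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %s: %d cpd nodes, %d edges (total weight %d)\n",
              x$species, length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Node-abundance vector over a fixed compound universe
#'
#' @param network a [build_network()] result
#' @param cpd_universe character vector of compound ids; must contain every
#'   node of the network. Entries outside the network are zero.
#' @return numeric vector named by `cpd_universe`
#' @export
node_abundance_vector <- function(network, cpd_universe) {
  stopifnot(inherits(network, "metabolic_network"))
  missing <- setdiff(network$nodes, cpd_universe)
  if (length(missing)) {
    stop_invalid("cpd universe is missing network nodes: ",
                 paste(utils::head(missing, 5), collapse = ", "))
  }
  v <- stats::setNames(numeric(length(cpd_universe)), cpd_universe)
  v[names(network$node_abundance)] <- network$node_abundance
  v
}

#' Export a network edge list as TSV
#'
#' Columns `source`, `target`, `weight`, sorted by (source, target) --
#' the layout graph tools import directly.
#' @param network a [build_network()] result
#' @param path output path
#' @export
export_edge_list <- function(network, path) {
  df <- network$edges
  names(df) <- c("source", "target", "weight")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge list written by [export_edge_list()]
#' @param path TSV path
#' @param species label for the reconstructed network
#' @return a `metabolic_network` (isolated nodes are not recoverable from
#'   an edge list and are absent)
#' @export
read_edge_list <- function(path, species = "species") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  nodes <- sort(unique(c(df$source, df$target)))
  ab <- stats::setNames(numeric(length(nodes)), nodes)
  for (col in c("source", "target")) {
    w <- tapply(df$weight, df[[col]], sum)
    ab[names(w)] <- ab[names(w)] + w
  }
  edges <- data.frame(from = df$source, to = df$target, weight = df$weight)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(species = species, nodes = nodes, edges = edges,
                 node_abundance = ab, unmapped_k = table(character(0))),
            class = "metabolic_network")
}
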