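# Two-step KEGG Orthology (KO) annotation.
#
# Step one (per-genome): each species arrives with a partial gene -> K-number
# map, typically the product of a similarity search against annotated
# databases. Step two (multi-species): because an orthogroup consists of
# homologous genes of related function, a K number assigned to any member
# can be extended to the members that failed direct annotation. The modal
# (most common) K among the directly annotated members becomes the
# orthogroup consensus and fills the gaps; direct assignments are never
# overwritten, so the propagated map always contains the direct map.

KO_PATTERN <- "^K[0-9]{5}$"

#' Load per-species gene-to-KO tables
#'
#' Each file is a two-column TSV `gene_id<TAB>K number` (K followed by five
#' digits, e.g. `K00001`). Malformed K numbers are rejected with their line
#' number; duplicated rows are deduplicated silently, but a gene id mapped
#' to two different K numbers is an annotation conflict.
#'
#' @param paths character vector of TSV paths (one per species; may be named)
#' @return named character vector gene id -> K number (the "direct" map)
#' @export
load_gene_ko_tsv <- function(paths) {
  direct <- character(0)
  for (path in paths) {
    if (!file.exists(path)) stop_invalid("file does not exist: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines)) {
      fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
      if (length(fields) != 2L) {
        stop_parse("expected 2 tab-separated fields at line ", i, " of ", path)
      }
      gene <- trimws(fields[1L]); k <- trimws(fields[2L])
      if (!grepl(KO_PATTERN, k)) {
        stop_parse("malformed K number '", k, "' at line ", i, " of ", path)
      }
      if (gene %in% names(direct)) {
        if (!identical(unname(direct[[gene]]), k)) {
          stop(errorCondition(
            paste0("annotation conflict for gene '", gene, "': ",
                   direct[[gene]], " vs ", k, " (line ", i, " of ", path, ")"),
            class = c("bqpipe_annotation_conflict", "error")))
        }
        next
      }
      direct[[gene]] <- k
    }
  }
  direct
}

#' Propagate KO annotations by orthogroup consensus
#'
#' For every orthogroup with at least one directly annotated gene, the
#' consensus K is the modal K number among its directly annotated members
#' (gene-level counting, so paralog multiplicity counts); ties are broken
#' by the lexicographically smallest K number. Previously unannotated
#' members receive the consensus with provenance `propagated`; direct
#' assignments are kept untouched. Orthogroups with no directly annotated
#' member get no consensus. Unassigned (singleton) genes keep only their
#' direct annotations. The operation is idempotent.
#'
#' @param table an [orthogroup_table()]
#' @param direct named character vector gene -> K (from [load_gene_ko_tsv()])
#' @return an object of class `annotation_map`: list with `direct`,
#'   `og_consensus` (orthogroup -> K, only OGs with a consensus) and
#'   `effective` (data.frame gene, k, provenance in {"direct","propagated"})
#' @export
propagate_ko <- function(table, direct) {
  stopifnot(inherits(table, "orthogroup_table"))
  direct <- unlist(direct) %||% character(0)
  consensus <- character(0)
  eff_gene <- character(0); eff_k <- character(0); eff_prov <- character(0)
  for (og in names(table$genes)) {
    members <- unlist(table$genes[[og]], use.names = FALSE)
    ks <- direct[members[members %in% names(direct)]]
    if (length(ks) > 0L) {
      tab <- table(ks)
      modal <- sort(names(tab)[tab == max(tab)])[1L]  # lexicographic tie-break
      consensus[[og]] <- modal
      missing <- members[!(members %in% names(direct))]
      eff_gene <- c(eff_gene, missing)
      eff_k <- c(eff_k, rep(modal, length(missing)))
      eff_prov <- c(eff_prov, rep("propagated", length(missing)))
    }
  }
  eff <- data.frame(
    gene = c(names(direct), eff_gene),
    k = c(unname(direct), eff_k),
    provenance = c(rep("direct", length(direct)), eff_prov),
    stringsAsFactors = FALSE
  )
  structure(list(direct = direct, og_consensus = consensus, effective = eff),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d direct, %d effective (%d OG consensuses)\n",
              length(x$direct), nrow(x$effective), length(x$og_consensus)))
  invisible(x)
}

#' Annotation (ID-mapping) efficiency report
#'
#' Percentage of all genes -- orthogroup members plus unassigned singletons
#' -- carrying a K number, before (direct only, "M1") and after orthogroup
#' consensus propagation ("M2").
#'
#' @param annotation an `annotation_map` from [propagate_ko()]
#' @param table the [orthogroup_table()] the maps were built from
#' @return list of class `efficiency_report` with counts and percentages
#' @export
annotation_efficiency <- function(annotation, table) {
  stopifnot(inherits(annotation, "annotation_map"), inherits(table, "orthogroup_table"))
  n_genes <- sum(vapply(table$genes, function(row) sum(lengths(row)), integer(1))) +
    length(unlist(table$unassigned, use.names = FALSE))
  n_direct <- length(annotation$direct)
  n_effective <- nrow(annotation$effective)
  structure(list(
    n_genes = n_genes,
    n_direct = n_direct,
    n_effective = n_effective,
    efficiency_direct = if (n_genes > 0L) 100 * n_direct / n_genes else 0,
    efficiency_effective = if (n_genes > 0L) 100 * n_effective / n_genes else 0
  ), class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("<efficiency_report> direct %.1f%% (%d/%d) -> effective %.1f%% (%d/%d)\n",
              x$efficiency_direct, x$n_direct, x$n_genes,
              x$efficiency_effective, x$n_effective, x$n_genes))
  invisible(x)
}

#' Per-species, per-category gene counts
#'
#' Maps effective annotations against a KO -> pathway-category table and
#' counts annotated genes per species per category. A K number belonging
#' to several pathways contributes once to each; K numbers absent from the
#' map are tallied under `"unmapped"`.
#'
#' @param annotation an `annotation_map`
#' @param table the [orthogroup_table()] (supplies gene -> species)
#' @param ko_to_pathway data.frame with columns `k`, `pathway`
#' @return integer matrix species x category
#' @export
category_counts <- function(annotation, table, ko_to_pathway) {
  stopifnot(inherits(annotation, "annotation_map"), inherits(table, "orthogroup_table"))
  stopifnot(all(c("k", "pathway") %in% names(ko_to_pathway)))
  gene_species <- character(0)
  for (og in names(table$genes)) {
    for (s in table$species) {
      g <- table$genes[[og]][[s]]
      if (length(g)) gene_species[g] <- s
    }
  }
  for (s in table$species) {
    g <- table$unassigned[[s]]
    if (length(g)) gene_species[g] <- s
  }
  path_by_k <- split(as.character(ko_to_pathway$pathway), as.character(ko_to_pathway$k))
  categories <- sort(unique(as.character(ko_to_pathway$pathway)))
  m <- matrix(0L, nrow = length(table$species), ncol = length(categories) + 1L,
              dimnames = list(table$species, c(categories, "unmapped")))
  eff <- annotation$effective
  if (nrow(eff) > 0L) {
    sp <- unname(gene_species[eff$gene])
    mapped <- eff$k %in% names(path_by_k)
    if (any(!mapped)) {
      tab <- table(factor(sp[!mapped], levels = table$species))
      m[, "unmapped"] <- as.integer(tab)
    }
    if (any(mapped)) {
      plists <- lapply(path_by_k[eff$k[mapped]], unique)
      sp_exp <- rep(sp[mapped], lengths(plists))
      cat_exp <- unlist(plists, use.names = FALSE)
      tab <- table(factor(sp_exp, levels = table$species),
                   factor(cat_exp, levels = categories))
      m[, categories] <- m[, categories] + matrix(as.integer(tab), nrow = nrow(m))
    }
  }
  m
}
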