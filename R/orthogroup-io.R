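# Orthogroup table I/O and pangenome statistics.
#
# The orthogroup (OG) is the unit of comparison: a set of genes descended
# from a single ancestral gene across the species compared (orthologs and
# paralogs). Tables follow the OrthoFinder conventions: `Orthogroups.tsv`
# has one row per OG, one tab-separated column per species holding a
# ", "-separated gene-id list; `Orthogroups.GeneCount.csv` holds the
# per-species gene counts. Singleton genes (not placed in any OG) are kept
# in a per-species `unassigned` slot, mirroring OrthoFinder's separate
# unassigned-genes output.

#' Construct an orthogroup table
#'
#' @param species character vector of species labels (column order is
#'   preserved through I/O).
#' @param genes named list: orthogroup id -> named list (species -> character
#'   vector of gene ids, possibly empty).
#' @param unassigned named list: species -> character vector of gene ids not
#'   placed in any orthogroup (singletons). Defaults to none.
#' @return an object of class `orthogroup_table`
#' @export
orthogroup_table <- function(species, genes, unassigned = NULL) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop_invalid("duplicate species labels")
  if (is.null(unassigned)) {
    unassigned <- stats::setNames(rep(list(character(0)), length(species)), species)
  }
  for (s in species) unassigned[[s]] <- as.character(unassigned[[s]] %||% character(0))
  unassigned <- unassigned[species]
  genes <- lapply(genes, function(row) {
    row <- lapply(stats::setNames(species, species), function(s) as.character(row[[s]] %||% character(0)))
    row
  })
  all_genes <- c(unlist(genes, use.names = FALSE), unlist(unassigned, use.names = FALSE))
  if (anyDuplicated(all_genes)) {
    dup <- all_genes[duplicated(all_genes)][1L]
    stop_invalid("gene id not globally unique: ", dup)
  }
  structure(list(species = species, genes = genes, unassigned = unassigned),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat(sprintf("<orthogroup_table> %d orthogroups x %d species (%d unassigned genes)\n",
              length(x$genes), length(x$species),
              length(unlist(x$unassigned, use.names = FALSE))))
  invisible(x)
}

n_orthogroups <- function(table) length(table$genes)

#' Read an OrthoFinder-style Orthogroups.tsv
#'
#' First row is the header `Orthogroup<TAB>sp1<TAB>...`; each subsequent row
#' is an orthogroup id followed by one cell per species containing a
#' comma-separated gene-id list (empty cell = no genes). Whitespace around
#' gene ids is trimmed. Ragged rows and duplicate orthogroup ids are parse
#' errors naming the offending line.
#'
#' @param path path to the TSV file
#' @param unassigned optional named list (species -> gene ids) of singleton
#'   genes to attach, e.g. read from a companion file.
#' @return an [orthogroup_table()]
#' @export
read_orthogroups_tsv <- function(path, unassigned = NULL) {
  if (!file.exists(path)) stop_invalid("file does not exist: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop_parse("empty file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  species <- header[-1L]
  ncol_expect <- length(header)
  rows <- list()
  for (i in seq_along(cells)[-1L]) {
    row <- cells[[i]]
    if (length(row) == 0L || (length(row) == 1L && row == "")) next
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(row) < ncol_expect) row <- c(row, rep("", ncol_expect - length(row)))
    if (length(row) != ncol_expect) {
      stop_parse("ragged row at line ", i, " of ", path,
                 ": expected ", ncol_expect, " fields, found ", length(row))
    }
    og <- row[1L]
    if (og %in% names(rows)) stop_parse("duplicate orthogroup id '", og, "' at line ", i)
    gene_lists <- lapply(row[-1L], function(cell) {
      if (!nzchar(trimws(cell))) return(character(0))
      trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
    })
    rows[[og]] <- stats::setNames(gene_lists, species)
  }
  orthogroup_table(species, rows, unassigned = unassigned)
}

#' Write an orthogroup table as Orthogroups.tsv
#'
#' @param table an [orthogroup_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_orthogroups_tsv <- function(table, path) {
  header <- paste(c("Orthogroup", table$species), collapse = "\t")
  body <- vapply(names(table$genes), function(og) {
    cells <- vapply(table$species,
                    function(s) paste(table$genes[[og]][[s]], collapse = ", "),
                    character(1))
    paste(c(og, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Per-orthogroup, per-species gene counts
#'
#' @param table an [orthogroup_table()]
#' @return integer matrix, rows = orthogroup ids, columns = species
#' @export
gene_counts <- function(table) {
  stopifnot(inherits(table, "orthogroup_table"))
  m <- matrix(0L, nrow = length(table$genes), ncol = length(table$species),
              dimnames = list(names(table$genes), table$species))
  for (og in names(table$genes)) {
    m[og, ] <- vapply(table$genes[[og]], length, integer(1))[table$species]
  }
  m
}

#' Write gene counts as Orthogroups.GeneCount.csv
#'
#' Comma-separated, same row/column order as the orthogroup table, with a
#' final `Total` column (ignored on read).
#' @param counts matrix from [gene_counts()]
#' @param path output path
#' @export
write_gene_counts_csv <- function(counts, path) {
  df <- as.data.frame(counts)
  df <- cbind(Orthogroup = rownames(counts), df, Total = rowSums(counts))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an Orthogroups.GeneCount.csv
#' @param path path to CSV; a trailing `Total` column is dropped if present
#' @return integer matrix rows = orthogroups, columns = species
#' @export
read_gene_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1L]]
  df <- df[-1L]
  if (identical(tail(names(df), 1L), "Total")) df <- df[-length(df)]
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  rownames(m) <- rn
  m
}

#' Pangenome partition: core / shared / unique orthogroups
#'
#' Core orthogroups occur (count >= 1) in every species; shared occur in
#' more than one but not all; unique occur in exactly one species. The
#' three classes partition the orthogroups present in at least one species.
#'
#' @param table an [orthogroup_table()]
#' @return a list of class `pangenome_summary` with counts `n_core`,
#'   `n_shared`, `n_unique`, the per-class orthogroup id vectors, and a
#'   per-species breakdown matrix (species x class counts of OGs the
#'   species participates in).
#' @export
pangenome_partition <- function(table) {
  stopifnot(inherits(table, "orthogroup_table"))
  if (length(table$species) < 1L) stop_invalid("need at least one species")
  counts <- gene_counts(table)
  present <- counts > 0L
  n_sp_per_og <- rowSums(present)
  core <- rownames(counts)[n_sp_per_og == length(table$species)]
  unique_ <- rownames(counts)[n_sp_per_og == 1L]
  shared <- rownames(counts)[n_sp_per_og > 1L & n_sp_per_og < length(table$species)]
  per_species <- sapply(c(core = list(core), shared = list(shared), unique = list(unique_)),
                        function(ids) colSums(present[ids, , drop = FALSE]))
  structure(list(
    n_core = length(core), n_shared = length(shared), n_unique = length(unique_),
    core = core, shared = shared, unique = unique_,
    per_species = per_species
  ), class = "pangenome_summary")
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat(sprintf("<pangenome_summary> core %d | shared %d | unique %d\n",
              x$n_core, x$n_shared, x$n_unique))
  invisible(x)
}

#' Orthogroup summary statistics
#'
#' Reports the totals conventionally quoted for an orthogroup analysis:
#' how many genes were assigned to orthogroups, the mean orthogroup size,
#' the size histogram, and the count/fraction of two-gene orthogroups.
#' Percentages are reported unrounded plus rounded companions (one decimal
#' for the assignment percentage, nearest integer for the two-gene
#' percentage and the mean), rounding half up to match how such numbers
#' are printed.
#'
#' @param table an [orthogroup_table()]
#' @return a list of class `og_stats`
#' @export
orthogroup_stats <- function(table) {
  stopifnot(inherits(table, "orthogroup_table"))
  sizes <- vapply(table$genes, function(row) sum(lengths(row)), integer(1))
  assigned <- sum(sizes)
  unassigned <- length(unlist(table$unassigned, use.names = FALSE))
  total <- assigned + unassigned
  n_ogs <- length(sizes)
  n_two <- sum(sizes == 2L)
  mean_sz <- if (n_ogs > 0L) assigned / n_ogs else NA_real_
  pct_assigned <- if (total > 0L) 100 * assigned / total else NA_real_
  structure(list(
    n_ogs = n_ogs,
    total_genes = total,
    assigned_genes = assigned,
    unassigned_genes = unassigned,
    pct_assigned = pct_assigned,
    pct_assigned_rounded = round_half_up(pct_assigned, 1),
    pct_unassigned = if (total > 0L) 100 - pct_assigned else NA_real_,
    mean_og_size = mean_sz,
    mean_og_size_rounded = round_half_up(mean_sz, 0),
    mean_undefined = n_ogs == 0L,
    og_size_histogram = if (n_ogs > 0L) table(factor(sizes, levels = seq_len(max(sizes)))) else table(integer(0)),
    n_two_gene_ogs = n_two,
    pct_two_gene_ogs = if (n_ogs > 0L) 100 * n_two / n_ogs else NA_real_,
    pct_two_gene_ogs_rounded = round_half_up(if (n_ogs > 0L) 100 * n_two / n_ogs else NA_real_, 0)
  ), class = "og_stats")
}

#' @export
print.og_stats <- function(x, ...) {
  cat(sprintf("<og_stats> %d OGs; %d/%d genes assigned (%.1f%%); mean size %.1f; %d two-gene OGs (%.0f%%)\n",
              x$n_ogs, x$assigned_genes, x$total_genes, x$pct_assigned,
              x$mean_og_size, x$n_two_gene_ogs, x$pct_two_gene_ogs))
  invisible(x)
}
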