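#' ASV/taxon count table with taxonomy
#'
#' The central container of the package: a taxa-by-samples matrix of
#' nonnegative integer counts plus one taxonomy record (genus and phylum,
#' possibly `"unclassified"`) per taxon. Construction validates the
#' invariants; all downstream functions assume a validated table.
#'
#' @param counts integer matrix, taxa in rows, samples in columns; must have
#'   unique row and column names.
#' @param taxonomy data frame with columns `taxon`, `genus`, `phylum` (and
#'   optionally `lineage`); one row per taxon. If `NULL`, all taxa are
#'   labelled `"unclassified"` with a warning.
#' @return an object of class `count_table`: a list with elements `counts`
#'   and `taxonomy`.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  stop_if_not(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must have taxon row names and sample column names")
  stop_if_not(!anyDuplicated(rownames(counts)), "duplicate taxon ids")
  stop_if_not(!anyDuplicated(colnames(counts)), "duplicate sample ids")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("counts must be nonnegative integers; offending cell: taxon '%s', sample '%s' (value %s)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(taxonomy)) {
    warning("no taxonomy supplied; labelling all taxa 'unclassified'")
    taxonomy <- data.frame(taxon = rownames(counts),
                           genus = "unclassified", phylum = "unclassified",
                           stringsAsFactors = FALSE)
  }
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  stop_if_not(all(c("taxon", "genus", "phylum") %in% names(taxonomy)),
              "taxonomy needs columns taxon, genus, phylum")
  miss <- setdiff(rownames(counts), taxonomy$taxon)
  if (length(miss) > 0) {
    warning(sprintf("%d taxa missing from taxonomy; labelled 'unclassified'",
                    length(miss)))
    taxonomy <- rbind(taxonomy[, c("taxon", "genus", "phylum")],
                      data.frame(taxon = miss, genus = "unclassified",
                                 phylum = "unclassified"))
  }
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$taxon), , drop = FALSE]
  rownames(taxonomy) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, %d genera, %d phyla\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$taxonomy$genus)),
              length(unique(x$taxonomy$phylum))))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Sample ids of a count table
#' @param x a `count_table`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Taxon ids of a count table
#' @param x a `count_table`.
#' @return character vector of taxon ids.
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' Subset a count table by samples and/or taxa
#'
#' @param x a `count_table`.
#' @param samples sample ids or indices (optional).
#' @param taxa taxon ids or indices (optional).
#' @return a `count_table` restricted to the requested rows/columns.
#' @export
subset_counts <- function(x, samples = NULL, taxa = NULL) {
  m <- x$counts
  if (!is.null(taxa)) m <- m[taxa, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  count_table(m, x$taxonomy[x$taxonomy$taxon %in% rownames(m), , drop = FALSE])
}

#' Aggregate counts to a taxonomic rank
#'
#' Sums counts over taxa sharing the same genus or phylum label. Taxa whose
#' label at the requested rank is `"unclassified"` are kept as distinct
#' groups, one per parent lineage (for genus the parent is the phylum), so
#' unclassified reads are never silently pooled across unrelated clades.
#' Per-sample totals are conserved exactly.
#'
#' @param x a `count_table`.
#' @param rank `"genus"` or `"phylum"`.
#' @return a `count_table` whose taxa are rank-level groups.
#' @export
aggregate_to_rank <- function(x, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  lab <- x$taxonomy[[rank]]
  stop_if_not(any(lab != "unclassified"),
              "rank '%s' absent from all lineages", rank)
  uncl <- lab == "unclassified"
  if (rank == "genus") {
    lab[uncl] <- paste0("unclassified_", x$taxonomy$phylum[uncl])
  } else {
    lab[uncl] <- "unclassified"
  }
  agg <- rowsum(x$counts, group = lab, reorder = TRUE)
  storage.mode(agg) <- "integer"
  if (rank == "genus") {
    phy <- tapply(x$taxonomy$phylum, lab, function(p) p[1])
    tax <- data.frame(taxon = rownames(agg), genus = rownames(agg),
                      phylum = as.character(phy[rownames(agg)]))
  } else {
    tax <- data.frame(taxon = rownames(agg), genus = "unclassified",
                      phylum = rownames(agg))
  }
  count_table(agg, tax)
}
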