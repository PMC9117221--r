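#' Read a count table from TSV or BIOM
#'
#' The TSV dialect is tab-separated UTF-8 with `#` comment lines ignored,
#' the first column holding taxon ids, one column per sample, and an
#' optional final `lineage` column with a QIIME-style string
#' (`k__...;p__Phylum;...;g__Genus`). Taxonomy can alternatively come from a
#' sidecar TSV with columns `taxon` and `lineage` (or `genus`/`phylum`).
#' BIOM support covers the JSON dialect via the biomformat package.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom"`.
#' @param taxonomy optional path to a sidecar taxonomy TSV.
#' @return a validated [count_table].
#' @export
read_counts <- function(path, format = c("tsv", "biom"), taxonomy = NULL) {
  format <- match.arg(format)
  stop_if_not(file.exists(path), "file not found: %s", path)
  if (format == "biom") {
    stop_if_not(requireNamespace("biomformat", quietly = TRUE),
                "biomformat package required for BIOM input")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
    tax <- NULL
    if (!is.null(om) && length(om) > 0) {
      lin <- vapply(seq_len(nrow(m)), function(i) {
        r <- if (is.data.frame(om)) unlist(om[i, ]) else unlist(om[[i]])
        paste(r, collapse = ";")
      }, character(1))
      tax <- parse_lineages(rownames(m), lin)
    }
    return(count_table(m, tax))
  }
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  lin_col <- which(tolower(names(df)) == "lineage")
  tax <- NULL
  if (length(lin_col) == 1) {
    tax <- parse_lineages(ids, as.character(df[[lin_col]]))
    df <- df[, -c(1, lin_col), drop = FALSE]
  } else {
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  if (!is.null(taxonomy)) {
    td <- read.delim(taxonomy, comment.char = "#", stringsAsFactors = FALSE)
    if ("lineage" %in% names(td)) {
      tax <- parse_lineages(td$taxon, td$lineage)
    } else {
      tax <- td[, intersect(c("taxon", "genus", "phylum"), names(td))]
    }
  }
  count_table(m, tax)
}

#' Write a count table as TSV
#'
#' Taxa in rows, samples in columns, first column `taxon`, last column
#' `lineage`. [read_counts()] parses the result losslessly.
#'
#' @param x a [count_table].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(taxon = taxon_ids(x), x$counts, check.names = FALSE)
  df$lineage <- make_lineages(x$taxonomy)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count table in BIOM (JSON dialect)
#'
#' @param x a [count_table].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_biom <- function(x, path) {
  stop_if_not(requireNamespace("biomformat", quietly = TRUE),
              "biomformat package required for BIOM output")
  b <- biomformat::make_biom(x$counts)
  biomformat::write_biom(b, path)
  invisible(path)
}

parse_lineages <- function(ids, lineage) {
  pick <- function(lin, prefix) {
    parts <- strsplit(lin, ";", fixed = TRUE)
    vapply(parts, function(p) {
      p <- trimws(p)
      hit <- grep(paste0("^", prefix, "__"), p, value = TRUE)
      val <- if (length(hit) > 0) sub(paste0("^", prefix, "__"), "", hit[1]) else ""
      if (nzchar(val)) val else "unclassified"
    }, character(1))
  }
  bad <- is.na(lineage) | !nzchar(trimws(lineage))
  if (any(bad)) {
    warning(sprintf("%d taxa have missing lineage; labelled 'unclassified'", sum(bad)))
    lineage[bad] <- ""
  }
  data.frame(taxon = ids, genus = pick(lineage, "g"), phylum = pick(lineage, "p"),
             lineage = lineage, stringsAsFactors = FALSE)
}

make_lineages <- function(taxonomy) {
  if ("lineage" %in% names(taxonomy) && all(nzchar(taxonomy$lineage))) {
    return(taxonomy$lineage)
  }
  paste0("p__", taxonomy$phylum, ";g__", taxonomy$genus)
}

#' Read per-sample metadata from TSV
#'
#' One header row; first column `sample_id`. Binary flag columns use the
#' states `yes`/`no`/`missing` (the latter, empty strings and `NA` are read
#' as missing). Ages outside [0, 120] are an error.
#'
#' @param path metadata TSV.
#' @param flags character vector naming the binary flag columns; by default
#'   every column whose non-missing values are all `yes`/`no`.
#' @return a data frame with one row per sample; flag columns are factors
#'   with levels `no`, `yes`.
#' @export
read_metadata <- function(path, flags = NULL) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", "", "missing"))
  names(df)[1] <- "sample_id"
  stop_if_not(!anyDuplicated(df$sample_id), "duplicate sample ids in metadata")
  if (is.null(flags)) {
    flags <- names(df)[vapply(df, function(col) {
      v <- col[!is.na(col)]
      length(v) > 0 && all(v %in% c("yes", "no"))
    }, logical(1))]
  }
  for (f in flags) {
    v <- df[[f]]
    stop_if_not(all(is.na(v) | v %in% c("yes", "no")),
                "flag column '%s' has states outside yes/no/missing", f)
    df[[f]] <- factor(v, levels = c("no", "yes"))
  }
  if ("age" %in% names(df)) {
    df$age <- as.numeric(df$age)
    stop_if_not(all(is.na(df$age) | (df$age >= 0 & df$age <= 120)),
                "ages must lie in [0, 120]")
  }
  attr(df, "flags") <- flags
  df
}

#' Write per-sample metadata as TSV
#'
#' @param meta metadata data frame (first column `sample_id`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  for (nm in names(out)) {
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "missing")
  invisible(path)
}

#' Read / write a square distance matrix as TSV
#'
#' Validates symmetry (to 1e-10) and a zero diagonal.
#'
#' @param path file path.
#' @return a `dist` object with sample labels.
#' @export
read_distance <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  validate_distance(m)
  as.dist(m)
}

#' @param d a `dist` object or symmetric matrix.
#' @rdname read_distance
#' @export
write_distance <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_distance <- function(m) {
  stop_if_not(nrow(m) == ncol(m), "distance matrix must be square")
  stop_if_not(all(is.finite(m)), "distance matrix has non-finite entries")
  stop_if_not(max(abs(m - t(m))) <= 1e-10, "distance matrix not symmetric")
  stop_if_not(all(diag(m) == 0), "distance diagonal must be exactly 0")
  stop_if_not(min(m) >= 0, "distances must be nonnegative")
  invisible(TRUE)
}

#' Read / write a rooted phylogeny (newick)
#'
#' Thin wrappers around \pkg{ape} kept for a uniform IO surface.
#'
#' @param path newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @param tree a `phylo` object.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write / read the planted-truth ledger of a synthetic cohort as JSON
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param path JSON file.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
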