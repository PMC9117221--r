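#' Centered log-ratio transform of a count table
#'
#' Maps each sample's composition to an unconstrained real vector:
#' `clr(x)_i = ln(x_i + pc) - mean_j ln(x_j + pc)`. The pseudocount handles
#' sampling zeros; the default of 1 added to all counts is the conventional
#' choice for amplicon tables and is exposed so analyses can pin it.
#'
#' @param x a [count_table] or a nonnegative matrix (taxa x samples).
#' @param pseudocount positive value added to every count.
#' @return a samples-by-taxa real matrix; every row sums to zero (within
#'   1e-8).
#' @export
clr_transform <- function(x, pseudocount = 1) {
  stop_if_not(is.numeric(pseudocount) && pseudocount > 0,
              "pseudocount must be positive")
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  lx <- log(t(m) + pseudocount)          # samples x taxa
  clr <- lx - rowMeans(lx)
  stop_if_not(all(is.finite(clr)), "CLR produced non-finite values")
  clr
}

#' Aitchison distance between samples
#'
#' Euclidean distance between CLR-transformed compositions; the
#' beta-diversity metric of the package. Being Euclidean, the resulting
#' matrix always embeds exactly in principal-coordinate space (no negative
#' eigenvalues), which the dispersion test relies on.
#'
#' @param x a [count_table], count matrix (taxa x samples), or an already
#'   CLR-transformed samples-by-taxa matrix (`clr = TRUE`).
#' @param pseudocount passed to [clr_transform()] when `x` holds counts.
#' @param clr set `TRUE` if `x` is already a CLR matrix.
#' @return a `dist` object over samples.
#' @export
aitchison_distance <- function(x, pseudocount = 1, clr = FALSE) {
  cm <- if (clr) as.matrix(x) else clr_transform(x, pseudocount)
  stop_if_not(all(is.finite(cm)), "non-finite CLR values")
  stop_if_not(nrow(cm) >= 2, "need at least 2 samples")
  dist(cm)
}

#' Alpha diversity per sample
#'
#' Shannon entropy (nats), Simpson's index (1 - sum p^2), species richness
#' (taxa with nonzero count) and, when a tree is given, Faith's
#' phylogenetic diversity (total branch length spanned by the observed
#' taxa, including the path to the root, so a sample containing every tip
#' scores the tree's total branch length). Computed on raw counts; no
#' rarefaction is applied.
#'
#' @param x a [count_table].
#' @param tree optional rooted `phylo` whose tips cover the observed taxa;
#'   required for `faith_pd`.
#' @param metrics subset of `c("shannon", "simpson", "richness",
#'   "faith_pd")`.
#' @return data frame with `sample_id` and one column per metric; samples
#'   with zero total get `NA` in every metric (with a warning).
#' @export
alpha_diversity <- function(x, tree = NULL,
                            metrics = c("shannon", "simpson", "richness",
                                        if (!is.null(tree)) "faith_pd")) {
  m <- x$counts
  comm <- t(m)                            # samples x taxa
  tot <- rowSums(comm)
  empty <- tot == 0
  if (any(empty)) {
    warning(sprintf("%d samples have zero total; alpha metrics reported as NA",
                    sum(empty)))
  }
  out <- data.frame(sample_id = rownames(comm), stringsAsFactors = FALSE)
  if ("shannon" %in% metrics) {
    out$shannon <- vegan::diversity(comm, index = "shannon")
  }
  if ("simpson" %in% metrics) {
    out$simpson <- vegan::diversity(comm, index = "simpson")
  }
  if ("richness" %in% metrics) out$richness <- rowSums(comm > 0)
  if ("faith_pd" %in% metrics) {
    stop_if_not(!is.null(tree), "faith_pd requires a tree")
    stop_if_not(ape::is.rooted(tree), "faith_pd requires a rooted tree")
    stop_if_not(all(colnames(comm) %in% tree$tip.label),
                "tree tips must cover all taxa")
    pd <- picante::pd(comm, tree, include.root = TRUE)
    out$faith_pd <- pd$PD
  }
  for (nm in setdiff(names(out), "sample_id")) out[[nm]][empty] <- NA_real_
  rownames(out) <- NULL
  out
}

#' UniFrac distances between samples
#'
#' Phylogeny-aware beta diversity. Unweighted UniFrac is the fraction of
#' branch length unique to either sample among the branch length covered by
#' their union; weighted UniFrac is the normalized abundance-weighted
#' variant, so both lie in [0, 1]. Computation is delegated to
#' \pkg{phyloseq}.
#'
#' @param x a [count_table].
#' @param tree rooted `phylo` with nonnegative branch lengths whose tips
#'   cover the taxa.
#' @param weighted logical; `FALSE` gives unweighted UniFrac.
#' @return a `dist` object over samples.
#' @export
unifrac <- function(x, tree, weighted = FALSE) {
  stop_if_not(inherits(tree, "phylo"), "tree must be a phylo object")
  stop_if_not(ape::is.rooted(tree), "UniFrac requires a rooted tree")
  stop_if_not(all(taxon_ids(x) %in% tree$tip.label),
              "all taxa must be present in the tree")
  stop_if_not(all(tree$edge.length >= 0), "branch lengths must be nonnegative")
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(x$counts, taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  phyloseq::UniFrac(ps, weighted = weighted, normalized = TRUE,
                    parallel = FALSE)
}
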